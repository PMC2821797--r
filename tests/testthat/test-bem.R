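# Shared BEM system at coarse resolution (built once per file).
bem_head <- small_head
bem_sys <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- assemble_bem(bem_head(), use_ipa = TRUE)
    cache
  }
})

test_that("the undeflated double-layer operator maps constants to
           constants", {
  sys <- bem_sys()
  n <- sys$n
  Mu <- sys$M - 1 / n               # remove the deflation term
  res <- Mu %*% rep(1, n)           # (I - Gamma) 1 should vanish
  expect_lt(max(abs(res)), 1e-10)
})

test_that("four surfaces assemble into a system of the total vertex count", {
  sys <- bem_sys()
  expect_identical(sys$n, as.integer(sum(sys$nv)))
  expect_identical(length(sys$nv), 4L)
  # closed-surface requirement is enforced
  broken <- bem_head()$meshes
  broken$scalp$triangles <- broken$scalp$triangles[-1, , drop = FALSE]
  expect_error(assemble_bem(broken, paper_shells()), "closed")
})

test_that("negating the moment negates the potentials exactly", {
  sys <- bem_sys()
  el <- small_electrodes()
  v1 <- bem_potential(sys, c(10, 20, 30), c(0, 1, 0), el)
  v2 <- bem_potential(sys, c(10, 20, 30), c(0, -1, 0), el)
  expect_equal(v2, -v1, tolerance = 1e-12)
})

test_that("BEM matches the analytic four-shell solution on spheres", {
  sys <- bem_sys()
  el <- small_electrodes()
  sp <- paper_shells()
  # radial dipole, eccentricity 0.5
  p1 <- c(0, 0, 0.5 * sp$radii[4])
  v <- bem_potential(sys, p1, c(0, 0, 1), el)
  expect_lt(rdm_mag(v, sphere_potential(p1, c(0, 0, 1), sp, el))["RDM"],
            0.05)
  # tangential dipole, eccentricity 0.8
  p2 <- c(0, 0, 0.8 * sp$radii[4])
  v <- bem_potential(sys, p2, c(1, 0, 0), el)
  expect_lt(rdm_mag(v, sphere_potential(p2, c(1, 0, 0), sp, el))["RDM"],
            0.10)
})

test_that("the isolated-problem correction improves accuracy with a
           realistic skull", {
  sys_no <- assemble_bem(bem_head(), use_ipa = FALSE)
  sys <- bem_sys()
  el <- small_electrodes()
  sp <- paper_shells()
  dip <- random_dipoles(8, max_ecc = 0.8, seed = 9)
  v_ipa <- bem_potential(sys, dip$pos, dip$mom, el)
  v_no <- bem_potential(sys_no, dip$pos, dip$mom, el)
  rdm <- function(V) sapply(seq_len(8), function(d)
    rdm_mag(V[, d], sphere_potential(dip$pos[d, ], dip$mom[d, ], sp,
                                     el))["RDM"])
  expect_lte(median(rdm(v_ipa)), median(rdm(v_no)))
})

test_that("lead-field columns equal single-dipole potentials and runs are
           deterministic", {
  sys <- bem_sys()
  el <- small_electrodes()
  src <- matrix(c(0, 0, 30, -20, 10, 25), 2, 3, byrow = TRUE)
  lf1 <- bem_leadfield(sys, el, src, "z")
  lf2 <- bem_leadfield(sys, el, src, "z")
  expect_identical(lf1$matrix, lf2$matrix)
  v <- bem_potential(sys, src[2, ], c(0, 0, 1), el)
  expect_lt(max(abs(lf1$matrix[, 2] - v)), 1e-10 * max(abs(v)))
  expect_equal(dim(lf1$matrix), c(62L, 2L))
})

test_that("an electrode placed at a scalp vertex reproduces the vertex
           potential", {
  sys <- bem_sys()
  scalp <- bem_head()$meshes$scalp
  vtx <- scalp$vertices[17, ]
  X <- local({
    dd <- sweep(sys$rr, 2, c(0, 0, 30))
    ir3 <- rowSums(dd^2)^(-1.5)
    sys$mults * ir3 * as.numeric(dd %*% c(1, 0, 0)) / (4 * pi)
  })
  vsurf <- eegfwd:::bem_solve(sys, X)
  P <- eegfwd:::bem_electrode_matrix(sys, matrix(vtx, 1))
  expect_equal(as.numeric(P %*% vsurf), vsurf[17], tolerance = 1e-9)
})

test_that("dipoles outside the brain surface are rejected", {
  sys <- bem_sys()
  el <- small_electrodes()
  expect_error(bem_potential(sys, c(0, 0, 80), c(1, 0, 0), el),
               "outside the brain")
})
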