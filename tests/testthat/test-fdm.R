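# Small uniform grids exercise the stencil; accuracy against the analytic
# sphere lives in the acceptance suite.

uniform_grid <- function(n = 7, sigma = 0.33, h = 1) {
  structure(list(labels = array(1L, c(n, n, n)), dims = rep(n, 3),
                 spacing = h, origin = rep(-(n - 1) / 2 * h, 3),
                 sigma = c(0, sigma)),
            class = "voxel_grid")
}

test_that("an interior stencil row is the 7-point Laplacian scaled by
           sigma h", {
  g <- uniform_grid(5, sigma = 0.33, h = 2)
  ctr <- eegfwd:::voxel_index(g, c(3, 3, 3))
  row <- eegfwd:::.fdm_row(as.integer(g$labels), as.integer(g$dims),
                           g$sigma, g$spacing, ctr - 1L)
  expect_equal(row[ctr], 6 * 0.33 * 2)
  nb <- c(eegfwd:::voxel_index(g, c(2, 3, 3)),
          eegfwd:::voxel_index(g, c(4, 3, 3)),
          eegfwd:::voxel_index(g, c(3, 2, 3)),
          eegfwd:::voxel_index(g, c(3, 4, 3)),
          eegfwd:::voxel_index(g, c(3, 3, 2)),
          eegfwd:::voxel_index(g, c(3, 3, 4)))
  expect_equal(unname(row[nb]), rep(-0.33 * 2, 6))
  expect_equal(sum(row), 0)
})

test_that("mixed faces use the harmonic mean of the two conductivities", {
  g <- uniform_grid(4, sigma = 0.33, h = 1)
  g$labels[3:4, , ] <- 2L
  g$sigma <- c(0, 0.33, 0.0042)
  v1 <- eegfwd:::voxel_index(g, c(2, 2, 2))   # label 1, +x neighbour label 2
  row <- eegfwd:::.fdm_row(as.integer(g$labels), as.integer(g$dims),
                           g$sigma, g$spacing, v1 - 1L)
  v2 <- eegfwd:::voxel_index(g, c(3, 2, 2))
  expect_equal(row[v2], -2 / (1 / 0.33 + 1 / 0.0042))
})

test_that("the operator is symmetric", {
  g <- uniform_grid(4)
  g$labels[1, 1, 1] <- 0L
  idx <- which(g$labels > 0)
  A <- sapply(idx, function(v)
    eegfwd:::.fdm_row(as.integer(g$labels), as.integer(g$dims), g$sigma,
                      g$spacing, v - 1L)[idx])
  expect_identical(max(abs(A - t(A))), 0)
})

test_that("dipole injection preserves net current and moment direction", {
  g <- uniform_grid(15, h = 2)
  inj <- eegfwd:::dipole_injection(g, c(0.3, -0.4, 0.2), c(1, -2, 0.5))
  expect_equal(sum(inj$currents), 0, tolerance = 1e-12)
  # realized moment = sum of I * node position
  pos <- t(sapply(inj$nodes, function(v) {
    k <- (v - 1) %/% (15 * 15)
    r <- (v - 1) %% (15 * 15)
    g$origin + c(r %% 15, r %/% 15, k) * g$spacing
  }))
  mom <- colSums(inj$currents * pos)
  expect_equal(mom, c(1, -2, 0.5), tolerance = 1e-12)
})

test_that("a disconnected conductive domain is refused with sizes", {
  g <- uniform_grid(7)
  g$labels[4, , ] <- 0L                 # split the cube in two
  expect_error(assemble_fdm(g), "disconnected")
})

test_that("zero moment gives a zero lead-field column", {
  head <- small_head()
  grid <- voxelize(head, 6)
  sys <- assemble_fdm(grid)
  el <- place_electrodes(head$meshes$scalp, 8)
  lf <- fdm_leadfield(sys, el, matrix(c(0, 0, 20), 1), c(0, 0, 0))
  expect_true(all(lf$matrix == 0))
})

test_that("reciprocal and direct lead fields agree", {
  head <- small_head()
  grid <- voxelize(head, 6)
  sys <- assemble_fdm(grid)
  el <- place_electrodes(head$meshes$scalp, 8)
  src <- rbind(c(0, 0, 25), c(15, -20, 10), c(-25, 5, 30))
  lr <- fdm_leadfield(sys, el, src, "y", mode = "reciprocal")
  ld <- fdm_leadfield(sys, el, src, "y", mode = "direct")
  expect_lt(max(abs(lr$matrix - ld$matrix)) / max(abs(ld$matrix)), 1e-6)
})

test_that("dipoles outside the brain compartment are rejected", {
  head <- small_head()
  grid <- voxelize(head, 6)
  sys <- assemble_fdm(grid)
  expect_error(fdm_solve(sys, c(0, 0, 85), c(1, 0, 0)), "brain")
})
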