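test_that("central dipole in a homogeneous sphere matches the closed form", {
  sp <- shell_spec(92, conductivities = rep(0.33, 4))
  el <- exact_sphere_sensors()
  v <- sphere_potential(c(0, 0, 0), c(0, 0, 1), sp, el)
  ref <- 3 * el$positions[, 3] / 92 / (4 * pi * 0.33 * 92^2)
  ref <- ref - mean(ref)
  expect_lt(max(abs(v - ref)) / max(abs(ref)), 1e-8)
})

test_that("potentials are linear in the moment and symmetric for a central
           radial dipole", {
  sp <- paper_shells()
  el <- exact_sphere_sensors()
  v1 <- sphere_potential(c(0, 0, 30), c(1, 0, 0), sp, el)
  v2 <- sphere_potential(c(0, 0, 30), c(2, 0, 0), sp, el)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  # central radial (z) dipole: potential depends only on the polar angle
  v <- sphere_potential(c(0, 0, 0), c(0, 0, 1), sp, el)
  z <- el$positions[, 3]
  ord <- order(z)
  expect_equal(cor(v[ord], z[ord]), 1, tolerance = 1e-10)
})

test_that("series is converged at the default order up to ecc 0.95", {
  sp <- paper_shells()
  el <- exact_sphere_sensors()
  p <- c(0, 0, 0.95 * sp$radii[4])
  v1 <- sphere_potential(p, c(1, 0, 0), sp, el, n_terms = 100)
  v2 <- sphere_potential(p, c(1, 0, 0), sp, el, n_terms = 200)
  expect_lt(max(abs(v1 - v2)) / max(abs(v2)), 1e-6)
})

test_that("solution is equivariant under joint rotation", {
  sp <- paper_shells()
  el <- exact_sphere_sensors(32)
  set.seed(5)
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  p <- c(10, 20, 30); m <- c(0, 1, 0)
  va <- sphere_potential(p, m, sp, el)
  vb <- sphere_potential(as.numeric(A %*% p), as.numeric(A %*% m), sp,
                         el$positions %*% t(A))
  expect_lt(max(abs(va - vb)), 1e-10 * max(abs(va)))
})

test_that("dipoles on or outside the brain shell are rejected", {
  sp <- paper_shells()
  el <- exact_sphere_sensors(16)
  expect_error(sphere_potential(c(0, 0, 77.28), c(1, 0, 0), sp, el),
               "strictly inside")
})

test_that("the sphere fit is exact on a spherical scalp", {
  head <- small_head()
  elec <- small_electrodes()
  for (s in c(1, 30, 62)) {
    fs <- fit_sensor_sphere(head$meshes$scalp, elec$positions[s, ],
                            paper_shells())
    expect_lt(max(abs(fs$center)), 1e-6)
    expect_false(fs$degenerate)
  }
})

test_that("fitted radii vary over an ellipsoidal scalp", {
  m <- sphere_mesh(92, 642)
  m$vertices <- m$vertices %*% diag(c(1, 0.9, 0.8))
  elec <- place_electrodes(m, 16)
  radii <- sapply(1:16, function(s)
    fit_sensor_sphere(m, elec$positions[s, ], paper_shells())$radii[1])
  expect_gt(diff(range(radii)), 1)
})

test_that("a too-small patch is refused", {
  head <- small_head()
  expect_error(fit_sensor_sphere(head$meshes$scalp, c(0, 0, 92),
                                 paper_shells(), patch_radius = 3),
               "fewer than 10")
})

test_that("on a spherical head the sensor-fitted lead field reduces to the
           single-sphere lead field", {
  sp <- paper_shells()
  # sensors exactly on the analytic sphere so all fitted spheres coincide
  el <- exact_sphere_sensors(16)
  scalp <- small_head()$meshes$scalp
  src <- matrix(c(0, 0, 30, 20, -10, 40, -30, 25, 5), 3, 3, byrow = TRUE)
  lf <- sensor_fitted_leadfield(scalp, sp, el, src, "y")
  ref <- sapply(1:3, function(s)
    sphere_potential(src[s, ], c(0, 1, 0), sp, el))
  expect_lt(max(abs(lf$matrix - ref)) / max(abs(ref)), 1e-6)
  expect_identical(attr(lf, "n_clipped"), 0L)
  expect_equal(max(abs(colSums(lf$matrix))), 0, tolerance = 1e-12)
})

test_that("out-of-shell sources are clipped and counted", {
  sp <- paper_shells()
  el <- exact_sphere_sensors(8)
  scalp <- small_head()$meshes$scalp
  src <- rbind(c(0, 0, 77.0), c(0, 0, 30))   # first is beyond 0.98 ecc
  lf <- sensor_fitted_leadfield(scalp, sp, el, src, "x")
  expect_gt(attr(lf, "n_clipped"), 0)
  expect_true(all(is.finite(lf$matrix)))
})
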