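test_that("PSF maps equal brute-force Pearson correlation of columns", {
  set.seed(4)
  M <- matrix(rnorm(20), 5, 4)
  L <- leadfield(M, "SPH", "x")
  m <- psf_map(L, 1)
  brute <- sapply(1:4, function(j) {
    a <- M[, 1] - mean(M[, 1]); b <- M[, j] - mean(M[, j])
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  expect_equal(m$values, brute, tolerance = 1e-14)
  expect_identical(m$values[1], 1)
  # anti-correlated column
  M2 <- cbind(M, -M[, 1])
  expect_equal(psf_map(leadfield(M2, "SPH", "x"), 1)$values[5], -1)
})

test_that("zero-variance columns are reported missing, not zero", {
  M <- cbind(rnorm(6), 1, rnorm(6))
  L <- leadfield(M, "BEM", "x")
  m <- psf_map(L, 1)
  expect_true(is.na(m$values[2]))
  expect_identical(m$n_missing, 1L)
  expect_error(psf_map(L, 2), "zero variance")
  st <- psf_stats(m)
  expect_identical(attr(st, "n_missing"), 1L)
  expect_false(any(is.na(st)))
})

test_that("PSF is invariant to positive column scaling and sensor
           offsets", {
  set.seed(5)
  M <- matrix(rnorm(200), 10, 20)
  ref <- psf_map(leadfield(M, "SPH", "x"), 3)$values
  scaled <- M %*% diag(runif(20, 0.1, 10))
  expect_equal(psf_map(leadfield(scaled, "SPH", "x"), 3)$values, ref,
               tolerance = 1e-12)
  shifted <- M + matrix(rnorm(20), 10, 20, byrow = TRUE)[, rep(1, 20)] * 0 +
    5
  expect_equal(psf_map(leadfield(shifted, "SPH", "x"), 3)$values, ref,
               tolerance = 1e-10)
})

test_that("RMS superposition follows the root-mean-square formula", {
  mk <- function(v) structure(list(values = v, seed = 1, orientation = "x",
                                   model = "SPH", n_missing = 0),
                              class = "psf_map")
  r <- rms_superposition(list(mk(c(1, 0.4)), mk(c(1, 0.38)),
                              mk(c(1, -0.16))))
  expect_equal(r$values[2], sqrt((0.4^2 + 0.38^2 + 0.16^2) / 3),
               tolerance = 1e-12)
  expect_equal(r$values[1], 1)
  expect_identical(r$orientation, "RMS")
  # identical maps collapse to the absolute value
  m <- mk(c(1, -0.5, 0.2))
  expect_equal(rms_superposition(list(m, m, m))$values, abs(m$values))
  # zero maps stay zero
  z <- mk(c(0, 0))
  z$seed <- 1
  expect_true(all(rms_superposition(list(z, z, z))$values == 0))
  bad <- mk(c(1, 0.2)); bad$seed <- 2
  expect_error(rms_superposition(list(mk(c(1, 0.2)), bad, mk(c(1, 0.2)))),
               "mismatched seeds")
})

test_that("smoothing is the identity at zero kernel and contracts
           variance", {
  set.seed(6)
  pos <- matrix(rnorm(300) * 30, 100, 3)
  v <- rnorm(100)
  expect_identical(smooth_on_mesh(v, pos, 0), v)
  expect_equal(smooth_on_mesh(rep(2, 100), pos, 15), rep(2, 100),
               tolerance = 1e-12)
  sm <- smooth_on_mesh(v, pos, 25)
  expect_lt(var(sm), var(v))
})

test_that("the FWHM/sigma factor matches the numeric half-maximum width of
           a unit Gaussian", {
  expect_equal(round(fwhm_sigma_factor(), 5), 2.35482)
  half_x <- uniroot(function(x) exp(-x^2 / 2) - 0.5, c(0, 3),
                    tol = 1e-12)$root
  expect_equal(2 * half_x, fwhm_sigma_factor(), tolerance = 1e-9)
  # round trip
  expect_equal(fwhm_sigma_factor() * (70.64 / fwhm_sigma_factor()), 70.64)
})

test_that("profile fitting recovers Gaussian widths and flags degenerate
           input", {
  set.seed(7)
  pos <- matrix(rnorm(3000) * 40, 1000, 3)
  pos[1, ] <- 0
  d <- sqrt(rowSums(pos^2))
  fit <- fit_psf_profile(exp(-d^2 / (2 * 30^2)), c(0, 0, 0), pos)
  expect_equal(fit$fwhm, 2.35482 * 30, tolerance = 0.1 / 70)
  expect_equal(fit$sigma_equivalent, 30, tolerance = 1e-2)
  # two-component recovery at 1% noise, within 5%
  y <- 0.6 * exp(-d^2 / (2 * 15^2)) + 0.4 * exp(-d^2 / (2 * 50^2)) +
    rnorm(1000, 0, 0.01)
  fit2 <- fit_psf_profile(y, c(0, 0, 0), pos)
  co <- coef(fit2)
  ord <- order(c(co["s1"], co["s2"]))
  ss <- c(co["s1"], co["s2"])[ord]
  aa <- c(co["a1"], co["a2"])[ord]
  expect_lt(abs(ss[1] - 15) / 15, 0.05)
  expect_lt(abs(ss[2] - 50) / 50, 0.05)
  expect_lt(abs(aa[1] - 0.6) / 0.6, 0.05)
  expect_lt(abs(aa[2] - 0.4) / 0.4, 0.05)
  expect_error(fit_psf_profile(rep(1, 1000), c(0, 0, 0), pos),
               "constant profile")
  expect_error(fit_psf_profile(d[1:10], c(0, 0, 0), pos[1:10, ]),
               "at least 20")
})

test_that("fit objects expose coef/predict/residuals consistently", {
  set.seed(8)
  pos <- matrix(rnorm(900) * 30, 300, 3)
  d <- sqrt(rowSums(pos^2))
  fit <- fit_psf_profile(exp(-d^2 / (2 * 20^2)), c(0, 0, 0), pos)
  expect_named(coef(fit), c("a1", "s1", "a2", "s2"))
  expect_equal(predict(fit, 0), unname(sum(coef(fit)[c("a1", "a2")])),
               tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("batch FWHM maps agree with the single-seed pipeline", {
  set.seed(9)
  ne <- 16; ns <- 120
  pos <- matrix(rnorm(3 * ns) * 30, ns, 3)
  mk <- function() {
    # smooth synthetic lead field: sensors see nearby sources more
    el <- matrix(rnorm(3 * ne) * 50, ne, 3)
    M <- exp(-as.matrix(dist(rbind(el, pos)))[1:ne, ne + (1:ns)]^2 / 1500)
    leadfield(M + 0.01 * matrix(rnorm(ne * ns), ne, ns), "SPH", "x")
  }
  lfs <- list(x = mk(), y = mk(), z = mk())
  seeds <- c(5, 60)
  tab <- fwhm_map(lfs, pos, seeds, kernel_fwhm = 10)
  expect_identical(nrow(tab), 2L)
  # single-seed recomputation
  maps <- lapply(lfs, psf_map, seed = seeds[1])
  sm <- smooth_on_mesh(maps$x, pos, 10)
  f1 <- fit_psf_profile(sm, pos[seeds[1], ], pos)$fwhm
  expect_equal(tab$fwhm_x[1], f1, tolerance = 1e-10)
  expect_true(all(tab$fwhm_rms > 0))
})

test_that("identical lead fields give an identically zero FWHM difference
           map", {
  set.seed(10)
  ns <- 80
  pos <- matrix(rnorm(3 * ns) * 30, ns, 3)
  M <- exp(-as.matrix(dist(pos))[1:10, ]^2 / 800)
  lfs <- list(x = leadfield(M, "BEM", "x"), y = leadfield(M, "BEM", "y"),
              z = leadfield(M, "BEM", "z"))
  t1 <- fwhm_map(lfs, pos, c(3, 40), kernel_fwhm = 0)
  t2 <- fwhm_map(lfs, pos, c(3, 40), kernel_fwhm = 0)
  expect_equal(t1$fwhm_rms - t2$fwhm_rms, c(0, 0))
})
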