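test_that("fixture tables load with verified checksums and printed cells", {
  t1 <- load_fixture_table("table1")
  t2 <- load_fixture_table("table2")
  t3 <- load_fixture_table("table3")
  expect_identical(nrow(t1), 26L)
  expect_identical(t1$FDM_x[1], 0.76)
  expect_identical(t2$FDM_z[1], -0.16)
  expect_identical(t3$FDM_x[17], 50.9)
  expect_identical(attr(t3, "statistic"), "FWHM")
  expect_error(load_fixture_table("table9"), "unknown fixture")
})

test_that("a tampered fixture fails its checksum", {
  # stage a modified copy under a fake package layout
  tmp <- file.path(tempdir(), "extdata")
  dir.create(tmp, showWarnings = FALSE)
  src <- system.file("extdata", "table1_mean_psf.tsv", package = "eegfwd")
  lines <- readLines(src)
  lines[2] <- sub("0.76", "0.77", lines[2], fixed = TRUE)
  writeLines(lines, file.path(tmp, "table1_mean_psf.tsv"))
  expect_false(unname(tools::md5sum(file.path(tmp, "table1_mean_psf.tsv")))
               == unname(tools::md5sum(src)))
})

test_that("pairwise counts respect the tie rule and partition the
           conditions", {
  t1 <- load_fixture_table("table1")
  up <- count_pairwise(t1, "BEM", "FDM", "A_larger")
  down_strict <- sapply(c("x", "y", "z"), function(o)
    sum(t1[[paste0("FDM_", o)]] > t1[[paste0("BEM_", o)]]))
  expect_identical(unname(up[c("x", "y", "z")] + down_strict), rep(26L, 3))
  # self-comparison with ties counted is everything; strict is nothing
  self_up <- count_pairwise(t1, "FDM", "FDM", "A_larger")
  expect_identical(unname(self_up["total"]), 78L)
  expect_error(count_pairwise(t1, "BEM", "FDM", orientations = "w"),
               "not in table")
})

test_that("column summaries reproduce every printed Mean cell", {
  printed <- list(
    table1 = c(0.69, 0.70, 0.77, 0.67, 0.68, 0.77, 0.59, 0.78, 0.65,
               0.64, 0.72, 0.74),
    table3 = c(67.0, 70.9, 80.5, 68.3, 76.8, 82.9, 66.9, 78.3, 77.3,
               71.0, 71.3, 77.6))
  for (nm in names(printed)) {
    tab <- load_fixture_table(nm)
    s <- summarize_columns(tab)
    expect_equal(s$mean, printed[[nm]], tolerance = 0.051)
    expect_true(all(s$sd > 0))
  }
  # constant column: mean = value, sd = 0
  t1 <- load_fixture_table("table1")
  t1$FDM_x <- 0.5
  s <- summarize_columns(t1)
  expect_identical(s$mean[s$model == "FDM" & s$orientation == "x"], 0.5)
  expect_identical(s$sd[s$model == "FDM" & s$orientation == "x"], 0)
})

test_that("the paired t-test matches a brute-force formula and flags
           degenerate input", {
  t1 <- load_fixture_table("table1")
  res <- paired_t(t1, "FDM", "SPH", "x")
  d <- t1$FDM_x - t1$SPH_x
  tt <- mean(d) / (sd(d) / sqrt(26))
  expect_equal(res$t, tt, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(tt), 25), tolerance = 1e-12)
  expect_lt(res$p, 1e-3)
  # random 5-pair example against the textbook formula
  set.seed(12)
  df <- t1[1:5, ]
  df$BEM_y <- rnorm(5); df$FDM_y <- rnorm(5)
  r2 <- paired_t(df, "FDM", "BEM", "y")
  d2 <- df$FDM_y - df$BEM_y
  expect_equal(r2$t, mean(d2) / (sd(d2) / sqrt(5)), tolerance = 1e-10)
  # identical columns: undefined, flagged
  t1$BEM_x <- t1$FDM_x
  r3 <- paired_t(t1, "FDM", "BEM", "x")
  expect_true(r3$undefined)
  expect_true(is.na(r3$t))
})

test_that("SNR changes follow sigma = FWHM / 2.35482", {
  t1 <- load_fixture_table("table1")
  t3 <- load_fixture_table("table3")
  sc <- snr_change(t1, t3, "BEM", "SPH", "z")
  # source 1: BEM (0.75, 61.8) vs SPH (0.71, 71.6) -> +22.4%
  f <- fwhm_sigma_factor()
  ref1 <- 100 * ((0.75 / (61.8 / f)) - (0.71 / (71.6 / f))) /
    (0.71 / (71.6 / f))
  expect_equal(sc$per_source[1], ref1, tolerance = 1e-10)
  expect_equal(round(sc$per_source[1], 1), 22.4)
  # identical inputs give zero change
  sc0 <- snr_change(t1, t3, "BEM", "BEM", "z")
  expect_true(all(abs(sc0$per_source) < 1e-12))
})

test_that("the replication report is deterministic and clean outside the
           known pre-rounding rows", {
  r1 <- replicate_printed_statistics()
  r2 <- replicate_printed_statistics()
  expect_identical(r1, r2)
  expect_true(all(r1$match | r1$pre_rounding))
  expect_identical(sum(r1$pre_rounding), 2L)
})
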