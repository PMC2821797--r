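test_that("zero deformation reproduces exact concentric spheres", {
  head <- small_head()
  for (k in 1:4) {
    r <- sqrt(rowSums(head$meshes[[k]]$vertices^2))
    expect_lt(max(abs(r - paper_shells()$radii[k])), 1e-6)
  }
})

test_that("deformed heads are deterministic and nested", {
  h1 <- make_nested_head(paper_shells(), deformation = 0.015, seed = 7,
                         target_vertices = 162)
  h2 <- make_nested_head(paper_shells(), deformation = 0.015, seed = 7,
                         target_vertices = 162)
  expect_identical(h1$meshes$scalp$vertices, h2$meshes$scalp$vertices)
  expect_identical(h1$meshes$brain$vertices, h2$meshes$brain$vertices)
  expect_true(isTRUE(check_nesting(h1)))
  # a different seed gives a different head
  h3 <- make_nested_head(paper_shells(), deformation = 0.015, seed = 8,
                         target_vertices = 162)
  expect_false(identical(h1$meshes$scalp$vertices,
                         h3$meshes$scalp$vertices))
})

test_that("excessive deformation triggers a nesting error naming the pair", {
  # the CSF/brain gap is the thinnest (3% of the radius); grow the
  # amplitude until the check trips
  amp <- 0.02
  res <- NULL
  for (i in 1:8) {
    res <- try(make_nested_head(paper_shells(), deformation = amp,
                                seed = 2, target_vertices = 162),
               silent = TRUE)
    if (inherits(res, "try-error")) break
    amp <- amp * 2
  }
  expect_true(inherits(res, "try-error"))
  expect_match(attr(res, "condition")$message, "intersect|collapses")
})

test_that("electrodes cover the cap quasi-uniformly on the scalp mesh", {
  elec <- small_electrodes()
  expect_identical(elec$n, 62L)
  d <- as.matrix(dist(elec$positions))
  diag(d) <- NA
  expect_gt(min(d, na.rm = TRUE), 0)
  # each electrode lies on the mesh surface (radial ray hit)
  dirs <- elec$positions / sqrt(rowSums(elec$positions^2))
  r <- eegfwd:::.ray_mesh_radius(dirs, small_head()$meshes$scalp$vertices,
                                 small_head()$meshes$scalp$triangles)
  expect_lt(max(abs(sqrt(rowSums(elec$positions^2)) - r)), 1e-6 * 92)
})

test_that("four electrodes on a full sphere are near-tetrahedral", {
  e4 <- place_electrodes(sphere_mesh(92, 642), 4, cap_degrees = 180)
  d <- as.matrix(dist(e4$positions))
  diag(d) <- NA
  nn <- apply(d, 1, min, na.rm = TRUE)
  expect_lt(max(nn) / min(nn), 1.5)
})

test_that("a too-small cap refuses the electrode count", {
  expect_error(place_electrodes(small_head()$meshes$scalp, 62,
                                cap_degrees = 3),
               "cap too small")
  expect_error(place_electrodes(small_head()$meshes$scalp, 3), "at least 4")
})

test_that("cortex source space stays inside the brain with even coverage", {
  brain <- small_head()$meshes$brain
  src <- make_cortex_source_space(brain, 1000, seed = 4)
  expect_identical(nrow(src$positions), 1000L)
  # inside the brain surface
  r <- sqrt(rowSums(src$positions^2))
  dirs <- src$positions / r
  rb <- eegfwd:::.ray_mesh_radius(dirs, brain$vertices, brain$triangles)
  expect_true(all(r < rb))
  # wrinkle 0: spherical brain gives a single radius
  src0 <- make_cortex_source_space(brain, 500, wrinkle = 0, seed = 1)
  r0 <- sqrt(rowSums(src0$positions^2))
  expect_lt(diff(range(r0)), 1e-6)
  # nearest-neighbour distances are homogeneous (CV < 0.5)
  d <- as.matrix(dist(src$positions))
  diag(d) <- NA
  nn <- apply(d, 1, min, na.rm = TRUE)
  expect_lt(sd(nn) / mean(nn), 0.5)
})

test_that("probe selection is spread at least as well as random picks", {
  brain <- small_head()$meshes$brain
  src <- make_cortex_source_space(brain, 800, seed = 2)
  src <- select_probe_sources(src, 26)
  expect_identical(length(src$probe_indices), 26L)
  expect_false(any(duplicated(src$probe_indices)))
  mind <- function(idx) {
    d <- as.matrix(dist(src$positions[idx, ]))
    diag(d) <- NA
    min(d, na.rm = TRUE)
  }
  fps <- mind(src$probe_indices)
  set.seed(11)
  rnd <- replicate(20, mind(sample(800, 26)))
  expect_gte(fps, median(rnd))
  # p = M returns everything
  all_idx <- select_probe_sources(src, 800)
  expect_identical(all_idx$probe_indices, 1:800)
  expect_error(select_probe_sources(src, 801), "exceed")
})

test_that("voxel labels follow the nested compartments", {
  grid <- voxelize(small_head(), 4)
  # center voxel is brain
  ctr <- eegfwd:::voxel_index(grid, eegfwd:::nearest_voxel(grid, c(0, 0, 0)))
  expect_identical(as.integer(grid$labels[ctr]), 4L)
  # a voxel beyond the scalp is outside
  out <- eegfwd:::voxel_index(grid, eegfwd:::nearest_voxel(grid, c(0, 0, 98)))
  expect_identical(as.integer(grid$labels[out]), 0L)
  # brain volume within 5% of the analytic sphere volume
  vol <- sum(grid$labels == 4) * grid$spacing^3
  expect_lt(abs(vol - 4 / 3 * pi * 77.28^3) / (4 / 3 * pi * 77.28^3), 0.05)
  # conductivities keyed by label
  expect_equal(grid$sigma, c(0, 0.33, 0.0042, 1.79, 0.33))
})

test_that("point files round-trip in millimetres", {
  p <- matrix(rnorm(30), 10, 3)
  f <- tempfile(fileext = ".tsv")
  write_points(p, f)
  expect_identical(readLines(f, n = 1), "# mm")
  expect_identical(read_points(f), p)
})
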