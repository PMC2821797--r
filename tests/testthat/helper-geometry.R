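# Shared small-scale geometry for the unit tests (built once per file).
paper_shells <- function() shell_spec(92)

small_head <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_nested_head(paper_shells(), deformation = 0, seed = 1,
                                 target_vertices = 492)
    cache
  }
})

small_electrodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- place_electrodes(small_head()$meshes$scalp, 62)
    cache
  }
})

# sensors exactly on the analytic sphere (not the faceted mesh), for
# comparisons against the analytic solution
exact_sphere_sensors <- function(n = 62, radius = 92, cap_degrees = 130) {
  dirs <- eegfwd:::fibonacci_sphere(n, cap_degrees * pi / 180)
  structure(list(positions = dirs * radius, n = n,
                 cap_degrees = cap_degrees), class = "sensor_array")
}

random_dipoles <- function(n, max_ecc = 0.8, seed = 3,
                           r_brain = 0.84 * 92) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ecc <- runif(n, 0.2, max_ecc)
  mom <- matrix(rnorm(3 * n), ncol = 3)
  list(pos = dirs * (ecc * r_brain),
       mom = mom / sqrt(rowSums(mom^2)),
       ecc = ecc)
}
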