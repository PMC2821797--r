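# Synthetic head geometry: nested four-shell surfaces (exact concentric
# spheres or smoothly deformed "realistic-like" variants), scalp sensors,
# a cortex-like source surface and a labeled voxel volume.

# real spherical harmonics up to degree 4, unit direction matrix n x 3
real_sph_harm_basis <- function(dirs, lmax = 4, lmin = 2) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  ct <- pmin(1, pmax(-1, z))
  phi <- atan2(y, x)
  out <- list()
  for (l in lmin:lmax) {
    plm <- assoc_legendre(l, ct)   # (l+1) columns, m = 0..l
    for (m in 0:l) {
      K <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      if (m == 0) {
        out[[length(out) + 1L]] <- K * plm[, 1]
      } else {
        out[[length(out) + 1L]] <- sqrt(2) * K * plm[, m + 1] * cos(m * phi)
        out[[length(out) + 1L]] <- sqrt(2) * K * plm[, m + 1] * sin(m * phi)
      }
    }
  }
  do.call(cbind, out)
}

# associated Legendre P_l^m(x) for m = 0..l (no Condon-Shortley phase
# cancellation issues for our use; standard recurrence)
assoc_legendre <- function(l, x) {
  out <- matrix(0, length(x), l + 1)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:l) {
    pmm <- rep(1, length(x))
    if (m > 0) pmm <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
    if (l == m) {
      out[, m + 1] <- pmm
      next
    }
    pmmp1 <- x * (2 * m + 1) * pmm
    if (l == m + 1) {
      out[, m + 1] <- pmmp1
      next
    }
    for (ll in (m + 2):l) {
      pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
      pmm <- pmmp1
      pmmp1 <- pll
    }
    out[, m + 1] <- pmmp1
  }
  out
}

# Smooth radial modulation fields for the four surfaces: a shared low-order
# spherical-harmonic field plus a small per-surface independent component,
# both normalized to unit RMS over the sphere. Returns a function
# (dirs, surface) -> multiplicative radius factor.
deformation_field <- function(amplitude, seed, n_surfaces = 4,
                              indep_fraction = 0.25, lmax = 4) {
  ncoef <- sum(2 * (2:lmax) + 1)
  set.seed(seed)
  shared <- rnorm(ncoef)
  indep <- matrix(rnorm(ncoef * n_surfaces), ncoef, n_surfaces)
  shared <- shared / sqrt(sum(shared^2))
  indep <- sweep(indep, 2, sqrt(colSums(indep^2)), "/")
  mix_s <- sqrt(1 - indep_fraction^2)
  function(dirs, k) {
    if (amplitude == 0) return(rep(1, nrow(dirs)))
    B <- real_sph_harm_basis(dirs, lmax = lmax)
    # unit-RMS normalisation: sum of squared coefficients = 1 and the basis
    # is orthonormal, so the field has unit RMS over the sphere
    co <- mix_s * shared + indep_fraction * indep[, k]
    1 + amplitude * sqrt(4 * pi) * as.numeric(B %*% co)
  }
}

#' Nested four-shell head surfaces
#'
#' Builds the scalp, skull, CSF and brain surfaces as geodesic sphere
#' meshes at the shell radii, optionally deformed by a smooth low-order
#' spherical-harmonic radial field (shared across surfaces, with a small
#' independent component per surface) to mimic a realistic, non-spherical
#' head. `deformation = 0` reproduces exact concentric spheres.
#'
#' @param shells A [shell_spec()].
#' @param deformation Relative radial deformation amplitude (RMS over the
#'   sphere); 0.05 means 5 percent of each radius.
#' @param seed Integer seed controlling the deformation field.
#' @param target_vertices Vertex count per surface (passed to
#'   [sphere_mesh()]).
#' @return An object of class `head_model`: list of four [tri_mesh()]
#'   (`scalp`, `skull`, `csf`, `brain`), plus the shell spec and
#'   deformation parameters.
#' @export
make_nested_head <- function(shells, deformation = 0, seed = 1,
                             target_vertices = 1500) {
  stopifnot(inherits(shells, "shell_spec"))
  fld <- deformation_field(deformation, seed)
  meshes <- vector("list", 4)
  names(meshes) <- shells$tissues
  for (k in 1:4) {
    m <- sphere_mesh(shells$radii[k], target_vertices, shells$tissues[k])
    if (deformation != 0) {
      dirs <- m$vertices / shells$radii[k]
      fac <- fld(dirs, k)
      if (any(fac <= 0.2))
        stop("deformation amplitude too large: surface ",
             shells$tissues[k], " collapses")
      m$vertices <- m$vertices * fac
    }
    meshes[[k]] <- m
  }
  head <- structure(list(meshes = meshes, shells = shells,
                         deformation = deformation, seed = seed,
                         target_vertices = target_vertices),
                    class = "head_model")
  chk <- check_nesting(head)
  if (!isTRUE(chk)) stop(chk)
  head
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf(
    "head_model: 4 nested surfaces, %d vertices each, deformation %.3g\n",
    nrow(x$meshes[[1]]$vertices), x$deformation))
  print(x$shells)
  invisible(x)
}

# surface radius along arbitrary unit directions, by bilinear interpolation
# of a ray-cast latitude/longitude table (surfaces are star-shaped)
radial_table <- function(mesh, n_theta = 181, n_phi = 360) {
  th <- seq(0, pi, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  grid <- expand.grid(th = th, ph = ph)
  dirs <- cbind(sin(grid$th) * cos(grid$ph),
                sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  r <- .ray_mesh_radius(dirs, mesh$vertices, mesh$triangles)
  if (any(r <= 0)) stop("mesh is not star-shaped around the origin")
  list(theta = th, phi = ph, r = matrix(r, n_theta, n_phi))
}

radial_lookup <- function(tab, dirs) {
  z <- pmin(1, pmax(-1, dirs[, 3] / sqrt(rowSums(dirs^2))))
  th <- acos(z)
  ph <- atan2(dirs[, 2], dirs[, 1]) %% (2 * pi)
  nt <- length(tab$theta); np <- length(tab$phi)
  dt <- pi / (nt - 1); dp <- 2 * pi / np
  it <- pmin(nt - 1, pmax(1, floor(th / dt) + 1))
  wt <- th / dt - (it - 1)
  ip <- floor(ph / dp) + 1
  wp <- ph / dp - (ip - 1)
  ip2 <- ip %% np + 1
  r11 <- tab$r[cbind(it, ip)]; r12 <- tab$r[cbind(it, ip2)]
  r21 <- tab$r[cbind(it + 1, ip)]; r22 <- tab$r[cbind(it + 1, ip2)]
  (1 - wt) * ((1 - wp) * r11 + wp * r12) + wt * ((1 - wp) * r21 + wp * r22)
}

#' Check that the four head surfaces are properly nested
#'
#' Compares surface radii along a dense set of directions; every inner
#' surface must lie strictly inside the next outer one.
#' @param head A `head_model`.
#' @param margin Minimal allowed gap in mm.
#' @return `TRUE`, or a character message naming the offending surface pair.
#' @export
check_nesting <- function(head, margin = 1e-6) {
  dirs <- fibonacci_sphere(500)
  tabs <- lapply(head$meshes, radial_table, n_theta = 91, n_phi = 180)
  rr <- sapply(tabs, radial_lookup, dirs = dirs)
  for (k in 1:3) {
    if (any(rr[, k + 1] >= rr[, k] - margin))
      return(sprintf("surfaces intersect after deformation: %s/%s",
                     names(head$meshes)[k], names(head$meshes)[k + 1]))
  }
  TRUE
}

# quasi-uniform unit directions: spherical Fibonacci lattice, optionally
# restricted to a polar cap [0, theta_max]
fibonacci_sphere <- function(n, theta_max = pi) {
  i <- seq_len(n)
  z_lo <- cos(theta_max)
  z <- 1 - (i - 0.5) / n * (1 - z_lo)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Place EEG electrodes quasi-uniformly on the scalp
#'
#' Spherical Fibonacci points on a polar cap, projected radially onto the
#' scalp mesh.
#'
#' @param scalp Scalp [tri_mesh()].
#' @param n Number of electrodes (>= 4).
#' @param cap_degrees Angular extent of the covered cap, measured as polar
#'   angle from the vertex (+z); 180 covers the full sphere.
#' @param min_spacing Smallest physically usable inter-electrode distance
#'   (mm); an error is raised when the cap cannot host `n` electrodes at
#'   that spacing.
#' @return An object of class `sensor_array`: `positions` (n x 3, mm) and
#'   `n`.
#' @export
place_electrodes <- function(scalp, n = 62, cap_degrees = 130,
                             min_spacing = 5) {
  if (n < 4) stop("'n' must be at least 4")
  n <- as.integer(n)
  theta_max <- cap_degrees * pi / 180
  rmax <- max(sqrt(rowSums(scalp$vertices^2)))
  cap_area <- 2 * pi * rmax^2 * (1 - cos(theta_max))
  if (cap_area / n < (min_spacing^2))
    stop("cap too small to host ", n, " electrodes at ", min_spacing,
         " mm minimum spacing")
  dirs <- fibonacci_sphere(n, theta_max)
  r <- .ray_mesh_radius(dirs, scalp$vertices, scalp$triangles)
  if (any(r <= 0)) stop("failed to project an electrode onto the scalp")
  structure(list(positions = dirs * r, n = n,
                 cap_degrees = cap_degrees),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d electrodes (cap %g deg)\n", x$n,
              x$cap_degrees))
  invisible(x)
}

#' Cortex-like source space
#'
#' `m` quasi-evenly spaced points strictly inside the brain compartment:
#' Fibonacci directions mapped to a radially shrunk copy of the brain
#' surface, optionally modulated by a smooth higher-order "wrinkle" field
#' mimicking gyral/sulcal depth variation.
#'
#' @param brain Brain [tri_mesh()].
#' @param m Number of source points (default 5000).
#' @param shrink Radial shrink factor relative to the brain surface.
#' @param wrinkle Relative amplitude of the radial wrinkle modulation
#'   (bounded so all points stay inside the brain surface).
#' @param seed Seed for the wrinkle phases.
#' @return An object of class `source_space`: `positions` (m x 3, mm),
#'   `orientations` (the three Cartesian unit vectors) and `probe_indices`
#'   (initially empty; see [select_probe_sources()]).
#' @export
make_cortex_source_space <- function(brain, m = 5000, shrink = 0.9,
                                     wrinkle = 0.04, seed = 1) {
  stopifnot(m >= 1)
  m <- as.integer(m)
  dirs <- fibonacci_sphere(m)
  # surface radius by barycentric interpolation of vertex radii, so a
  # perfectly spherical brain yields a single radius independent of the
  # tessellation
  hit <- .ray_mesh_hit(dirs, brain$vertices, brain$triangles)
  if (any(hit[, 1] <= 0)) stop("brain mesh is not star-shaped")
  vrad <- sqrt(rowSums(brain$vertices^2))
  tri <- brain$triangles[hit[, 2], , drop = FALSE]
  rbrain <- hit[, 3] * vrad[tri[, 1]] + hit[, 4] * vrad[tri[, 2]] +
    hit[, 5] * vrad[tri[, 3]]
  if (wrinkle > 0) {
    set.seed(seed)
    ph <- runif(6, 0, 2 * pi)
    k <- sample(5:9, 6, replace = TRUE)
    x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
    w <- (sin(k[1] * x + ph[1]) * cos(k[2] * y + ph[2]) +
            sin(k[3] * y + ph[3]) * cos(k[4] * z + ph[4]) +
            sin(k[5] * z + ph[5]) * cos(k[6] * x + ph[6])) / 3
    fac <- 1 + wrinkle * w            # |w| <= 1 by construction
  } else {
    fac <- rep(1, m)
  }
  radius <- shrink * rbrain * fac
  if (any(radius >= rbrain * 0.995))
    stop("source points would fall outside the brain surface; ",
         "reduce 'shrink' or 'wrinkle'")
  structure(list(positions = dirs * radius,
                 orientations = diag(3),
                 probe_indices = integer(0),
                 m = m, shrink = shrink, wrinkle = wrinkle, seed = seed),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d points, %d probes\n", x$m,
              length(x$probe_indices)))
  invisible(x)
}

#' Select spatially spread probe sources
#'
#' Farthest-point (greedy maximin) sampling over the source positions,
#' giving a rather uniform spatial coverage of the cortex-like surface.
#' Deterministic: the sweep starts from the point farthest from the
#' centroid.
#'
#' @param space A [make_cortex_source_space()] result.
#' @param p Number of probes (default 26).
#' @return The `source_space` with `probe_indices` of length `p` filled in.
#' @export
select_probe_sources <- function(space, p = 26) {
  m <- nrow(space$positions)
  p <- as.integer(p)
  if (p > m) stop("'p' cannot exceed the number of source points")
  if (p == m) {
    space$probe_indices <- seq_len(m)
    return(space)
  }
  pos <- space$positions
  cen <- colMeans(pos)
  d0 <- sqrt(colSums((t(pos) - cen)^2))
  sel <- integer(p)
  sel[1] <- which.max(d0)
  mind <- sqrt(colSums((t(pos) - pos[sel[1], ])^2))
  if (p > 1) for (i in 2:p) {
    sel[i] <- which.max(mind)
    di <- sqrt(colSums((t(pos) - pos[sel[i], ])^2))
    mind <- pmin(mind, di)
  }
  space$probe_indices <- sel
  space
}

#' Voxelize nested head surfaces into a labeled volume
#'
#' Each voxel is labeled by the innermost surface containing its center
#' (0 outside, 1 scalp, 2 skull, 3 CSF, 4 brain); conductivities follow
#' the shell specification.
#'
#' @param head A `head_model`.
#' @param spacing Voxel edge length in mm.
#' @return An object of class `voxel_grid`: integer `labels` array with
#'   `dims`, `spacing`, `origin` (coordinates of the first voxel center)
#'   and `sigma` (conductivity per label, index 1 = label 0).
#' @export
voxelize <- function(head, spacing = 2) {
  stopifnot(inherits(head, "head_model"), spacing > 0)
  chk <- check_nesting(head)
  if (!isTRUE(chk)) stop(chk)
  rmax <- max(sqrt(rowSums(head$meshes$scalp$vertices^2)))
  half <- ceiling((rmax + 2 * spacing) / spacing)
  ax <- (-half:half) * spacing
  dims <- rep(length(ax), 3)
  centers <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r <- sqrt(rowSums(centers^2))
  dirs <- centers / pmax(r, 1e-12)
  dirs[r < 1e-12, ] <- c(0, 0, 1)
  labels <- integer(nrow(centers))
  tabs <- lapply(head$meshes, radial_table)
  for (k in 1:4) {                     # scalp -> brain, innermost wins
    rk <- radial_lookup(tabs[[k]], dirs)
    labels[r <= rk] <- k
  }
  structure(list(labels = array(labels, dims), dims = dims,
                 spacing = spacing, origin = c(ax[1], ax[1], ax[1]),
                 sigma = c(0, head$shells$conductivities)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels at %g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  tab <- table(factor(x$labels, levels = 0:4,
                      labels = c("outside", "scalp", "skull", "csf",
                                 "brain")))
  print(tab)
  invisible(x)
}

#' Write point coordinates as tab-delimited text
#' @param points n x 3 matrix (mm).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mm", con)
  writeLines(apply(points, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read point coordinates written by [write_points()]
#' @param path Input file.
#' @return n x 3 matrix.
#' @export
read_points <- function(path) {
  matrix(scan(path, skip = 1, quiet = TRUE), ncol = 3, byrow = TRUE)
}
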