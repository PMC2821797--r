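# Analytic EEG forward solution for a current dipole in a four-layer
# concentric sphere, and the sensor-fitted sphere scheme in which the
# multilayer sphere is refitted to the local scalp under each electrode.
#
# Per spherical-harmonic degree n the potential in layer j is
# A_j r^n + B_j r^-(n+1); interface continuity of V and sigma dV/dr plus
# the insulating outer boundary determine the surface gain of each degree
# relative to the infinite-medium multipole coefficient. The infinite-
# medium dipole expansion used here is
#   V_inf = 1/(4 pi s1) sum_n b^(n-1) r^-(n+1)
#           [ n (m.rd) P_n(c) + (m.(re - c rd)) P_n'(c) ],  c = re.rd.

# Legendre P_n and P_n' for n = 1..N at values x (vectorized):
# returns list of two (N x length(x)) matrices.
legendre_pn <- function(N, x) {
  P <- matrix(0, N, length(x))
  dP <- matrix(0, N, length(x))
  pm1 <- rep(1, length(x))   # P_0
  p <- x                      # P_1
  P[1, ] <- p
  dP[1, ] <- 1
  one_m_x2 <- 1 - x^2
  sing <- one_m_x2 < 1e-14
  if (N > 1) for (n in 2:N) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    pm1 <- p
    p <- pn
    P[n, ] <- p
    d <- n * (pm1 - x * p) / one_m_x2
    if (any(sing)) d[sing] <- sign(x[sing])^(n + 1) * n * (n + 1) / 2
    dP[n, ] <- d
  }
  list(P = P, dP = dP)
}

# Per-degree surface gains for the layered sphere, relative to the
# infinite-medium coefficient, evaluated at the outer surface.
# Layers are traversed inner (brain) to outer (scalp); radii normalized by
# the outer radius.
sphere_layer_gains <- function(shells, n_terms) {
  # scaled variables u = A r^n, w = B r^-(n+1) at the running radius keep
  # the propagation well conditioned at high degree
  rho <- rev(shells$radii) / shells$radii[1]  # interfaces inner->outer; + 1
  sig <- rev(shells$conductivities)           # brain, csf, skull, scalp
  gains <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    # interface map (u, w) -> M %*% (u, w) in the scaled variables
    Ms <- lapply(1:3, function(j) {
      sa <- sig[j]; sb <- sig[j + 1]
      matrix(c(sa * n + sb * (n + 1), n * (sb - sa),
               (n + 1) * (sb - sa), n * sb + (n + 1) * sa),
             2, 2) / (sb * (2 * n + 1))
    })
    su <- sw <- numeric(3)
    for (j in 1:3) {
      rnext <- if (j < 3) rho[j + 1] else 1
      su[j] <- (rnext / rho[j])^n
      sw[j] <- (rho[j] / rnext)^(n + 1)
    }
    # backward admittance pass: Y = w/u from the insulating outer
    # boundary (Y = n/(n+1)) down to the brain surface; tracking the
    # ratio only keeps the recursion free of the growing solution
    Y <- n / (n + 1)
    Ys <- numeric(3)                    # Y just inside interface j
    for (j in 3:1) {
      Y <- Y * su[j] / sw[j]            # undo radius carry
      M <- Ms[[j]]
      Ys[j] <- (M[1, 1] * Y - M[2, 1]) / (M[2, 2] - M[1, 2] * Y)
      Y <- Ys[j]
    }
    # at the brain surface w = 1 (normalized source), so u = 1 / Y
    u <- 1 / Y
    for (j in 1:3)
      u <- (Ms[[j]][1, 1] + Ms[[j]][1, 2] * Ys[j]) * u * su[j]
    # surface value u + w = u (1 + n/(n+1)); source at surface is
    # beta = rho1^(n+1)
    gains[n] <- u * (1 + n / (n + 1)) / rho[1]^(n + 1)
  }
  gains
}

#' Analytic dipole potential in a four-layer sphere
#'
#' Legendre-series solution for a current dipole inside the brain
#' compartment of a concentric four-shell sphere, evaluated at electrode
#' positions (projected radially to the scalp radius) and average
#' referenced.
#'
#' @param pos Dipole position (3-vector, mm), relative to `center`.
#' @param moment Dipole moment (3-vector); units are arbitrary but
#'   consistent across solvers (potentials scale linearly).
#' @param shells A [shell_spec()].
#' @param electrodes A `sensor_array` or an n x 3 matrix of positions.
#' @param n_terms Series truncation order.
#' @param center Sphere center.
#' @return Numeric vector of average-referenced potentials, one per
#'   electrode.
#' @export
sphere_potential <- function(pos, moment, shells, electrodes,
                             n_terms = 100, center = c(0, 0, 0)) {
  el <- if (inherits(electrodes, "sensor_array")) electrodes$positions
        else as.matrix(electrodes)
  v <- sphere_potential_multi(matrix(pos, 1), matrix(moment, 1), shells, el,
                              n_terms, center)
  as.numeric(v - mean(v))
}

# Potentials (electrodes x dipoles) for several dipoles sharing one sphere;
# NOT average referenced (callers re-reference at the end).
sphere_potential_multi <- function(pos, mom, shells, el, n_terms = 100,
                                   center = c(0, 0, 0)) {
  R <- shells$radii[1]
  rbrain <- shells$radii[4]
  sigma1 <- shells$conductivities[4]
  pos <- sweep(pos, 2, center)
  el <- sweep(el, 2, center)
  b <- sqrt(rowSums(pos^2))
  if (any(b / rbrain >= 1))
    stop("dipole must lie strictly inside the brain shell ",
         "(eccentricity < 1)")
  gains <- sphere_layer_gains(shells, n_terms)
  # electrodes evaluated on the outer radius along their directions
  eln <- el / sqrt(rowSums(el^2))
  ne <- nrow(eln); nd <- nrow(pos)
  out <- matrix(0, ne, nd)
  for (d in seq_len(nd)) {
    m <- mom[d, ]
    if (b[d] < 1e-9 * R) {
      # central dipole: only the n = 1 term survives
      out[, d] <- gains[1] * as.numeric(eln %*% m) / (4 * pi * sigma1 * R^2)
      next
    }
    rd <- pos[d, ] / b[d]
    cosg <- pmin(1, pmax(-1, as.numeric(eln %*% rd)))
    lp <- legendre_pn(n_terms, cosg)
    mr <- sum(m * rd)
    # tangential factor: m . (re - cosg * rd) per electrode
    mt <- as.numeric(eln %*% m) - cosg * mr
    bt <- b[d] / R
    ns <- seq_len(n_terms)
    wn <- gains * bt^(ns - 1)
    out[, d] <- (mr * colSums((wn * ns) * lp$P) +
                   mt * colSums(wn * lp$dP)) / (4 * pi * sigma1 * R^2)
  }
  out
}

#' Fit a sphere to the scalp patch under a sensor
#'
#' Least-squares (algebraic) sphere fit to the scalp vertices within a
#' geodesic `patch_radius` of the sensor; the outer radius is then reset
#' to the sensor-center distance and the inner radii follow the shell
#' ratios.
#'
#' @param scalp Scalp [tri_mesh()].
#' @param sensor Sensor position (3-vector, mm).
#' @param shells A [shell_spec()].
#' @param patch_radius Geodesic patch radius in mm.
#' @return An object of class `fitted_sphere`: `center`, `radii`,
#'   `degenerate` flag.
#' @export
fit_sensor_sphere <- function(scalp, sensor, shells, patch_radius = 40) {
  vd <- sqrt(colSums((t(scalp$vertices) - sensor)^2))
  nearest <- which.min(vd)
  gd <- mesh_geodesic(scalp, nearest, cutoff = patch_radius)
  sel <- which(gd <= patch_radius)
  if (length(sel) < 10)
    stop("scalp patch contains fewer than 10 vertices; ",
         "increase 'patch_radius'")
  fit <- fit_sphere_ls(scalp$vertices[sel, , drop = FALSE])
  degenerate <- FALSE
  rmax <- max(sqrt(rowSums(scalp$vertices^2)))
  if (!fit$ok || fit$radius > 10 * rmax) {
    degenerate <- TRUE
    fit <- fit_sphere_ls(scalp$vertices)
  }
  outer <- sqrt(sum((sensor - fit$center)^2))
  structure(list(center = fit$center,
                 radii = outer * shells$ratios,
                 degenerate = degenerate),
            class = "fitted_sphere")
}

# algebraic least-squares sphere: minimize |x|^2 - 2 c.x + (|c|^2 - R^2)
fit_sphere_ls <- function(pts) {
  A <- cbind(2 * pts, 1)
  y <- rowSums(pts^2)
  sv <- svd(A)
  ok <- sv$d[4] > 1e-8 * sv$d[1]
  co <- sv$v %*% (crossprod(sv$u, y) / sv$d)
  center <- co[1:3]
  r2 <- co[4] + sum(center^2)
  list(center = as.numeric(center),
       radius = sqrt(max(r2, 0)), ok = ok && r2 > 0)
}

# geodesic distance from one vertex over mesh edges (Dijkstra); vertices
# farther than 'cutoff' keep distance Inf
mesh_geodesic <- function(mesh, from, cutoff = Inf) {
  nv <- nrow(mesh$vertices)
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  adj <- vector("list", nv)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- rbind(adj[[e[i, 1]]], c(e[i, 2], w[i]))
    adj[[e[i, 2]]] <- rbind(adj[[e[i, 2]]], c(e[i, 1], w[i]))
  }
  dist <- rep(Inf, nv)
  dist[from] <- 0
  done <- rep(FALSE, nv)
  for (iter in seq_len(nv)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || dist[u] > cutoff) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    upd <- dist[u] + nb[, 2]
    better <- upd < dist[nb[, 1]]
    dist[nb[, 1][better]] <- upd[better]
  }
  dist
}

#' Fit spheres to the scalp under every sensor
#'
#' @param scalp Scalp [tri_mesh()].
#' @param electrodes A `sensor_array`.
#' @param shells A [shell_spec()].
#' @param patch_radius Geodesic patch radius (mm).
#' @return List of `fitted_sphere`, one per sensor.
#' @export
fit_all_sensor_spheres <- function(scalp, electrodes, shells,
                                   patch_radius = 40) {
  lapply(seq_len(electrodes$n), function(s)
    fit_sensor_sphere(scalp, electrodes$positions[s, ], shells,
                      patch_radius))
}

#' Sensor-fitted multilayer-sphere lead field
#'
#' Computes each lead-field row with a multilayer sphere fitted to the
#' scalp under that sensor; on a perfectly spherical head all fitted
#' spheres coincide with the global sphere. Sources falling outside a
#' fitted brain shell are clipped to a maximal eccentricity and counted.
#'
#' @param scalp Scalp [tri_mesh()].
#' @param shells A [shell_spec()].
#' @param electrodes A `sensor_array`.
#' @param sources A `source_space` or m x 3 position matrix.
#' @param orientation `"x"`, `"y"` or `"z"`, or a unit 3-vector.
#' @param n_terms Series truncation order.
#' @param patch_radius Scalp patch radius for the per-sensor fit (mm).
#' @param max_eccentricity Eccentricity at which out-of-shell sources are
#'   clipped.
#' @param fits Optional precomputed [fit_all_sensor_spheres()] result
#'   (reused across orientations).
#' @return A [leadfield()] (average referenced), with attribute
#'   `n_clipped` counting clipped sensor-source pairs.
#' @export
sensor_fitted_leadfield <- function(scalp, shells, electrodes, sources,
                                    orientation = "x", n_terms = 100,
                                    patch_radius = 40,
                                    max_eccentricity = 0.98,
                                    fits = NULL) {
  pos <- source_positions(sources)
  mom <- orientation_vector(orientation)
  ne <- electrodes$n
  if (is.null(fits))
    fits <- fit_all_sensor_spheres(scalp, electrodes, shells, patch_radius)
  L <- matrix(0, ne, nrow(pos))
  n_clipped <- 0L
  for (s in seq_len(ne)) {
    fs <- fits[[s]]
    sp_s <- shell_spec(fs$radii[1], shells$ratios, shells$conductivities)
    p <- sweep(pos, 2, fs$center)
    b <- sqrt(rowSums(p^2))
    lim <- max_eccentricity * fs$radii[4]
    clip <- b > lim
    n_clipped <- n_clipped + sum(clip)
    if (any(clip)) p[clip, ] <- p[clip, ] * (lim / b[clip])
    row <- sphere_row(p, mom, sp_s, electrodes$positions[s, ] - fs$center,
                      n_terms)
    L[s, ] <- row
  }
  lf <- leadfield(L, model = "SPH", orientation = orientation_tag(orientation))
  attr(lf, "n_clipped") <- n_clipped
  rereference_average(lf)
}

# one sensor row: potentials of all dipoles (rows of pos, common moment) at
# a single electrode of its fitted sphere
sphere_row <- function(pos, m, shells, el, n_terms) {
  R <- shells$radii[1]
  sigma1 <- shells$conductivities[4]
  gains <- sphere_layer_gains(shells, n_terms)
  eln <- el / sqrt(sum(el^2))
  b <- sqrt(rowSums(pos^2))
  central <- b < 1e-9 * R
  rd <- pos / pmax(b, 1e-300)
  cosg <- pmin(1, pmax(-1, as.numeric(rd %*% eln)))
  mr <- as.numeric(rd %*% m)
  mt <- sum(m * eln) - cosg * mr
  bt <- b / R
  # recurrences over sources, accumulating the series directly
  ns <- nrow(pos)
  acc <- numeric(ns)
  Pm1 <- rep(1, ns); P <- cosg
  one_m_x2 <- pmax(1 - cosg^2, 1e-14)
  bpow <- rep(1, ns)                    # bt^(n-1)
  for (n in seq_len(n_terms)) {
    dP <- n * (Pm1 - cosg * P) / one_m_x2
    acc <- acc + gains[n] * bpow * (n * mr * P + mt * dP)
    bpow <- bpow * bt
    Pn1 <- ((2 * n + 1) * cosg * P - n * Pm1) / (n + 1)
    Pm1 <- P
    P <- Pn1
  }
  acc[central] <- gains[1] * sum(m * eln) / 1
  acc / (4 * pi * sigma1 * R^2)
}

source_positions <- function(sources) {
  if (inherits(sources, "source_space")) sources$positions
  else as.matrix(sources)
}

orientation_vector <- function(orientation) {
  if (is.character(orientation))
    switch(orientation,
           x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("unknown orientation tag: ", orientation))
  else {
    v <- as.numeric(orientation)
    stopifnot(length(v) == 3)
    v
  }
}

orientation_tag <- function(orientation) {
  if (is.character(orientation)) orientation else "custom"
}
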