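# Boundary-element EEG forward solver: linear collocation with analytic
# solid-angle potential integrals on the four nested surfaces, deflation of
# the undetermined potential constant, and an isolated-source (isolated
# problem approach, IPA) correction at the skull inner boundary for the
# poorly conducting skull.
#
# Discretized double-layer equation (vertices as collocation points):
#   v = x + G v,   G = (1/2pi) gamma(k,l) W_kl,
# where W holds the analytic linear-basis solid-angle integrals,
# gamma(k,l) = (sigma_in(l) - sigma_out(l)) / (sigma_in(k) + sigma_out(k)),
# and x_i = 2/(sigma_in + sigma_out)_i * (1/4pi) q.(r_i - r0)/|r_i - r0|^3.
# The singular system is deflated by a rank-one correction.
#
# IPA: with e = sigma_skull/sigma_csf << 1 the potential inside the skull
# is split into the isolated potential v_iso of the CSF+brain region bounded
# by the skull inner surface (vacuum outside) and a small remainder solved
# from the full system with a modified right-hand side; the split is an
# exact reformulation that avoids the numerical cancellation of the strongly
# attenuated transmitted potential.

#' Assemble a four-shell BEM system
#'
#' @param head A `head_model` (its four surfaces are used outer to inner),
#'   or a list of four [tri_mesh()] ordered scalp, skull, CSF, brain.
#' @param shells A [shell_spec()]; required when `head` is a plain list.
#' @param use_ipa Apply the isolated-problem correction at the skull inner
#'   boundary (recommended for realistic skull conductivity).
#' @return An object of class `bem_system`.
#' @export
assemble_bem <- function(head, shells = NULL, use_ipa = TRUE) {
  if (inherits(head, "head_model")) {
    surfaces <- head$meshes
    shells <- head$shells
  } else {
    surfaces <- head
    if (is.null(shells)) stop("'shells' is required with a list of meshes")
  }
  stopifnot(length(surfaces) == 4)
  for (k in 1:4) {
    chk <- mesh_is_closed(surfaces[[k]])
    if (!isTRUE(chk))
      stop("surface ", k, " is not a closed oriented mesh: ", chk)
  }
  sig_in <- shells$conductivities
  sig_out <- c(0, shells$conductivities[-4])
  if (any(abs(sig_in - sig_out) < 1e-15))
    stop("zero conductivity jump across a surface")

  nv <- vapply(surfaces, function(s) nrow(s$vertices), 0L)
  offsets <- cumsum(c(0L, nv))
  rr <- do.call(rbind, lapply(surfaces, `[[`, "vertices"))
  tris <- do.call(rbind, lapply(seq_along(surfaces), function(k)
    surfaces[[k]]$triangles - 1L + offsets[k]))
  tri_surf <- rep.int(seq_along(surfaces), vapply(surfaces, function(s)
    nrow(s$triangles), 0L))
  vert_surf <- rep.int(seq_along(surfaces), nv)

  W <- .bem_lin_pot_coeff(rr, tris, tri_surf, vert_surf)
  .bem_correct_auto(W, tris, tri_surf, vert_surf, as.integer(offsets))

  n <- nrow(W)
  gamma <- outer(1 / (sig_in + sig_out), sig_in - sig_out)
  blk <- function(M, i, j) M[(offsets[i] + 1):offsets[i + 1],
                             (offsets[j] + 1):offsets[j + 1], drop = FALSE]
  # M = I + 1/n - (1/2pi) gamma o W
  Mfull <- W
  for (i in 1:4) for (j in 1:4) {
    ri <- (offsets[i] + 1):offsets[i + 1]
    cj <- (offsets[j] + 1):offsets[j + 1]
    Mfull[ri, cj] <- 1 / n - gamma[i, j] / (2 * pi) * Mfull[ri, cj]
  }
  diag(Mfull) <- diag(Mfull) + 1
  mults <- rep(2 / (sig_in + sig_out), nv)

  sys <- list(M = Mfull, rr = rr, tris0 = tris, offsets = offsets,
              nv = nv, surfaces = surfaces, shells = shells,
              mults = mults, use_ipa = use_ipa, n = n,
              cache = new.env(parent = emptyenv()))

  if (use_ipa) {
    eps <- sig_in[2] / sig_in[3]       # sigma_skull / sigma_csf
    iso <- (offsets[3] + 1):offsets[5] # csf + brain surface vertices
    n_iso <- length(iso)
    sin_iso <- sig_in[3:4]
    sout_iso <- c(0, sig_in[3])
    gam_iso <- outer(1 / (sin_iso + sout_iso), sin_iso - sout_iso)
    off_iso <- c(0L, nv[3], nv[3] + nv[4])
    Miso <- W[iso, iso]
    for (i in 1:2) for (j in 1:2) {
      ri <- (off_iso[i] + 1):off_iso[i + 1]
      cj <- (off_iso[j] + 1):off_iso[j + 1]
      Miso[ri, cj] <- 1 / n_iso - gam_iso[i, j] / (2 * pi) * Miso[ri, cj]
    }
    diag(Miso) <- diag(Miso) + 1
    # Right-hand-side coupling U (n x n_iso): all sources are O(eps).
    # On the outer rows the infinite-medium source cancels against the
    # isolated-conductor double layer (exterior representation of the
    # isolated problem); the residual coupling is -eps sigma_csf /
    # (sigma_in + sigma_out) D_k3 vhat_3. The isolated-surface rows keep
    # the exact O(eps) remainders of the reformulated system.
    U <- matrix(0, n, n_iso)
    i3 <- seq_len(nv[3])               # csf-surface columns within iso
    for (k in 1:2) {
      rk <- (offsets[k] + 1):offsets[k + 1]
      U[rk, i3] <- -eps * (sig_in[3] / (sig_in[k] + sig_out[k])) /
        (2 * pi) * blk(W, k, 3)
    }
    r3 <- (offsets[3] + 1):offsets[4]
    U[r3, i3] <- -eps / (1 + eps) *
      (diag(nv[3]) + gam_iso[1, 1] / (2 * pi) * blk(W, 3, 3))
    r4 <- (offsets[4] + 1):offsets[5]
    U[r4, i3] <- -eps * gam_iso[2, 1] / (2 * pi) * blk(W, 4, 3)
    kappa <- rep(c(1 + eps, 1), nv[3:4])
    sys$ipa <- list(M_iso = Miso, U = U, kappa = kappa, eps = eps,
                    iso = iso)
  }
  class(sys) <- "bem_system"
  sys
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("bem_system: %d vertices (%s), IPA %s\n", x$n,
              paste(x$nv, collapse = "+"),
              if (x$use_ipa) "on" else "off"))
  invisible(x)
}

# solve the (deflated) systems for a batch of right-hand sides;
# returns surface potentials (n x nrhs)
bem_solve <- function(system, X) {
  X <- as.matrix(X)
  if (!is.null(system$ipa)) {
    ip <- system$ipa
    Xi <- ip$kappa * X[ip$iso, , drop = FALSE]
    Vhat <- solve(ip$M_iso, Xi)
    # all direct source terms are absorbed into the isolated solution
    B <- ip$U %*% Vhat
    V <- solve(system$M, B)
    V[ip$iso, ] <- V[ip$iso, , drop = FALSE] + Vhat
    V
  } else {
    solve(system$M, X)
  }
}

# electrode interpolation matrix (n_el x n): barycentric weights on the
# scalp mesh along the radial directions of the electrode positions
bem_electrode_matrix <- function(system, electrodes) {
  el <- if (inherits(electrodes, "sensor_array")) electrodes$positions
        else as.matrix(electrodes)
  dirs <- el / sqrt(rowSums(el^2))
  scalp <- system$surfaces[[1]]
  hit <- .ray_mesh_hit(dirs, scalp$vertices, scalp$triangles)
  if (any(hit[, 1] <= 0))
    stop("an electrode does not project onto the scalp surface")
  P <- matrix(0, nrow(el), system$n)
  for (i in seq_len(nrow(el))) {
    tri <- scalp$triangles[hit[i, 2], ]
    P[i, system$offsets[1] + tri] <- hit[i, 3:5]
  }
  P
}

#' BEM scalp potentials of one or more dipoles
#'
#' @param system A [assemble_bem()] result.
#' @param pos Dipole position(s): 3-vector or n x 3 matrix (mm).
#' @param moment Dipole moment(s): 3-vector or n x 3 matrix.
#' @param electrodes A `sensor_array` or electrode position matrix.
#' @return Average-referenced potentials: a vector (single dipole) or an
#'   electrodes x dipoles matrix.
#' @export
bem_potential <- function(system, pos, moment, electrodes) {
  single <- is.null(dim(pos))
  pos <- matrix(pos, ncol = 3, byrow = single && length(pos) == 3)
  moment <- matrix(moment, ncol = 3, byrow = single && length(moment) == 3)
  stopifnot(nrow(pos) == nrow(moment))
  check_inside_brain(system, pos)
  P <- bem_electrode_matrix(system, electrodes)
  X <- vapply(seq_len(nrow(pos)), function(d) {
    dd <- sweep(system$rr, 2, pos[d, ])
    ir3 <- rowSums(dd^2)^(-1.5)
    system$mults * ir3 * as.numeric(dd %*% moment[d, ]) / (4 * pi)
  }, numeric(system$n))
  V <- P %*% bem_solve(system, X)
  V <- sweep(V, 2, colMeans(V))
  if (single) as.numeric(V) else V
}

check_inside_brain <- function(system, pos) {
  brain <- system$surfaces[[4]]
  r <- sqrt(rowSums(pos^2))
  dirs <- pos / pmax(r, 1e-12)
  dirs[r < 1e-12, ] <- rep(c(0, 0, 1), each = sum(r < 1e-12))
  rb <- .ray_mesh_radius(dirs, brain$vertices, brain$triangles)
  if (any(r >= rb))
    stop("dipole lies on or outside the brain surface")
  invisible(TRUE)
}

# transfer matrices from right-hand sides to electrode potentials;
# cached in the system environment per electrode set
bem_transfer <- function(system, electrodes) {
  P <- bem_electrode_matrix(system, electrodes)
  key <- paste0("T_", digest_matrix(P))
  if (!is.null(system$cache[[key]])) return(system$cache[[key]])
  T0 <- t(solve(t(system$M), t(P)))
  out <- list(T0 = T0)
  if (!is.null(system$ipa)) {
    ip <- system$ipa
    G <- T0 %*% ip$U + P[, ip$iso, drop = FALSE]
    Tiso <- t(solve(t(ip$M_iso), t(G)))
    out$Tiso <- sweep(Tiso, 2, ip$kappa, "*")
    out$iso <- ip$iso
    # the direct source term is fully absorbed into the isolated route
    out$T0 <- NULL
  }
  system$cache[[key]] <- out
  out
}

digest_matrix <- function(m) {
  # cheap content key: dimensions plus a few moments
  paste(dim(m)[1], dim(m)[2], format(sum(m), digits = 12),
        format(sum(m * seq_along(m)), digits = 12), sep = "_")
}

#' BEM lead field
#'
#' Uses a transfer-matrix factorization (one factorization per electrode
#' set, reused across sources and orientations).
#'
#' @param system A [assemble_bem()] result.
#' @param electrodes A `sensor_array`.
#' @param sources A `source_space` or m x 3 position matrix.
#' @param orientation `"x"`, `"y"`, `"z"` or a unit 3-vector.
#' @param chunk Number of sources per right-hand-side block.
#' @return An average-referenced [leadfield()].
#' @export
bem_leadfield <- function(system, electrodes, sources, orientation = "x",
                          chunk = 500) {
  pos <- source_positions(sources)
  mom <- matrix(orientation_vector(orientation), 1)
  tr <- bem_transfer(system, electrodes)
  ne <- if (inherits(electrodes, "sensor_array")) electrodes$n
        else nrow(electrodes)
  L <- matrix(0, ne, nrow(pos))
  starts <- seq(1, nrow(pos), by = chunk)
  for (s0 in starts) {
    s1 <- min(s0 + chunk - 1, nrow(pos))
    if (!is.null(tr$Tiso)) {
      X <- .bem_inf_rhs(system$rr[tr$iso, , drop = FALSE],
                        system$mults[tr$iso],
                        pos[s0:s1, , drop = FALSE], mom)
      L[, s0:s1] <- tr$Tiso %*% X
    } else {
      X <- .bem_inf_rhs(system$rr, system$mults,
                        pos[s0:s1, , drop = FALSE], mom)
      L[, s0:s1] <- tr$T0 %*% X
    }
  }
  lf <- leadfield(L, model = "BEM",
                  orientation = orientation_tag(orientation))
  rereference_average(lf)
}
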