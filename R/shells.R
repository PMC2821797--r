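#' Four-layer shell specification
#'
#' Radii and conductivities of the four nested head compartments, ordered
#' outer to inner: scalp, skull, cerebrospinal fluid (CSF), brain. The
#' default radius proportions are 1:0.95:0.87:0.84 and the default
#' conductivities 0.33, 0.0042, 1.79 and 0.33 S/m (scalp, skull, CSF,
#' brain).
#'
#' @param outer_radius Scalp radius in mm.
#' @param ratios Four strictly decreasing fractions, the first equal to 1;
#'   layer radii are `outer_radius * ratios`.
#' @param conductivities Four positive conductivities in S/m, outer to
#'   inner.
#' @return An object of class `shell_spec` with elements `radii` (mm),
#'   `conductivities` (S/m), `ratios` and `tissues`.
#' @examples
#' sp <- shell_spec(92)
#' sp$radii  # 92.00 87.40 80.04 77.28
#' @export
shell_spec <- function(outer_radius = 92,
                       ratios = c(1, 0.95, 0.87, 0.84),
                       conductivities = c(0.33, 0.0042, 1.79, 0.33)) {
  if (!is.numeric(outer_radius) || length(outer_radius) != 1L ||
      outer_radius <= 0)
    stop("'outer_radius' must be a single positive length (mm)")
  if (length(ratios) != 4L || length(conductivities) != 4L)
    stop("'ratios' and 'conductivities' must have length 4")
  if (abs(ratios[1] - 1) > 1e-12)
    stop("the first radius ratio must be 1 (the scalp surface)")
  if (any(diff(ratios) >= 0))
    stop("radius ratios must be strictly decreasing (nested shells)")
  if (any(ratios <= 0))
    stop("radius ratios must be positive")
  if (any(conductivities <= 0))
    stop("all conductivities must be positive (S/m)")
  structure(
    list(radii = outer_radius * ratios,
         conductivities = as.numeric(conductivities),
         ratios = as.numeric(ratios),
         tissues = c("scalp", "skull", "csf", "brain")),
    class = "shell_spec")
}

#' @export
print.shell_spec <- function(x, ...) {
  cat("Four-layer shell specification (outer to inner)\n")
  df <- data.frame(tissue = x$tissues,
                   radius_mm = x$radii,
                   conductivity_S_per_m = x$conductivities)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rescale a shell specification to a new outer radius
#'
#' Keeps the radius proportions and conductivities, used when fitting the
#' multilayer sphere to an individual sensor.
#'
#' @param shells A [shell_spec()].
#' @param outer_radius New scalp radius in mm.
#' @return A `shell_spec`.
#' @export
rescale_shells <- function(shells, outer_radius) {
  stopifnot(inherits(shells, "shell_spec"))
  shell_spec(outer_radius, shells$ratios, shells$conductivities)
}
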