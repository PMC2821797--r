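#' Lead-field matrix container
#'
#' A sensors x sources matrix of forward potentials for one head model and
#' one source orientation; each column holds the electrode potentials of a
#' unit dipole at one source position.
#'
#' @param matrix Numeric sensors x sources matrix.
#' @param model Model tag: `"SPH"`, `"BEM"` or `"FDM"`.
#' @param orientation Orientation tag: `"x"`, `"y"`, `"z"` (or `"custom"`).
#' @param reference Reference convention, `"none"` or `"average"`.
#' @param geometry Optional geometry checksum string.
#' @return An object of class `leadfield`.
#' @export
leadfield <- function(matrix, model, orientation, reference = "none",
                      geometry = NULL) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) < 1L) stop("lead field must have at least one source")
  structure(list(matrix = matrix, model = model, orientation = orientation,
                 reference = reference, geometry = geometry),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("leadfield: %s/%s, %d sensors x %d sources (%s reference)\n",
              x$model, x$orientation, nrow(x$matrix), ncol(x$matrix),
              x$reference))
  invisible(x)
}

#' @export
dim.leadfield <- function(x) dim(x$matrix)

#' Re-reference a lead field to the average reference
#'
#' Removes the mean over sensors from every column; idempotent.
#' @param L A [leadfield()].
#' @return The re-referenced `leadfield`.
#' @export
rereference_average <- function(L) {
  stopifnot(inherits(L, "leadfield"))
  if (identical(L$reference, "average")) return(L)
  L$matrix <- sweep(L$matrix, 2, colMeans(L$matrix))
  L$reference <- "average"
  L
}

#' Shape and magnitude error between two potential vectors
#'
#' `RDM = || v/||v|| - w/||w|| ||` (relative difference measure, 0 for
#' identical shapes, sqrt(2) for orthogonal ones) and `MAG = ||v|| / ||w||`.
#'
#' @param v,w Numeric potential vectors of equal length.
#' @return Named numeric vector `c(RDM=, MAG=)`.
#' @export
rdm_mag <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stop("zero-norm potential vector")
  c(RDM = sqrt(sum((v / nv - w / nw)^2)), MAG = nv / nw)
}

#' Write a lead field as a plain-text container
#'
#' Full-precision tab-delimited matrix plus a JSON metadata sidecar
#' (`<path>.json`); the round trip through [read_leadfield()] is
#' bit-identical.
#'
#' @param L A [leadfield()].
#' @param path Output file for the matrix.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(L, path) {
  stopifnot(inherits(L, "leadfield"))
  con <- file(path, "w")
  writeLines(apply(L$matrix, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  close(con)
  meta <- list(model = L$model, orientation = L$orientation,
               reference = L$reference, geometry = L$geometry,
               dim = dim(L$matrix))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a lead field written by [write_leadfield()]
#' @param path Matrix file path.
#' @return A [leadfield()].
#' @export
read_leadfield <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- matrix(scan(path, quiet = TRUE), nrow = meta$dim[1], byrow = TRUE)
  leadfield(m, meta$model, meta$orientation, meta$reference,
            if (is.null(meta$geometry)) NULL else meta$geometry)
}

#' Assemble lead fields for several orientations with one solver
#'
#' Calls a solver handle for each requested orientation and returns the
#' lead fields as a named list. The solver handle is a function
#' `f(orientation)` returning a [leadfield()]; the three standard
#' orientations give the three matrices the PSF analysis consumes jointly.
#'
#' @param solver Function of one argument (orientation tag).
#' @param orientations Character vector, default `c("x","y","z")`.
#' @return Named list of `leadfield` objects.
#' @export
assemble_leadfields <- function(solver, orientations = c("x", "y", "z")) {
  if (length(orientations) < 1) stop("no orientations requested")
  out <- lapply(orientations, solver)
  names(out) <- orientations
  for (o in orientations)
    if (!inherits(out[[o]], "leadfield"))
      stop("solver handle did not return a leadfield for orientation ", o)
  out
}
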