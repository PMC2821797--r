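#' Triangle mesh constructor
#'
#' A closed triangulated surface: `vertices` is an n x 3 coordinate matrix
#' (mm), `triangles` an m x 3 matrix of 1-based vertex indices wound
#' counter-clockwise seen from outside.
#'
#' @param vertices Numeric n x 3 matrix.
#' @param triangles Integer m x 3 matrix of 1-based indices.
#' @param tissue Optional tissue label.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles, tissue = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            min(triangles) >= 1L, max(triangles) <= nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles,
                 tissue = tissue),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles%s (Euler: %d)\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$tissue)) "" else paste0(" [", x$tissue, "]"),
              mesh_euler(x)))
  invisible(x)
}

#' Euler characteristic V - E + F of a mesh
#'
#' Equals 2 for a closed surface of sphere topology.
#' @param mesh A [tri_mesh()].
#' @return Integer.
#' @export
mesh_euler <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - nrow(e) + nrow(tr)
}

mesh_edge_counts <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Check that a mesh is a closed oriented 2-manifold
#'
#' Every edge must be shared by exactly two triangles and traversed once in
#' each direction (consistent winding).
#' @param mesh A [tri_mesh()].
#' @return `TRUE` or a character description of the first defect found.
#' @export
mesh_is_closed <- function(mesh) {
  cnt <- mesh_edge_counts(mesh)
  if (any(cnt != 2L))
    return(sprintf("%d edges are not shared by exactly two triangles",
                   sum(cnt != 2L)))
  tr <- mesh$triangles
  dir_e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(dir_e[, 1], dir_e[, 2])
  if (any(duplicated(key)))
    return("inconsistent triangle winding (a directed edge repeats)")
  TRUE
}

#' Total surface area of a mesh
#' @param mesh A [tri_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

# Orient all triangles counter-clockwise seen from outside (star-shaped
# surfaces around the origin/centroid).
orient_outward <- function(vertices, triangles, center = NULL) {
  if (is.null(center)) center <- colMeans(vertices)
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  a <- vertices[triangles[, 2], , drop = FALSE] - v1
  b <- vertices[triangles[, 3], , drop = FALSE] - v1
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  cen <- sweep(v1, 2, center)
  flip <- rowSums(nrm * cen) < 0
  triangles[flip, c(2, 3)] <- triangles[flip, c(3, 2)]
  triangles
}

#' Geodesic sphere mesh
#'
#' Icosahedron-based class-I geodesic tessellation projected to a sphere.
#' The subdivision frequency is chosen so the vertex count is as close as
#' possible to `target_vertices` (counts follow 10 f^2 + 2); the result is
#' guaranteed within 20 percent of the target for targets >= 12.
#'
#' @param radius Sphere radius (mm).
#' @param target_vertices Requested vertex count (>= 12).
#' @param tissue Optional tissue label.
#' @return A closed, outward-oriented [tri_mesh()].
#' @examples
#' m <- sphere_mesh(92, 1500)
#' nrow(m$vertices)  # 1442
#' @export
sphere_mesh <- function(radius, target_vertices, tissue = NULL) {
  if (target_vertices < 12)
    stop("'target_vertices' must be at least 12 (icosahedron)")
  f <- max(1L, round(sqrt((target_vertices - 2) / 10)))
  # pick the frequency whose count is closest to the target
  cand <- unique(pmax(1L, f + (-1:1)))
  f <- cand[which.min(abs(10 * cand^2 + 2 - target_vertices))]
  ico <- icosahedron()
  geo <- subdivide_geodesic(ico$vertices, ico$triangles, f)
  vv <- geo$vertices / sqrt(rowSums(geo$vertices^2)) * radius
  tri <- orient_outward(vv, geo$triangles, c(0, 0, 0))
  tri_mesh(vv, tri, tissue)
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = tr)
}

# Split every triangle into f^2 smaller ones on the barycentric lattice,
# merging duplicate vertices along shared corners/edges via exact integer
# lattice keys.
subdivide_geodesic <- function(vertices, triangles, f) {
  if (f == 1L)
    return(list(vertices = vertices, triangles = triangles))
  vert_list <- list()
  keys <- character(0)
  n_new <- 0L
  get_vertex <- function(p, key) {
    hit <- match(key, keys)
    if (!is.na(hit)) return(hit)
    n_new <<- n_new + 1L
    keys[n_new] <<- key
    vert_list[[n_new]] <<- p / sqrt(sum(p^2))
    n_new
  }
  lattice_key <- function(t, parents, i, j) {
    w <- c(f - i - j, i, j)           # weights on parents 1,2,3
    nz <- which(w > 0)
    if (length(nz) == 1) return(paste0("c", parents[nz]))
    if (length(nz) == 2) {
      u <- parents[nz[1]]; v <- parents[nz[2]]
      wu <- w[nz[1]]
      if (u > v) { tmp <- u; u <- v; v <- tmp; wu <- w[nz[2]] }
      return(paste0("e", u, "_", v, "_", wu))
    }
    paste0("f", t, "_", i, "_", j)
  }
  tris_out <- vector("list", nrow(triangles))
  for (t in seq_len(nrow(triangles))) {
    parents <- triangles[t, ]
    a <- vertices[parents[1], ]
    b <- vertices[parents[2], ]
    c3 <- vertices[parents[3], ]
    # lattice index (i,j): point = a + i/f*(b-a) + j/f*(c-a), i+j <= f
    idx <- matrix(NA_integer_, f + 1, f + 1)
    for (i in 0:f) for (j in 0:(f - i)) {
      p <- a + (i / f) * (b - a) + (j / f) * (c3 - a)
      idx[i + 1, j + 1] <- get_vertex(p, lattice_key(t, parents, i, j))
    }
    tt <- list()
    for (i in 0:(f - 1)) for (j in 0:(f - 1 - i)) {
      tt[[length(tt) + 1L]] <- c(idx[i + 1, j + 1], idx[i + 2, j + 1],
                                 idx[i + 1, j + 2])
      if (i + j < f - 1)
        tt[[length(tt) + 1L]] <- c(idx[i + 2, j + 1], idx[i + 2, j + 2],
                                   idx[i + 1, j + 2])
    }
    tris_out[[t]] <- do.call(rbind, tt)
  }
  list(vertices = do.call(rbind, vert_list),
       triangles = do.call(rbind, tris_out))
}

#' Write a mesh as ascii PLY
#' @param mesh A [tri_mesh()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read an ascii PLY mesh
#' @param path PLY file written by [write_ply()] (ascii, double vertices).
#' @return A [tri_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  start <- which(lines == "end_header")
  verts <- matrix(scan(text = lines[start + seq_len(nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  faces <- matrix(scan(text = lines[start + nv + seq_len(nf)], quiet = TRUE),
                  ncol = 4, byrow = TRUE)
  tri_mesh(verts, faces[, 2:4] + 1L)
}
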