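#' Triangulated surface mesh
#'
#' Lightweight container for a triangulated 3D surface in millimetres:
#' an n x 3 vertex matrix and an m x 3 matrix of 1-based triangle indices.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based triangle vertex indices.
#' @return An object of class \code{surface_mesh} with elements
#'   \code{vertices} and \code{faces}.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stopf("vertices must have 3 columns")
  if (ncol(faces) != 3L) stopf("faces must have 3 columns")
  if (!all(is.finite(vertices))) stopf("vertex coordinates must be finite")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stopf("face indices out of range [1, %d]", nrow(vertices))
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# edge table as a 2-column matrix of sorted vertex index pairs (one row per
# half edge); used for manifold/closedness checks and adjacency
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_face_counts <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  table(key)
}

#' Test whether a mesh is a closed 2-manifold surface
#'
#' @param mesh a \code{surface_mesh}.
#' @return TRUE if every undirected edge is shared by exactly two triangles.
#' @export
is_closed_mesh <- function(mesh) {
  cnt <- edge_face_counts(mesh)
  length(cnt) > 0L && all(cnt == 2L)
}

is_manifold_mesh <- function(mesh) {
  cnt <- edge_face_counts(mesh)
  all(cnt <= 2L)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a \code{surface_mesh}.
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem volume; positive when triangle winding gives outward
#' normals.
#' @param mesh a \code{surface_mesh}.
#' @return numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# area-weighted outward vertex normals (rows normalised)
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    r <- rowsum(fn, group = f[, c])
    idx <- as.integer(rownames(r))
    n[idx, ] <- n[idx, ] + r
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# list of neighbouring vertex indices per vertex
vertex_neighbors <- function(mesh) {
  e <- mesh_edges(mesh)
  e <- unique(cbind(e[, 1], e[, 2]))
  both <- rbind(e, e[, c(2, 1)])
  split(both[, 2], factor(both[, 1], levels = seq_len(nrow(mesh$vertices))))
}

#' Exact closest points on a mesh surface
#'
#' For each query point returns the exact nearest point on the triangulated
#' surface, the distance, and the triangle index (lowest index wins ties).
#'
#' @param points numeric k x 3 matrix of query points (mm).
#' @param mesh target \code{surface_mesh}.
#' @return list with \code{points} (k x 3), \code{distance} (k),
#'   \code{triangle} (k, 1-based).
#' @export
closest_points <- function(points, mesh) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  closest_point_mesh_cpp(points, mesh$vertices, mesh$faces)
}

#' Surface-to-surface distance summary
#'
#' Vertex-sampled directed and symmetric mean surface distances between two
#' meshes.
#'
#' @param mesh_a,mesh_b \code{surface_mesh} objects.
#' @return list with \code{mean_ab}, \code{mean_ba}, \code{symmetric_mean},
#'   \code{hausdorff} (all mm).
#' @export
surface_distance <- function(mesh_a, mesh_b) {
  dab <- closest_points(mesh_a$vertices, mesh_b)$distance
  dba <- closest_points(mesh_b$vertices, mesh_a)$distance
  list(mean_ab = mean(dab), mean_ba = mean(dba),
       symmetric_mean = (mean(dab) + mean(dba)) / 2,
       hausdorff = max(max(dab), max(dba)))
}

#' Dice overlap coefficient between two binary masks
#' @param a,b logical arrays of identical shape.
#' @return numeric scalar in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
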