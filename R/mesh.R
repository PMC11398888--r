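#' Triangle mesh
#'
#' Create a triangle mesh from a vertex coordinate matrix and a face index
#' matrix. The mesh is the carrier of all finite-element structure in the
#' package: subject geometries, the common template, and the domain of every
#' vertex-valued map.
#'
#' Faces are 0-based and oriented counter-clockwise seen from outside
#' (outward normals). Orientation and validity are checked, not repaired:
#' a triangle whose area falls below \code{1e-12} times the squared
#' bounding-box diagonal is a hard error, because silently skipping
#' degenerate elements corrupts the finite-element penalty downstream.
#'
#' @param vertices numeric s x 3 matrix of vertex coordinates (mm).
#' @param faces integer t x 3 matrix of 0-based vertex indices.
#' @param check logical; validate invariants (default \code{TRUE}).
#' @return an object of class \code{fos_mesh} with elements
#'   \code{vertices} and \code{faces}.
#' @export
fos_mesh <- function(vertices, faces, check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an s x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be a t x 3 matrix")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "fos_mesh")
  if (check) validate_mesh(mesh)
  mesh
}

#' @exportS3Method base::print
print.fos_mesh <- function(x, ...) {
  cat(sprintf("<fos_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Vertex and face counts of a mesh
#' @param mesh a \code{fos_mesh}.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

bbox_diagonal <- function(vertices) {
  rng <- apply(vertices, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}

# Per-face area vector and (optionally) unit normals.
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  nrm2 <- sqrt(rowSums(cr^2))
  list(area = nrm2 / 2, normal = cr / pmax(nrm2, .Machine$double.xmin))
}

face_areas <- function(mesh) face_geometry(mesh)$area

#' Validate a triangle mesh
#'
#' Checks index bounds, finiteness, and the degenerate-triangle tolerance
#' (area > 1e-12 times squared bounding-box diagonal). With
#' \code{closed = TRUE} additionally requires every edge to be shared by
#' exactly two faces and Euler characteristic V - E + F = 2.
#'
#' @param mesh a \code{fos_mesh}.
#' @param closed logical; also check closedness (default \code{FALSE}).
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, closed = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) stop("non-finite vertex coordinates")
  s <- nrow(v)
  if (nrow(f) > 0L && (min(f) < 0L || max(f) >= s))
    stop("face indices out of range [0, s)")
  a <- face_areas(mesh)
  tol <- 1e-12 * bbox_diagonal(v)^2
  bad <- which(a <= tol)
  if (length(bad) > 0L)
    stop(sprintf("degenerate triangle at face index %d (area %.3e)",
                 bad[1L] - 1L, a[bad[1L]]))
  if (closed) {
    ec <- edge_counts(mesh)
    if (any(ec$count != 2L))
      stop("mesh not closed: found edges not shared by exactly 2 faces")
    chi <- s - nrow(ec) + nrow(f)
    if (chi != 2L)
      stop(sprintf("Euler characteristic %d != 2", chi))
  }
  invisible(mesh)
}

# Undirected edge table with incidence counts.
edge_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  data.frame(key = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Euler characteristic of a mesh
#'
#' V - E + F with undirected edge counting; 2 for a closed surface of
#' spherical topology.
#'
#' @param mesh a \code{fos_mesh}.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(edge_counts(mesh)) + n_faces(mesh)
}

#' Total surface area of a mesh
#' @param mesh a \code{fos_mesh}.
#' @return total area (squared input units).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Vertex function on a mesh
#'
#' A piecewise-linear scalar field given by one value per vertex, in the
#' units of the carried quantity (e.g. mm for cortical thickness). The
#' linear finite-element basis implied by the mesh interpolates the values.
#'
#' @param values numeric vector of length equal to the vertex count.
#' @param mesh the carrying \code{fos_mesh}.
#' @return an object of class \code{vertex_function}.
#' @export
vertex_function <- function(values, mesh) {
  values <- as.numeric(values)
  if (length(values) != n_vertices(mesh))
    stop("length of values must equal the vertex count of the mesh")
  if (!all(is.finite(values))) stop("vertex function values must be finite")
  structure(list(values = values, mesh = mesh), class = "vertex_function")
}

#' @exportS3Method base::print
print.vertex_function <- function(x, ...) {
  cat(sprintf("<vertex_function> %d values, range [%.4g, %.4g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# Coerce a vertex_function or bare numeric to a plain value vector of
# length s, with a size check.
vf_values <- function(f, s) {
  v <- if (inherits(f, "vertex_function")) f$values else as.numeric(f)
  if (length(v) != s) stop("vertex function length does not match mesh")
  v
}
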