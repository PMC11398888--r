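#' Generalized Procrustes alignment of corresponded meshes
#'
#' Removes translation, scale, and rigid rotation from a set of
#' vertex-corresponded meshes while iteratively estimating a template.
#' Each mesh is centered at the origin and scaled to unit centroid size
#' (root sum of squared vertex distances from the centroid); rotations are
#' the orthogonal Procrustes solutions with determinant +1 (no
#' reflections). The template is the vertex-wise mean, re-normalized and
#' iterated until the mean Procrustes distance changes by less than 1e-8
#' relatively.
#'
#' @param meshes list of corresponded \code{fos_mesh}es.
#' @return list with \code{aligned} (list of meshes) and \code{template}
#'   (a \code{fos_mesh} with faces copied from the inputs).
#' @export
gpa_align <- function(meshes) {
  if (length(meshes) == 0L) stop("need at least one mesh")
  s <- n_vertices(meshes[[1L]])
  if (!all(vapply(meshes, n_vertices, 1L) == s))
    stop("all meshes must share the vertex count")
  faces <- meshes[[1L]]$faces
  norm_conf <- function(X) {
    X <- sweep(X, 2L, colMeans(X))
    X / sqrt(sum(X^2))
  }
  confs <- lapply(meshes, function(m) norm_conf(m$vertices))
  if (length(confs) == 1L) {
    tmpl <- fos_mesh(confs[[1L]], faces, check = FALSE)
    return(list(aligned = list(tmpl), template = tmpl))
  }
  rotate_to <- function(X, Tm) {
    sv <- svd(crossprod(X, Tm))
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) {                 # enforce a proper rotation
      u <- sv$u
      u[, ncol(u)] <- -u[, ncol(u)]
      R <- u %*% t(sv$v)
    }
    X %*% R
  }
  tmpl <- confs[[1L]]
  prev_dist <- Inf
  for (it in seq_len(200L)) {
    confs <- lapply(confs, rotate_to, Tm = tmpl)
    tmpl_new <- norm_conf(Reduce(`+`, confs) / length(confs))
    dist <- mean(vapply(confs,
                        function(X) sqrt(sum((X - tmpl_new)^2)), 1.0))
    tmpl <- tmpl_new
    if (is.finite(prev_dist) &&
        abs(prev_dist - dist) <= 1e-8 * max(prev_dist, 1e-30)) break
    prev_dist <- dist
  }
  list(aligned = lapply(confs, fos_mesh, faces = faces, check = FALSE),
       template = fos_mesh(tmpl, faces, check = FALSE))
}
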