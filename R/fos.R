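#' Function on surface (FoS)
#'
#' A pair of a subject-specific closed geometry and a scalar map supported
#' on it, e.g. a cortical surface with its thickness map. The map must have
#' one value per mesh vertex; meshes are assumed vertex-corresponded across
#' subjects.
#'
#' @param geometry a \code{fos_mesh}.
#' @param map a \code{vertex_function} on \code{geometry}, or a bare value
#'   vector.
#' @return object of class \code{fos}.
#' @export
fos <- function(geometry, map) {
  values <- vf_values(map, n_vertices(geometry))
  structure(list(geometry = geometry,
                 map = vertex_function(values, geometry)),
            class = "fos")
}

#' @exportS3Method base::print
print.fos <- function(x, ...) {
  cat(sprintf("<fos> %d vertices, map range [%.4g, %.4g]\n",
              n_vertices(x$geometry), min(x$map$values), max(x$map$values)))
  invisible(x)
}

#' Linear representation of a FoS
#'
#' The pair (velocity field, spatially normalized map): the subject
#' geometry is the flow of the velocity field applied to the template, and
#' the normalized map carries the subject's scalar values on the template.
#' Both components live in linear spaces, which is what makes penalized
#' linear discriminant estimation possible.
#'
#' @param velocity a \code{velocity_field}.
#' @param normalized_map a \code{vertex_function} on the template.
#' @return object of class \code{linear_representation}.
#' @export
linear_representation <- function(velocity, normalized_map) {
  structure(list(velocity = velocity, normalized_map = normalized_map),
            class = "linear_representation")
}

#' Pull back a subject map onto the template
#'
#' Under exact vertex correspondence the pullback
#' \eqn{x_i = z_i \circ \phi_{v_i}} is an index map: the template vertex j
#' receives the subject's value at its corresponding vertex j, with no
#' interpolation.
#'
#' @param subject a \code{fos}.
#' @param template the template \code{fos_mesh}.
#' @return \code{vertex_function} on the template.
#' @export
pullback_map <- function(subject, template) {
  if (n_vertices(subject$geometry) != n_vertices(template))
    stop("subject and template vertex counts differ")
  vertex_function(subject$map$values, template)
}

#' Reconstruct a FoS from its linear representation
#'
#' Applies the velocity flow to the template and transports the normalized
#' map values unchanged onto the corresponding deformed vertices, inverting
#' the representation.
#'
#' @param template the template \code{fos_mesh}.
#' @param rep a \code{linear_representation}.
#' @param steps Euler sub-steps of the flow.
#' @return a \code{fos}.
#' @export
reconstruct_fos <- function(template, rep, steps = 8L) {
  geom <- deform_mesh(template, rep$velocity, steps)
  out <- fos(geom, rep$normalized_map$values)
  attr(out, "flipped_fraction") <- attr(geom, "flipped_fraction")
  out
}

#' Discriminant trajectory of FoSs
#'
#' The curve of FoSs traced by moving along the fitted discriminant
#' directions: geometry is the flow of \eqn{\bar v + c_1 \beta^G} applied
#' to the template, and the map is \eqn{c_2 \beta^F} transported onto the
#' deformed vertices. Larger c1, c2 describe configurations more strongly
#' associated with the positive class.
#'
#' @param template the template \code{fos_mesh}.
#' @param v_mean mean velocity field \eqn{\bar v}.
#' @param betaG geometric discriminant direction (\code{velocity_field},
#'   sharing kernel and control points with \code{v_mean}).
#' @param betaF map discriminant direction (\code{vertex_function} or
#'   value vector on the template).
#' @param c1,c2 trajectory coordinates.
#' @param steps Euler sub-steps of the flow.
#' @return a \code{fos} with attribute \code{flipped_fraction}.
#' @export
fos_trajectory <- function(template, v_mean, betaG, betaF, c1, c2,
                           steps = 8L) {
  vfield <- combine_velocity(v_mean, betaG, 1, c1)
  geom <- deform_mesh(template, vfield, steps)
  out <- fos(geom, c2 * vf_values(betaF, n_vertices(template)))
  attr(out, "flipped_fraction") <- attr(geom, "flipped_fraction")
  out
}
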