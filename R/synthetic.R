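#' Unit icosphere template
#'
#' Builds a unit-sphere triangle mesh by repeated 1-to-4 subdivision of a
#' regular icosahedron with projection of every new vertex onto the
#' sphere. Vertex counts are 12, 42, 162, 642, 2562, ... for levels
#' 0, 1, 2, 3, 4; the mesh is closed with outward orientation.
#'
#' @param level non-negative subdivision level.
#' @return a \code{fos_mesh}.
#' @export
make_template <- function(level = 2L) {
  level <- as.integer(level)
  if (level < 0L) stop("level must be >= 0")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  for (l in seq_len(level)) {
    nv <- nrow(v)
    midmap <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midmap[[key]]
      if (is.null(idx)) {
        p <- (verts[a + 1L, ] + verts[b + 1L, ]) / 2
        p <- p / sqrt(sum(p^2))
        verts <<- rbind(verts, p)
        idx <- nrow(verts) - 1L
        midmap[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[4L * (k - 1L) + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  fos_mesh(v, f)
}

#' Simulation scenario
#'
#' Collects every knob of the synthetic FoS generator. Maps emulate
#' cortical-thickness-like fields: a constant baseline (mm), a smooth
#' Gaussian bump contrast between classes, and Karhunen-Loeve noise built
#' from Laplace-Beltrami eigenfunctions of the template with a power-law
#' spectrum (mode j carries variance \code{noise_amp^2 j^-decay},
#' j = 2..k+1; the constant mode is excluded so the noise is zero-mean in
#' space). Geometries are deformations of the template by class-mean plus
#' subject-specific smooth random velocity fields, with amplitudes given
#' as RMS vertex displacements in template units.
#'
#' @param level icosphere subdivision level of the template.
#' @param n_per_class subjects per class.
#' @param delta class contrast amplitude of the map bump (mm).
#' @param bump_center,bump_width center (unit vector) and width of the
#'   Gaussian bump.
#' @param map_base baseline map value (mm).
#' @param noise_k number of Laplace-Beltrami noise modes.
#' @param noise_amp noise amplitude multiplier; may be length 2 for
#'   per-class amplitudes.
#' @param decay spectrum decay exponent (> 1 so the spectrum is
#'   square-summable); may be length 2 for per-class exponents (the
#'   unequal-covariance regime).
#' @param contrast_mode \code{"bump"}: class means differ by
#'   \code{delta * bump}; \code{"cov_aligned"}: the true discriminant
#'   direction is the bump itself and the mean difference is the
#'   covariance operator applied to it.
#' @param geom_amplitude RMS displacement of the class-mean geometric
#'   effect (0 disables it).
#' @param geom_noise RMS displacement of the per-subject random field.
#' @param geom_control_m number of velocity control points.
#' @param steps Euler sub-steps of the deformation flow.
#' @param seed integer master seed; every random draw derives from it.
#' @return object of class \code{simulation_scenario}.
#' @export
simulation_scenario <- function(level = 2L, n_per_class = 50L,
                                delta = 0.5, bump_center = c(0, 0, 1),
                                bump_width = 0.7, map_base = 2.5,
                                noise_k = 40L, noise_amp = 1,
                                decay = 2, contrast_mode = c("bump", "cov_aligned"),
                                geom_amplitude = 0.1, geom_noise = 0.03,
                                geom_control_m = 42L, steps = 8L,
                                seed = 1L) {
  contrast_mode <- match.arg(contrast_mode)
  if (any(decay <= 1)) stop("decay must exceed 1 (square-summable spectrum)")
  if (!all(is.finite(c(delta, noise_amp, geom_amplitude, geom_noise))))
    stop("amplitudes must be finite")
  structure(list(level = as.integer(level),
                 n_per_class = as.integer(n_per_class), delta = delta,
                 bump_center = bump_center / sqrt(sum(bump_center^2)),
                 bump_width = bump_width, map_base = map_base,
                 noise_k = as.integer(noise_k),
                 noise_amp = rep_len(noise_amp, 2L),
                 decay = rep_len(decay, 2L),
                 regime = if (length(unique(rep_len(decay, 2L))) == 1L &&
                              length(unique(rep_len(noise_amp, 2L))) == 1L)
                   "equal" else "unequal",
                 contrast_mode = contrast_mode,
                 geom_amplitude = geom_amplitude, geom_noise = geom_noise,
                 geom_control_m = as.integer(geom_control_m),
                 steps = as.integer(steps), seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Precompute template structures for a scenario
#'
#' Template mesh, finite-element operators (with the default epsilon),
#' Laplace-Beltrami eigenpairs for the noise modes, kernel and control
#' points. Replicated simulations should share one cache.
#'
#' @param scenario a \code{simulation_scenario}.
#' @return list with \code{template}, \code{ops}, \code{eig},
#'   \code{kernel}, \code{control_points}.
#' @export
scenario_cache <- function(scenario) {
  template <- make_template(scenario$level)
  s <- n_vertices(template)
  if (scenario$noise_k + 1L >= s)
    stop("noise_k too large for this template resolution")
  ops0 <- assemble_penalty(template, epsilon = 0)
  eig <- lb_eigenpairs(ops0, k = scenario$noise_k + 1L)
  theta2 <- eig$values[eig$values > 1e-8][1L]
  eps <- 1e-3 * theta2^2
  ops <- assemble_penalty(template, epsilon = eps)
  kernel <- default_kernel(template)
  cp <- template$vertices[farthest_points(template, scenario$geom_control_m), ,
                          drop = FALSE]
  list(template = template, ops = ops, eig = eig, kernel = kernel,
       control_points = cp)
}

# Gaussian bump values at template vertices.
bump_values <- function(template, scenario) {
  d2 <- rowSums(sweep(template$vertices, 2L, scenario$bump_center)^2)
  exp(-d2 / scenario$bump_width^2)
}

#' Simulate spatially normalized maps
#'
#' Draws \eqn{x_i = m_{g_i} + \sum_{j \ge 2} \sqrt{\tilde\theta_j}
#' \zeta_{ij} \phi_j} with iid standard normal scores and spectrum
#' \eqn{\tilde\theta_j = a_g^2 j^{-decay_g}} over Laplace-Beltrami
#' eigenfunctions of the template; class means differ by the scenario's
#' bump contrast. Fully determined by the scenario seed.
#'
#' @param ops \code{fem_operators} of the template.
#' @param scenario a \code{simulation_scenario}.
#' @param labels vector of class labels in \{1, 2\}.
#' @param eig precomputed \code{lb_eigenpairs} with at least
#'   \code{noise_k + 1} pairs (computed here if \code{NULL}).
#' @return list with \code{maps} (list of \code{vertex_function}),
#'   \code{contrast} (\code{vertex_function}, class-2 minus class-1 mean),
#'   \code{beta0} (\code{vertex_function}, the true discriminant
#'   direction under \code{"cov_aligned"}; \code{NULL} otherwise),
#'   \code{class_means}.
#' @export
simulate_maps <- function(ops, scenario, labels, eig = NULL) {
  template <- ops$mesh
  s <- length(ops$lumped_mass)
  k <- scenario$noise_k
  if (is.null(eig)) {
    if (k + 1L >= s) stop("noise_k too large for this template")
    eig <- lb_eigenpairs(ops, k = k + 1L)
  }
  if (ncol(eig$vectors) < k + 1L) stop("eigenpair cache too small")
  Phi <- eig$vectors[, 2:(k + 1L), drop = FALSE]   # exclude the constant
  jidx <- 2:(k + 1L)
  bump <- bump_values(template, scenario)
  base <- rep(scenario$map_base, s)
  # the contrast profile is the mean-centered bump: the noise excludes the
  # constant mode, so an uncentered contrast would make the classes
  # perfectly separable through a noise-free global offset, which is not a
  # realistic regime
  area <- sum(ops$lumped_mass)
  bc <- bump - sum(ops$lumped_mass * bump) / area
  if (scenario$contrast_mode == "bump") {
    contrast <- scenario$delta * bc
    beta0 <- NULL
  } else {
    # true discriminant direction is the centered bump; the mean
    # difference is the (equal-regime) covariance operator applied to it,
    # computed spectrally
    b <- as.numeric(t(Phi) %*% (ops$mass %*% bc))
    theta <- scenario$noise_amp[1L]^2 * jidx^(-scenario$decay[1L])
    contrast <- as.numeric(Phi %*% (theta * b)) * scenario$delta
    beta0 <- vertex_function(scenario$delta * bc, template)
  }
  mean1 <- base - contrast / 2
  mean2 <- base + contrast / 2
  n <- length(labels)
  maps <- vector("list", n)
  withr::with_seed(scenario$seed + 11L, {
    for (i in seq_len(n)) {
      g <- if (labels[i] == 1L) 1L else 2L
      sd_j <- scenario$noise_amp[g] * jidx^(-scenario$decay[g] / 2)
      zeta <- stats::rnorm(k)
      vals <- (if (g == 1L) mean1 else mean2) +
        as.numeric(Phi %*% (sd_j * zeta))
      maps[[i]] <- vertex_function(vals, template)
    }
  })
  list(maps = maps, contrast = vertex_function(contrast, template),
       beta0 = beta0,
       class_means = list(vertex_function(mean1, template),
                          vertex_function(mean2, template)))
}

# Draw a smooth random kernel field and rescale its coefficients so the
# RMS vertex velocity equals `rms` (zero field if rms == 0).
random_field <- function(template, kernel, control_points, rms) {
  m <- nrow(control_points)
  A <- matrix(stats::rnorm(3L * m), m, 3L)
  if (rms <= 0) return(velocity_field(control_points, 0 * A, kernel))
  v <- velocity_field(control_points, A, kernel)
  cur <- sqrt(mean(rowSums(eval_velocity(v, template$vertices)^2)))
  velocity_field(control_points, A * (rms / cur), kernel)
}

#' Simulate subject geometries
#'
#' Each subject's velocity field is the class-mean field (one smooth
#' random field per scenario, applied with opposite signs to the two
#' classes at half the geometric amplitude) plus an independent smooth
#' random field per subject; geometries are the Euler flows of these
#' fields applied to the template. Errors out if any deformation flips a
#' face, advising a smaller amplitude.
#'
#' @param template the template \code{fos_mesh}.
#' @param kernel a \code{kernel_spec}.
#' @param scenario a \code{simulation_scenario}.
#' @param labels vector of class labels in \{1, 2\}.
#' @param control_points optional m x 3 control-point matrix.
#' @return list with \code{velocities} (list of \code{velocity_field}),
#'   \code{meshes} (list of \code{fos_mesh}), \code{mean_effect} (the
#'   class-mean field at unit amplitude).
#' @export
simulate_geometries <- function(template, kernel, scenario, labels,
                                control_points = NULL) {
  if (is.null(control_points))
    control_points <- template$vertices[
      farthest_points(template, scenario$geom_control_m), , drop = FALSE]
  n <- length(labels)
  withr::with_seed(scenario$seed + 23L, {
    mean_field <- random_field(template, kernel, control_points, 1)
    velocities <- vector("list", n)
    for (i in seq_len(n)) {
      sgn <- if (labels[i] == 1L) -1 else 1
      noise <- random_field(template, kernel, control_points,
                            scenario$geom_noise)
      velocities[[i]] <- velocity_field(
        control_points,
        sgn * (scenario$geom_amplitude / 2) * mean_field$coefficients +
          noise$coefficients,
        kernel)
    }
  })
  meshes <- vector("list", n)
  for (i in seq_len(n)) {
    meshes[[i]] <- deform_mesh(template, velocities[[i]], scenario$steps)
    if (attr(meshes[[i]], "flipped_fraction") > 0)
      stop("deformation flipped faces; use a smaller geometric amplitude")
  }
  list(velocities = velocities, meshes = meshes, mean_effect = mean_field)
}

#' Simulate a labeled FoS dataset with known ground truth
#'
#' Composes the map and geometry generators: balanced labels, raw FoSs
#' (subject meshes carrying subject maps), and the exact linear
#' representations (the generating velocity fields and normalized maps),
#' so representation-estimation error can be isolated from fitting error.
#'
#' @param scenario a \code{simulation_scenario}.
#' @param cache optional \code{\link{scenario_cache}} result to share
#'   across replicates.
#' @return list with \code{labels}, \code{fos} (list of \code{fos}),
#'   \code{reps} (list of \code{linear_representation}),
#'   \code{ground_truth} (contrast, beta0, class means, mean geometric
#'   effect, scenario), \code{template}, \code{ops}, \code{kernel},
#'   \code{eig}.
#' @export
simulate_dataset <- function(scenario, cache = NULL) {
  if (scenario$n_per_class < 1L) stop("n_per_class must be >= 1")
  if (is.null(cache)) cache <- scenario_cache(scenario)
  labels <- rep(c(1L, 2L), each = scenario$n_per_class)
  mp <- simulate_maps(cache$ops, scenario, labels, eig = cache$eig)
  geo <- simulate_geometries(cache$template, cache$kernel, scenario, labels,
                             control_points = cache$control_points)
  n <- length(labels)
  fos_list <- vector("list", n)
  reps <- vector("list", n)
  for (i in seq_len(n)) {
    fos_list[[i]] <- fos(geo$meshes[[i]], mp$maps[[i]]$values)
    reps[[i]] <- linear_representation(geo$velocities[[i]], mp$maps[[i]])
  }
  list(labels = labels, fos = fos_list, reps = reps,
       ground_truth = list(contrast = mp$contrast, beta0 = mp$beta0,
                           class_means = mp$class_means,
                           mean_effect = geo$mean_effect,
                           scenario = scenario),
       template = cache$template, ops = cache$ops, kernel = cache$kernel,
       eig = cache$eig)
}
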