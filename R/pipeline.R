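#' Stratified train/validation/test split
#'
#' Randomly assigns subjects to the three splits, stratified by class so
#' that each split's class counts differ from the rounded targets by at
#' most one (largest-remainder rounding within class).
#'
#' @param labels two-class label vector.
#' @param fractions length-3 non-negative fractions (train, validation,
#'   test) summing to 1.
#' @param seed integer seed.
#' @return character vector in \code{c("train", "validation", "test")}
#'   aligned with \code{labels}.
#' @export
split_dataset <- function(labels, fractions = c(0.5, 0.2, 0.3), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative numbers summing to 1")
  splits <- c("train", "validation", "test")
  out <- character(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nc <- length(idx)
      target <- fractions * nc
      cnt <- floor(target)
      rem <- nc - sum(cnt)
      if (rem > 0) {
        extra <- order(target - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[extra] <- cnt[extra] + 1
      }
      out[sample(idx)] <- rep(splits, times = cnt)
    }
  })
  out
}

#' Dataset manifest I/O
#'
#' A manifest is a headered tab-delimited table with columns
#' \code{mesh_path}, \code{map_path}, \code{label} and optionally
#' \code{split}; the template mesh path travels in a comment header line.
#'
#' @param path file path.
#' @name manifest_io
NULL

#' @rdname manifest_io
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# template:", lines, value = TRUE)
  tab <- utils::read.delim(textConnection(
    grep("^#", lines, invert = TRUE, value = TRUE)))
  attr(tab, "template_path") <-
    if (length(hdr)) trimws(sub("^# template:", "", hdr[1L])) else NA
  needed <- c("mesh_path", "map_path", "label")
  if (!all(needed %in% names(tab)))
    stop("manifest must have columns mesh_path, map_path, label")
  base <- dirname(normalizePath(path))
  for (col in c("mesh_path", "map_path"))
    tab[[col]] <- ifelse(grepl("^/", tab[[col]]), tab[[col]],
                         file.path(base, tab[[col]]))
  missing <- c(tab$mesh_path, tab$map_path)[!file.exists(
    c(tab$mesh_path, tab$map_path))]
  if (length(missing))
    stop("manifest refers to missing files: ", missing[1L])
  tab
}

#' @rdname manifest_io
#' @param manifest data.frame as above.
#' @param template_path path of the template mesh recorded in the header.
#' @export
write_manifest <- function(manifest, path, template_path = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(template_path))
    writeLines(sprintf("# template: %s", template_path), con)
  suppressWarnings(utils::write.table(manifest, con, sep = "\t",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

# Tiny FNV-1a hash of a deparsed object; stamps artifacts with the
# effective configuration.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' Materializes every default so the effective configuration can be
#' echoed into the results bundle.
#'
#' @param scenario a \code{simulation_scenario} (synthetic input), or
#'   \code{NULL} when a manifest is supplied.
#' @param manifest_path path to a dataset manifest (ignored when a
#'   scenario is given).
#' @param fractions train/validation/test fractions.
#' @param grid data.frame of \code{lambda1}, \code{lambda2} values.
#' @param gamma velocity-matching regularization.
#' @param steps Euler sub-steps of the deformation flow.
#' @param control_m number of velocity control points.
#' @param threshold_criterion \code{"youden"} or
#'   \code{"fixed_specificity"}.
#' @param specificity target for \code{"fixed_specificity"}.
#' @param use_exact_representations logical; for synthetic data, skip the
#'   alignment and velocity re-estimation stages and use the generating
#'   representations directly.
#' @param trajectories optional data.frame of \code{c1}, \code{c2} values
#'   at which trajectory FoSs are produced.
#' @param out_dir optional output directory.
#' @param seed master seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = NULL, manifest_path = NULL,
                            fractions = c(0.5, 0.2, 0.3),
                            grid = expand.grid(lambda1 = 10^c(-2, 0, 2),
                                               lambda2 = 10^c(-4, -2, 0)),
                            gamma = 1e-4, steps = 8L, control_m = 64L,
                            threshold_criterion = "youden",
                            specificity = 0.9,
                            use_exact_representations = FALSE,
                            trajectories = NULL, out_dir = NULL,
                            seed = 1L) {
  structure(list(scenario = scenario, manifest_path = manifest_path,
                 fractions = fractions, grid = grid, gamma = gamma,
                 steps = as.integer(steps), control_m = as.integer(control_m),
                 threshold_criterion = threshold_criterion,
                 specificity = specificity,
                 use_exact_representations = use_exact_representations,
                 trajectories = trajectories, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full discriminant pipeline
#'
#' Loads or simulates a labeled FoS dataset, aligns the geometries by
#' generalized Procrustes analysis, estimates subject velocity fields and
#' pulls maps back to the template, splits the data, selects the
#' penalties on the validation AUC over the configured grid, chooses the
#' score threshold on the validation set, and evaluates AUC, sensitivity
#' and specificity on the test set. Every seed, tolerance, and matrix
#' dimension is logged in the returned bundle; with \code{out_dir} set,
#' the report, audit table, model archive and optional trajectory meshes
#' are written as delimited text/PLY stamped with the config hash.
#'
#' @param config a \code{pipeline_config}.
#' @return results bundle (list); see Details in the package vignette.
#' @export
run_pipeline <- function(config) {
  hash <- config_hash(config)
  if (!is.null(config$scenario)) {
    ds <- stage("simulate", simulate_dataset(config$scenario))
    labels <- ds$labels
    meshes <- lapply(ds$fos, `[[`, "geometry")
    maps <- lapply(ds$fos, `[[`, "map")
  } else {
    man <- stage("load", read_manifest(config$manifest_path))
    labels <- man$label
    meshes <- stage("load", lapply(man$mesh_path, read_mesh))
    maps <- stage("load", Map(function(p, m) read_vertex_function(p, m),
                              man$map_path, meshes))
  }
  n <- length(labels)
  if (config$use_exact_representations && !is.null(config$scenario)) {
    template <- ds$template
    ops <- ds$ops
    kernel <- ds$kernel
    reps <- ds$reps
    resid <- rep(0, n)
  } else {
    al <- stage("align", gpa_align(meshes))
    template <- al$template
    stage("align", validate_mesh(template, closed = TRUE))
    ops <- stage("assemble",
                 assemble_penalty(template, default_epsilon(template)))
    kernel <- default_kernel(template)
    cp <- default_control_points(template, config$control_m)
    reps <- vector("list", n)
    resid <- numeric(n)
    for (i in seq_len(n)) {
      v <- stage(sprintf("represent (subject %d)", i),
                 estimate_velocity(template, al$aligned[[i]], kernel,
                                   control_points = cp,
                                   gamma = config$gamma,
                                   steps = config$steps))
      resid[i] <- attr(v, "residual_rms")
      x <- stage(sprintf("represent (subject %d)", i),
                 pullback_map(fos(al$aligned[[i]], maps[[i]]$values),
                              template))
      reps[[i]] <- linear_representation(v, x)
    }
  }
  assignment <- stage("split",
                      split_dataset(labels, config$fractions, config$seed))
  pick <- function(split) list(
    labels = labels[assignment == split],
    reps = reps[assignment == split])
  train <- pick("train")
  validation <- pick("validation")
  test <- pick("test")
  base_cfg <- fit_config(seed = config$seed)
  sel <- stage("select",
               select_lambdas(train, validation, config$grid,
                              epsilon = ops$epsilon, kernel = kernel,
                              ops = ops, config = base_cfg))
  model <- sel$model
  val_scores <- predict(model, validation$reps, ops)
  model$threshold <- stage("threshold",
    if (config$threshold_criterion == "youden")
      choose_threshold(val_scores, validation$labels)
    else choose_threshold(val_scores, validation$labels,
                          "fixed_specificity", q = config$specificity))
  test_scores <- predict(model, test$reps, ops)
  pos <- test$labels == model$classes[2L]
  metrics <- data.frame(
    auc = rank_auc(test_scores, test$labels),
    sensitivity = mean(test_scores[pos] > model$threshold),
    specificity = mean(test_scores[!pos] <= model$threshold),
    threshold = model$threshold)
  trajs <- NULL
  if (!is.null(config$trajectories)) {
    trajs <- stage("trajectory", lapply(seq_len(nrow(config$trajectories)),
      function(k) fos_trajectory(
        template, model$v_mean, discriminant_field(model),
        model$cF, config$trajectories$c1[k], config$trajectories$c2[k],
        steps = config$steps)))
  }
  bundle <- list(model = model, selection = sel$table,
                 best_config = sel$best, metrics = metrics,
                 assignment = assignment,
                 validation_scores = val_scores, test_scores = test_scores,
                 representation_residual_rms = resid,
                 template = template, ops = ops, kernel = kernel,
                 trajectories = trajs,
                 effective_config = config, config_hash = hash,
                 dims = c(n = n, s = length(ops$lumped_mass)))
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Geometric discriminant direction of a fitted model
#'
#' The representer expansion of the geometric direction collapses, under
#' the quadrature used for the Gram matrix, to a kernel field on the
#' quadrature points with coefficients given by the weighted centered
#' training evaluations times the representer coefficients; this returns
#' that field, sharing control points with the mean velocity field so it
#' can be combined into trajectories.
#'
#' @param model a \code{flda_model}.
#' @return a \code{velocity_field}.
#' @export
discriminant_field <- function(model) {
  ev <- model$gram$evals
  m <- dim(ev)[1L]
  A <- matrix(0, m, 3L)
  for (d in 1:3)
    A[, d] <- matrix(ev[, d, ], nrow = m) %*% model$cG
  velocity_field(model$gram$quad_points, A, model$kernel)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash: %s", bundle$config_hash)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(stamp, con)
    suppressWarnings(utils::write.table(df, con, sep = "\t",
                                        row.names = FALSE, quote = FALSE))
    close(con)
    p
  }
  wt(bundle$metrics, "report.tsv")
  wt(bundle$selection, "validation_auc.tsv")
  wt(data.frame(subject = seq_along(bundle$assignment),
                split = bundle$assignment), "splits.tsv")
  write_ply(bundle$template, file.path(out_dir, "template.ply"))
  write_vertex_function(vertex_function(bundle$model$cF, bundle$template),
                        file.path(out_dir, "beta_map_coefficients.tsv"))
  write_vertex_function(bundle$model$x_mean,
                        file.path(out_dir, "map_mean.tsv"))
  write_velocity_field(bundle$model$v_mean,
                       file.path(out_dir, "velocity_mean.tsv"))
  write_velocity_field(discriminant_field(bundle$model),
                       file.path(out_dir, "beta_geometry.tsv"))
  wt(data.frame(key = c("lambda1", "lambda2", "epsilon", "seed",
                        "n", "s", "threshold"),
                value = c(bundle$best_config$lambda1,
                          bundle$best_config$lambda2,
                          bundle$best_config$epsilon,
                          bundle$effective_config$seed,
                          bundle$dims["n"], bundle$dims["s"],
                          bundle$model$threshold)),
     "model_config.tsv")
  if (!is.null(bundle$trajectories))
    for (k in seq_along(bundle$trajectories)) {
      write_ply(bundle$trajectories[[k]]$geometry,
                file.path(out_dir, sprintf("trajectory_%02d.ply", k)))
      write_vertex_function(bundle$trajectories[[k]]$map,
                            file.path(out_dir,
                                      sprintf("trajectory_%02d_map.tsv", k)))
    }
  invisible(out_dir)
}
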