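#' Auxiliary regression responses for discriminant analysis
#'
#' Recodes a binary label vector as the scalar responses that turn the
#' discriminant problem into least-squares regression:
#' \eqn{y_i = -n/n_1} for the first class and \eqn{y_i = n/n_2} for the
#' second (classes in sorted label order). The responses sum to zero.
#'
#' @param labels length-n vector with exactly two distinct values.
#' @return object of class \code{auxiliary_responses}: list with \code{y},
#'   \code{n1}, \code{n2}, \code{classes}.
#' @export
auxiliary_responses <- function(labels) {
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("labels must contain exactly two classes")
  g1 <- labels == classes[1L]
  n <- length(labels)
  n1 <- sum(g1)
  n2 <- n - n1
  y <- ifelse(g1, -n / n1, n / n2)
  structure(list(y = y, n1 = n1, n2 = n2, classes = classes),
            class = "auxiliary_responses")
}

#' Gram matrix of velocity fields
#'
#' Quadrature approximation of the kernel-weighted double integrals
#' \eqn{\Sigma_{ij} = \int\int v_i(p)^T K(p,q) v_j(q) dp dq}:
#' \eqn{\Sigma_{ij} = \sum_{a,b} w_a w_b v_i(p_a)^T K(p_a,p_b) v_j(p_b)}.
#' This matrix is both the design block for the geometric component and
#' the squared RKHS norm metric of its representer expansion.
#'
#' @param velocities list of n \code{velocity_field}s sharing a kernel.
#' @param kernel the shared \code{kernel_spec}.
#' @param quad_points m x 3 matrix of quadrature points.
#' @param quad_weights length-m positive weights (default all 1; the
#'   overall scale is absorbed by the penalty grid).
#' @return object of class \code{gram_matrix}: list with \code{sigma}
#'   (n x n symmetric), \code{quad_points}, \code{quad_weights},
#'   \code{kernel}, \code{evals} (m x 3 x n array of weighted field
#'   evaluations, kept for scoring new subjects), \code{Kq} (m x m kernel
#'   matrix), and \code{quadrature} (description).
#' @export
gram_matrix <- function(velocities, kernel,
                        quad_points, quad_weights = rep(1, nrow(quad_points))) {
  n <- length(velocities)
  quad_points <- as.matrix(quad_points)
  m <- nrow(quad_points)
  if (any(quad_weights <= 0)) stop("quadrature weights must be positive")
  for (v in velocities)
    if (!same_kernel(v$kernel, kernel)) stop("kernel mismatch among fields")
  Kq <- kernel_matrix(kernel, quad_points, quad_points)
  evals <- array(0, dim = c(m, 3L, n))
  for (i in seq_len(n))
    evals[, , i] <- quad_weights * eval_velocity(velocities[[i]], quad_points)
  sigma <- matrix(0, n, n)
  for (d in 1:3) {
    Vd <- matrix(evals[, d, ], nrow = m)
    sigma <- sigma + crossprod(Vd, Kq %*% Vd)
  }
  sigma <- (sigma + t(sigma)) / 2
  structure(list(sigma = sigma, quad_points = quad_points,
                 quad_weights = quad_weights, kernel = kernel,
                 evals = evals, Kq = Kq,
                 quadrature = sprintf(
                   "tensor-product quadrature on %d points", m)),
            class = "gram_matrix")
}

# Weighted field evaluation block for a single (possibly new) field,
# matching the quadrature of a gram_matrix.
gram_row <- function(gram, velocity) {
  Vst <- gram$quad_weights * eval_velocity(velocity, gram$quad_points)
  n <- dim(gram$evals)[3L]
  out <- numeric(n)
  for (d in 1:3) {
    Vd <- matrix(gram$evals[, d, ], nrow = nrow(gram$quad_points))
    out <- out + as.numeric(crossprod(Vd, gram$Kq %*% Vst[, d]))
  }
  out
}

#' Fit configuration
#'
#' Tuning and solver parameters for the penalized discriminant fits. The
#' objective follows the augmented formulation without the 1/n factor, so
#' lambda values scale with n relative to the averaged form of the
#' estimator.
#'
#' @param lambda1 positive penalty on the geometric RKHS norm.
#' @param lambda2 positive penalty on the map roughness J.
#' @param epsilon non-negative shrinkage weight inside J; \code{NULL}
#'   means: inherit from the supplied operators.
#' @param tol LSQR convergence tolerance on the relative residual
#'   gradient.
#' @param max_iter LSQR iteration cap (\code{NULL}: 10 per unknown).
#' @param seed integer seed recorded with fits.
#' @return object of class \code{fit_config}.
#' @export
fit_config <- function(lambda1 = 1, lambda2 = 1, epsilon = NULL,
                       tol = 1e-10, max_iter = NULL, seed = 1L) {
  if (lambda1 <= 0 || lambda2 <= 0) stop("lambda1 and lambda2 must be positive")
  if (!is.null(epsilon) && epsilon < 0) stop("epsilon must be non-negative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, epsilon = epsilon,
                 tol = tol, max_iter = max_iter, seed = as.integer(seed)),
            class = "fit_config")
}

# Pivoted Cholesky-type factor L with L'L = B (+ jitter on the diagonal
# when B is not identically zero).
sigma_factor <- function(B, jitter_scale = 1e-10) {
  n <- nrow(B)
  tr <- sum(diag(B))
  if (tr <= 0) return(matrix(0, n, n))
  Bj <- B + diag(jitter_scale * tr / n, n)
  R <- suppressWarnings(chol(Bj, pivot = TRUE))
  piv <- attr(R, "pivot")
  R[, match(seq_len(n), piv), drop = FALSE]
}

# Penalty matrix for a given epsilon, re-derived from assembled operators
# so that the fit config is the single source of truth for epsilon.
penalty_for <- function(ops, epsilon) {
  if (!is.null(epsilon) && abs(epsilon - ops$epsilon) > 0) {
    Matrix::forceSymmetric(
      ops$stiffness %*% Matrix::Diagonal(x = 1 / ops$lumped_mass) %*%
        ops$stiffness + epsilon * ops$mass)
  } else ops$penalty
}

#' Build the sparse augmented least-squares system
#'
#' Stacks the blocks of the augmented formulation of the bivariate
#' penalized discriminant problem: data block \code{[Sigma, X M]}, map
#' roughness block \code{[0, sqrt(lambda2) Mt^{-1/2} S]}, map shrinkage
#' block \code{[0, sqrt(lambda2 epsilon) R_M]} (omitted when
#' \code{epsilon = 0}, leaving n + 2s rows), and RKHS block
#' \code{[sqrt(lambda1) L_Sigma, 0]}, with right-hand side \code{(y, 0)}.
#' \code{R_M} is a sparse Cholesky factor of the mass matrix and
#' \code{L_Sigma} a pivoted Cholesky factor of the (jittered) Gram matrix;
#' any factor with \code{L'L = Sigma} yields the same normal equations.
#'
#' @param sigma a \code{gram_matrix} or plain n x n matrix.
#' @param X n x s matrix of map basis coefficients.
#' @param ops \code{fem_operators} of the template.
#' @param config a \code{fit_config}.
#' @param y an \code{auxiliary_responses} or plain numeric vector.
#' @return list with sparse \code{A} ((n + 2s + n) x (n + s) for
#'   \code{epsilon > 0}), \code{rhs}, and the dimensions \code{n},
#'   \code{s}.
#' @export
build_augmented_system <- function(sigma, X, ops, config, y) {
  Sig <- if (inherits(sigma, "gram_matrix")) sigma$sigma else as.matrix(sigma)
  yv <- if (inherits(y, "auxiliary_responses")) y$y else as.numeric(y)
  n <- nrow(Sig)
  s <- length(ops$lumped_mass)
  if (nrow(X) != n || ncol(X) != s || length(yv) != n)
    stop("inconsistent dimensions among sigma, X, y, ops")
  if (config$lambda1 <= 0 || config$lambda2 <= 0)
    stop("lambda1 and lambda2 must be positive")
  eps <- if (is.null(config$epsilon)) ops$epsilon else config$epsilon
  M <- ops$mass
  S <- ops$stiffness
  XM <- as.matrix(X %*% M)
  Lsig <- sigma_factor(Sig)
  Mt_inv_half_S <- Matrix::Diagonal(x = 1 / sqrt(ops$lumped_mass)) %*% S
  blocks <- list(
    cbind(Matrix::Matrix(Sig, sparse = TRUE),
          Matrix::Matrix(XM, sparse = TRUE)),
    cbind(Matrix::Matrix(0, s, n), sqrt(config$lambda2) * Mt_inv_half_S))
  if (eps > 0) {
    RM <- Matrix::chol(M)
    blocks <- c(blocks, list(
      cbind(Matrix::Matrix(0, s, n),
            sqrt(config$lambda2 * eps) * RM)))
  }
  blocks <- c(blocks, list(
    cbind(sqrt(config$lambda1) * Matrix::Matrix(Lsig, sparse = TRUE),
          Matrix::Matrix(0, n, s))))
  A <- do.call(rbind, blocks)
  rhs <- c(yv, numeric(nrow(A) - n))
  list(A = A, rhs = rhs, n = n, s = s)
}

#' Solve the augmented system by sparse iterative least squares
#'
#' LSQR on the stacked system; never forms the normal matrix densely.
#' Convergence is declared when the relative residual-gradient norm drops
#' below the configured tolerance; hitting the iteration cap yields a
#' warning with the achieved tolerance, and the current iterate is still
#' returned.
#'
#' @param system list from \code{\link{build_augmented_system}}.
#' @param config a \code{fit_config}.
#' @return list with \code{cG} (length n), \code{cF} (length s),
#'   \code{iterations}, \code{converged}.
#' @export
solve_augmented <- function(system, config = fit_config()) {
  itnlim <- if (is.null(config$max_iter)) 10L * ncol(system$A)
            else config$max_iter
  res <- lsqr(system$A, system$rhs, atol = config$tol, itnlim = itnlim)
  if (!res$converged)
    warning(sprintf(
      "LSQR hit the iteration cap (%d); achieved relative gradient %.2e",
      res$itn, res$relgrad))
  list(cG = res$x[seq_len(system$n)],
       cF = res$x[system$n + seq_len(system$s)],
       iterations = res$itn, converged = res$converged)
}

#' Fit the functional linear discriminant model
#'
#' Centers the training representations by the mean velocity field (mean
#' of coefficients over a shared control-point set) and the vertex-wise
#' mean map, recodes the labels as auxiliary responses, assembles the
#' augmented sparse system, and solves it by LSQR. The result holds the
#' representer coefficients of the geometric direction, the finite-element
#' coefficients of the map direction, the centering functions, and a
#' default score threshold (Youden on the training scores; refit it on
#' validation data for honest operating points).
#'
#' @param labels length-n vector with two classes; scores are oriented so
#'   that the second sorted class has the larger mean score.
#' @param reps list of n \code{linear_representation}s on a common
#'   template, with velocity fields sharing kernel and control points.
#' @param ops \code{fem_operators} of the template.
#' @param kernel the shared \code{kernel_spec}.
#' @param config a \code{fit_config}.
#' @return object of class \code{flda_model}.
#' @export
fit_flda <- function(labels, reps, ops, kernel, config = fit_config()) {
  aux <- auxiliary_responses(labels)
  n <- length(reps)
  if (length(labels) != n) stop("labels and reps lengths differ")
  s <- length(ops$lumped_mass)
  vels <- lapply(reps, `[[`, "velocity")
  cp <- vels[[1L]]$control_points
  for (v in vels) {
    if (!same_kernel(v$kernel, kernel)) stop("kernel mismatch")
    if (max(abs(v$control_points - cp)) > 1e-10)
      stop("velocity fields must share control points")
  }
  coef_mean <- Reduce(`+`, lapply(vels, `[[`, "coefficients")) / n
  v_mean <- velocity_field(cp, coef_mean, kernel)
  vels_c <- lapply(vels, function(v)
    velocity_field(cp, v$coefficients - coef_mean, kernel))
  X <- do.call(rbind, lapply(reps, function(r) r$normalized_map$values))
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2L, x_mean)
  spread <- max(abs(Xc)) +
    max(vapply(vels_c, function(v) max(abs(v$coefficients)), 1.0))
  if (spread < 1e-14) stop("degenerate training data: all predictors identical")
  gram <- gram_matrix(vels_c, kernel, quad_points = cp)
  eps <- if (is.null(config$epsilon)) ops$epsilon else config$epsilon
  cfg <- config
  cfg$epsilon <- eps
  sys <- build_augmented_system(gram, Xc, ops, cfg, aux)
  sol <- solve_augmented(sys, cfg)
  model <- structure(list(
    cG = sol$cG, cF = sol$cF, v_mean = v_mean,
    x_mean = vertex_function(x_mean, ops$mesh),
    gram = gram, kernel = kernel, config = cfg, classes = aux$classes,
    labels = labels, ops_epsilon = eps, s = s,
    iterations = sol$iterations), class = "flda_model")
  train_scores <- vapply(reps, function(r) score_flda(model, r, ops), 1.0)
  model$threshold <- tryCatch(
    choose_threshold(train_scores, labels),
    error = function(e) NA_real_)
  model$train_scores <- train_scores
  model
}

#' @exportS3Method base::print
print.flda_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<flda_model> n = %d, s = %d, lambda1 = %.3g, lambda2 = %.3g, ",
    "epsilon = %.3g\n  classes: %s vs %s; threshold = %.4g\n"),
    length(x$cG), x$s, x$config$lambda1, x$config$lambda2,
    x$config$epsilon, as.character(x$classes[1L]),
    as.character(x$classes[2L]), x$threshold))
  invisible(x)
}

#' Discriminant score of a new subject
#'
#' \eqn{\langle v^* - \bar v, \beta^G \rangle + \langle x^* - \bar x,
#' \beta^F \rangle}: the geometric term is the quadrature Gram row of the
#' centered new field against the centered training fields times the
#' representer coefficients; the map term is the mass-weighted inner
#' product with the finite-element coefficients of the map direction.
#' Scores above the threshold predict the second class.
#'
#' @param model a \code{flda_model}.
#' @param rep a \code{linear_representation} on the training template.
#' @param ops \code{fem_operators} of the template.
#' @return scalar score.
#' @export
score_flda <- function(model, rep, ops) {
  if (length(rep$normalized_map$values) != model$s)
    stop("representation is not on the training template")
  v_c <- combine_velocity(rep$velocity, model$v_mean, 1, -1)
  geo <- sum(gram_row(model$gram, v_c) * model$cG)
  xc <- rep$normalized_map$values - model$x_mean$values
  geo + as.numeric(xc %*% (ops$mass %*% model$cF))
}

#' @rdname score_flda
#' @param object a \code{flda_model}.
#' @param newdata list of \code{linear_representation}s.
#' @param type \code{"score"} or \code{"label"}.
#' @param ... unused.
#' @export
predict.flda_model <- function(object, newdata, ops, type = c("score", "label"),
                               ...) {
  type <- match.arg(type)
  sc <- vapply(newdata, function(r) score_flda(object, r, ops), 1.0)
  if (type == "score") return(sc)
  object$classes[ifelse(sc > object$threshold, 2L, 1L)]
}

#' Choose a score threshold
#'
#' Default criterion is Youden's J (sensitivity + specificity - 1), with
#' the second sorted class treated as positive and predicted when the
#' score exceeds the threshold; ties are broken toward the smallest
#' threshold, and perfectly separated scores yield the midpoint of the
#' gap. The alternative picks the smallest threshold achieving a given
#' specificity.
#'
#' @param scores numeric scores.
#' @param labels two-class labels aligned with scores.
#' @param criterion \code{"youden"} or \code{"fixed_specificity"}.
#' @param q required specificity for \code{"fixed_specificity"}.
#' @return scalar threshold.
#' @export
choose_threshold <- function(scores, labels,
                             criterion = c("youden", "fixed_specificity"),
                             q = 0.9) {
  criterion <- match.arg(criterion)
  aux <- auxiliary_responses(labels)
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("no discriminating threshold: all scores equal")
  # candidates are midpoints between consecutive distinct scores, so a
  # perfectly separating threshold lands in the middle of the gap
  cand <- (u[-1L] + u[-length(u)]) / 2
  pos <- labels == aux$classes[2L]
  sens <- vapply(cand, function(c) mean(scores[pos] > c), 1.0)
  spec <- vapply(cand, function(c) mean(scores[!pos] <= c), 1.0)
  if (criterion == "youden") {
    J <- sens + spec - 1
    return(cand[which.max(J)])   # which.max takes the first = smallest
  }
  ok <- which(spec >= q)
  if (length(ok) == 0L) stop("requested specificity unattainable")
  cand[ok[1L]]
}

#' Rank-based AUC
#'
#' Mann-Whitney area under the ROC curve: the probability that a random
#' score from the second sorted class exceeds one from the first, with
#' ties counted one half.
#'
#' @param scores numeric scores.
#' @param labels two-class labels aligned with scores.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  aux <- auxiliary_responses(labels)
  pos <- labels == aux$classes[2L]
  r <- rank(scores)
  (sum(r[pos]) - aux$n2 * (aux$n2 + 1) / 2) / (aux$n1 * aux$n2)
}

#' Select penalties on a validation set
#'
#' Fits the discriminant model on the training data for every grid point
#' and returns the configuration maximizing the validation AUC, together
#' with the full audit table. AUC ties break toward larger penalties
#' (larger lambda2, then lambda1), favoring smoother estimates.
#'
#' @param train,validation lists with elements \code{labels} and
#'   \code{reps}.
#' @param grid data.frame with columns \code{lambda1}, \code{lambda2}.
#' @param epsilon shrinkage weight fixed across the grid (\code{NULL}:
#'   inherit from \code{ops}).
#' @param kernel shared \code{kernel_spec}.
#' @param ops \code{fem_operators} of the template.
#' @param config base \code{fit_config} supplying solver settings.
#' @return list with \code{best} (a \code{fit_config}), \code{table}
#'   (grid with validation AUC), \code{model} (refit at the best point).
#' @export
select_lambdas <- function(train, validation, grid, epsilon = NULL,
                           kernel, ops, config = fit_config()) {
  if (nrow(grid) == 0L) stop("empty grid")
  aucs <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cfg <- config
    cfg$lambda1 <- grid$lambda1[k]
    cfg$lambda2 <- grid$lambda2[k]
    cfg$epsilon <- epsilon
    m <- fit_flda(train$labels, train$reps, ops, kernel, cfg)
    sc <- predict(m, validation$reps, ops)
    aucs[k] <- rank_auc(sc, validation$labels)
  }
  tab <- cbind(grid, auc = aucs)
  ord <- order(-aucs, -grid$lambda2, -grid$lambda1)
  best_idx <- ord[1L]
  best <- config
  best$lambda1 <- grid$lambda1[best_idx]
  best$lambda2 <- grid$lambda2[best_idx]
  best$epsilon <- epsilon
  model <- fit_flda(train$labels, train$reps, ops, kernel, best)
  list(best = best, table = tab, model = model)
}
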