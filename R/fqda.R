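#' Fit the approximate functional quadratic discriminant model
#'
#' Estimates two class-specific penalized directions: beta1 minimizes
#' \eqn{(1/n_1)\sum_{g_i=1}(1 - \langle x_i, \beta_1\rangle)^2 +
#' \lambda_1 J(\beta_1)} and beta2 minimizes the analogous objective with
#' \eqn{(1 + \langle x_i, \beta_2\rangle)^2} over the second class. Each
#' fit reuses the sparse augmented least-squares machinery
#' (single-predictor specialization). The training maps are then projected
#' to \eqn{u_i = (\langle x_i, \beta_1\rangle, \langle x_i,
#' \beta_2\rangle)} and a two-class Gaussian quadratic rule (per-class 2-D
#' means and covariances, priors from training frequencies) is fitted on
#' the projections. This quadratic step is what lets the model exploit
#' differing class covariance structures.
#'
#' @param labels two-class label vector.
#' @param maps list of \code{vertex_function}s (or value vectors) on the
#'   template: the spatially normalized maps.
#' @param ops \code{fem_operators} of the template.
#' @param lambda1,lambda2 positive per-class roughness penalties.
#' @param epsilon shrinkage weight inside J (\code{NULL}: inherit from
#'   \code{ops}).
#' @param config \code{fit_config} supplying solver settings.
#' @return object of class \code{fqda_model}.
#' @export
fit_fqda <- function(labels, maps, ops, lambda1 = 1, lambda2 = 1,
                     epsilon = NULL, config = fit_config()) {
  aux <- auxiliary_responses(labels)
  if (lambda1 <= 0 || lambda2 <= 0) stop("lambda1 and lambda2 must be positive")
  s <- length(ops$lumped_mass)
  X <- do.call(rbind, lapply(maps, vf_values, s = s))
  if (nrow(X) != length(labels)) stop("labels and maps lengths differ")
  eps <- if (is.null(epsilon)) ops$epsilon else epsilon
  fit_one <- function(Xg, lambda, sign) {
    ng <- nrow(Xg)
    # objective (1/ng)||1 -+ Xg M c||^2 + lambda c'Dc as a stacked system
    M <- ops$mass
    S <- ops$stiffness
    blocks <- list(
      Matrix::Matrix(as.matrix(Xg %*% M) / sqrt(ng), sparse = TRUE),
      sqrt(lambda) * Matrix::Diagonal(x = 1 / sqrt(ops$lumped_mass)) %*% S)
    if (eps > 0)
      blocks <- c(blocks, list(sqrt(lambda * eps) * Matrix::chol(M)))
    A <- do.call(rbind, blocks)
    rhs <- c(rep(sign / sqrt(ng), ng), numeric(nrow(A) - ng))
    itnlim <- if (is.null(config$max_iter)) 10L * s else config$max_iter
    res <- lsqr(A, rhs, atol = config$tol, itnlim = itnlim)
    if (!res$converged)
      warning(sprintf("LSQR hit the iteration cap (%d)", res$itn))
    res$x
  }
  g1 <- labels == aux$classes[1L]
  cF1 <- fit_one(X[g1, , drop = FALSE], lambda1, +1)
  cF2 <- fit_one(X[!g1, , drop = FALSE], lambda2, -1)
  Mmat <- ops$mass
  U <- cbind(as.numeric(X %*% (Mmat %*% cF1)),
             as.numeric(X %*% (Mmat %*% cF2)))
  fit_gauss <- function(Ug) {
    mu <- colMeans(Ug)
    Sg <- stats::cov(Ug)
    # regularize toward a spherical floor so tiny classes stay invertible
    Sg <- Sg + diag(1e-10 * (sum(diag(Sg)) + 1e-30), 2L)
    list(mean = mu, cov = Sg)
  }
  structure(list(cF1 = cF1, cF2 = cF2, lambda1 = lambda1, lambda2 = lambda2,
                 epsilon = eps, classes = aux$classes,
                 priors = c(aux$n1, aux$n2) / (aux$n1 + aux$n2),
                 gauss = list(fit_gauss(U[g1, , drop = FALSE]),
                              fit_gauss(U[!g1, , drop = FALSE])),
                 projections = U, s = s), class = "fqda_model")
}

#' @exportS3Method base::print
print.fqda_model <- function(x, ...) {
  cat(sprintf(paste0("<fqda_model> s = %d, lambda1 = %.3g, lambda2 = %.3g; ",
                     "classes %s vs %s\n"),
              x$s, x$lambda1, x$lambda2, as.character(x$classes[1L]),
              as.character(x$classes[2L])))
  invisible(x)
}

# log Gaussian discriminant score of 2-D points for one class component.
gauss_log_density <- function(U, comp, prior) {
  d <- sweep(U, 2L, comp$mean)
  Si <- solve(comp$cov)
  -0.5 * rowSums((d %*% Si) * d) - 0.5 * log(det(comp$cov)) + log(prior)
}

#' Classify maps with a fitted quadratic discriminant model
#'
#' Projects each map along the two estimated directions and assigns the
#' class with the larger Gaussian quadratic discriminant score in the 2-D
#' projected space.
#'
#' @param model a \code{fqda_model}.
#' @param maps list of \code{vertex_function}s or value vectors on the
#'   template (a single map may be given directly).
#' @param ops \code{fem_operators} of the template.
#' @return list with \code{label} (predicted classes), \code{projection}
#'   (n x 2 matrix), \code{score} (log-density difference, class 2 minus
#'   class 1; usable for ROC analysis).
#' @export
classify_fqda <- function(model, maps, ops) {
  if (inherits(maps, "vertex_function") || is.numeric(maps))
    maps <- list(maps)
  X <- do.call(rbind, lapply(maps, vf_values, s = model$s))
  M <- ops$mass
  U <- cbind(as.numeric(X %*% (M %*% model$cF1)),
             as.numeric(X %*% (M %*% model$cF2)))
  if (!all(is.finite(U))) stop("non-finite projection")
  s1 <- gauss_log_density(U, model$gauss[[1L]], model$priors[1L])
  s2 <- gauss_log_density(U, model$gauss[[2L]], model$priors[2L])
  list(label = model$classes[ifelse(s2 > s1, 2L, 1L)],
       projection = U, score = s2 - s1)
}
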