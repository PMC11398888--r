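test_that("auxiliary responses implement the two-class coding exactly", {
  a <- auxiliary_responses(c(1, 1, 2, 2))
  expect_equal(a$y, c(-2, -2, 2, 2))
  b <- auxiliary_responses(c(1, 2, 2, 2))
  expect_equal(b$y, c(-4, 4 / 3, 4 / 3, 4 / 3))
  withr::with_seed(3, {
    for (k in 1:10) {
      lab <- sample(c("a", "b"), 30, replace = TRUE)
      if (length(unique(lab)) < 2L) next
      expect_lt(abs(sum(auxiliary_responses(lab)$y)), 1e-10 * 30)
    }
  })
  expect_error(auxiliary_responses(rep(1, 5)), "two classes")
})

test_that("the Gram matrix matches hand-computable kernel sums", {
  k <- kernel_spec(0.8)
  p <- rbind(c(0, 0, 0))
  withr::with_seed(8, {
    cp <- matrix(rnorm(9), 3, 3)
    v1 <- velocity_field(cp, matrix(rnorm(9), 3, 3), k)
    v2 <- velocity_field(cp, matrix(rnorm(9), 3, 3), k)
    g <- gram_matrix(list(v1, v2), k, p)
    expect_equal(g$sigma[1L, 2L],
                 sum(eval_velocity(v1, p) * eval_velocity(v2, p)),
                 tolerance = 1e-12)
    vz <- velocity_field(cp, matrix(0, 3, 3), k)
    g0 <- gram_matrix(list(v1, vz), k, p)
    expect_identical(g0$sigma[2L, ], c(0, 0))
    expect_identical(g0$sigma[, 2L], c(0, 0))
  })
  # two quad points at distance d, fields constant u and w on the quad set:
  # Sigma_12 = u'w (2 + 2 exp(-d^2/sigma^2))
  d <- 1.3
  q2 <- rbind(c(0, 0, 0), c(d, 0, 0))
  u <- c(0.3, -0.2, 0.5)
  w <- c(-1, 0.4, 0.2)
  mkconst <- function(val) {
    K <- exp(-as.matrix(dist(q2))^2 / 0.8^2)
    velocity_field(q2, solve(K, rbind(val, val)), kernel_spec(0.8))
  }
  g2 <- gram_matrix(list(mkconst(u), mkconst(w)), kernel_spec(0.8), q2)
  expect_equal(g2$sigma[1L, 2L], sum(u * w) * (2 + 2 * exp(-d^2 / 0.8^2)),
               tolerance = 1e-10)
  expect_error(gram_matrix(list(mkconst(u)), kernel_spec(0.5), q2), "kernel")
})

test_that("the augmented system has the documented block structure", {
  withr::with_seed(19, {
    mesh <- make_template(1)
    s <- 42L; n <- 10L
    ops <- assemble_penalty(mesh, 0.02)
    k <- default_kernel(mesh)
    cp <- default_control_points(mesh, 8L)
    vels <- lapply(1:n, function(i)
      velocity_field(cp, matrix(rnorm(24), 8, 3) * 0.1, k))
    gram <- gram_matrix(vels, k, cp)
    X <- matrix(rnorm(n * s), n, s)
    y <- auxiliary_responses(rep(1:2, each = 5L))
    cfg <- fit_config(lambda1 = 0.3, lambda2 = 0.05)
    sys <- build_augmented_system(gram, X, ops, cfg, y)
    expect_identical(dim(sys$A), c(n + 2L * s + n, n + s))
    expect_identical(sys$rhs, c(y$y, numeric(2L * s + n)))
    # analytic normal-equation blocks
    D <- as.matrix(ops$stiffness %*% diag(1 / ops$lumped_mass) %*%
                     ops$stiffness) + 0.02 * as.matrix(ops$mass)
    XM <- X %*% as.matrix(ops$mass)
    Sg <- gram$sigma
    jit <- 1e-10 * sum(diag(Sg)) / n
    H <- rbind(cbind(Sg %*% Sg + 0.3 * (Sg + jit * diag(n)), Sg %*% XM),
               cbind(t(XM) %*% Sg, t(XM) %*% XM + 0.05 * D))
    expect_lt(max(abs(as.matrix(Matrix::crossprod(sys$A)) - H)),
              1e-10 * max(abs(H)))
    # epsilon = 0 drops the shrinkage block
    cfg0 <- fit_config(lambda1 = 0.3, lambda2 = 0.05, epsilon = 0)
    sys0 <- build_augmented_system(gram, X, ops, cfg0, y)
    expect_identical(nrow(sys0$A), n + s + n)
    expect_error(fit_config(lambda1 = -1), "positive")
  })
})

test_that("LSQR agrees with dense normal-equation solves and shrinks under huge penalties", {
  withr::with_seed(29, {
    mesh <- make_template(1)
    s <- 42L; n <- 12L
    ops <- assemble_penalty(mesh, 0.02)
    k <- default_kernel(mesh)
    cp <- default_control_points(mesh, 8L)
    vels <- lapply(1:n, function(i)
      velocity_field(cp, matrix(rnorm(24), 8, 3) * 0.1, k))
    gram <- gram_matrix(vels, k, cp)
    X <- matrix(rnorm(n * s), n, s)
    y <- auxiliary_responses(rep(1:2, each = 6L))
    cfg <- fit_config(lambda1 = 0.7, lambda2 = 0.1)
    sys <- build_augmented_system(gram, X, ops, cfg, y)
    sol <- solve_augmented(sys, cfg)
    dense <- dense_flda_solution(gram$sigma, X, ops, 0.7, 0.1, 0.02, y$y)
    expect_lt(sqrt(sum((c(sol$cG, sol$cF) - dense)^2) / sum(dense^2)), 1e-6)
    # objective optimality under random perturbations
    obj <- function(cG, cF) {
      D <- as.matrix(ops$stiffness %*% diag(1 / ops$lumped_mass) %*%
                       ops$stiffness) + 0.02 * as.matrix(ops$mass)
      r <- y$y - gram$sigma %*% cG - X %*% as.matrix(ops$mass) %*% cF
      sum(r^2) + 0.7 * sum(cG * (gram$sigma %*% cG)) +
        0.1 * sum(cF * (D %*% cF))
    }
    o0 <- obj(sol$cG, sol$cF)
    for (t in 1:50) {
      dG <- rnorm(n) * 1e-3
      dF <- rnorm(s) * 1e-3
      expect_gte(obj(sol$cG + dG, sol$cF + dF), o0 - 1e-10 * abs(o0))
    }
    # penalty domination
    cfg_big <- fit_config(lambda1 = 1e6, lambda2 = 1e6)
    big <- solve_augmented(build_augmented_system(gram, X, ops, cfg_big, y),
                           cfg_big)
    expect_lt(sqrt(sum(big$cG^2)), 1e-4 * sqrt(sum(sol$cG^2)))
    expect_lt(sqrt(sum(big$cF^2)), 1e-4 * sqrt(sum(sol$cF^2)))
  })
})

test_that("fitting is equivariant under subject reordering", {
  withr::with_seed(31, {
    sc <- maps_scenario(8L, seed = 2, level = 1L, noise_k = 20L)
    ds <- simulate_dataset(sc)
    cfg <- fit_config(lambda1 = 1, lambda2 = 0.01, epsilon = ds$ops$epsilon)
    m1 <- fit_flda(ds$labels, ds$reps, ds$ops, ds$kernel, cfg)
    perm <- sample(length(ds$labels))
    m2 <- fit_flda(ds$labels[perm], ds$reps[perm], ds$ops, ds$kernel, cfg)
    expect_equal(m2$cG, m1$cG[perm], tolerance = 1e-6)
    expect_equal(m2$cF, m1$cF, tolerance = 1e-6)
  })
})

test_that("the univariate special case solves the map-only normal equations", {
  withr::with_seed(37, {
    sc <- maps_scenario(10L, seed = 3, level = 1L, noise_k = 20L)
    ds <- simulate_dataset(sc)
    cfg <- fit_config(lambda1 = 1, lambda2 = 0.05, epsilon = ds$ops$epsilon)
    model <- fit_flda(ds$labels, ds$reps, ds$ops, ds$kernel, cfg)
    # all velocities are zero fields here: cF must solve
    # (M X'X M + lambda2 D) c = M X' y on the centered maps
    X <- do.call(rbind, lapply(ds$reps, function(r) r$normalized_map$values))
    Xc <- scale(X, scale = FALSE)
    y <- auxiliary_responses(ds$labels)$y
    M <- as.matrix(ds$ops$mass)
    D <- as.matrix(ds$ops$penalty)
    cF <- solve(M %*% t(Xc) %*% Xc %*% M + 0.05 * D, M %*% t(Xc) %*% y)
    expect_lt(sqrt(sum((model$cF - cF)^2) / sum(cF^2)), 1e-5)
    expect_lt(max(abs(model$cG)), 1e-8 * max(1, max(abs(cF))))
  })
})

test_that("the fitted map direction points toward the generating contrast", {
  signs <- sapply(1:10, function(rep) {
    sc <- maps_scenario(15L, seed = 40 + rep)
    ds <- simulate_dataset(sc)
    model <- fit_flda(ds$labels, ds$reps, ds$ops, ds$kernel,
                      fit_config(lambda1 = 1, lambda2 = 1e-3,
                                 epsilon = ds$ops$epsilon))
    sign(inner_product_l2(ds$ops, model$cF, ds$ground_truth$contrast$values))
  })
  expect_true(all(signs == 1))
})

test_that("doubling the penalties never increases the fitted roughness", {
  withr::with_seed(41, {
    sc <- maps_scenario(12L, seed = 6, level = 1L, noise_k = 20L)
    ds <- simulate_dataset(sc)
    D <- as.matrix(ds$ops$penalty)
    rough <- sapply(c(0.01, 0.02, 0.04), function(l2) {
      m <- fit_flda(ds$labels, ds$reps, ds$ops, ds$kernel,
                    fit_config(lambda1 = l2 * 100, lambda2 = l2,
                               epsilon = ds$ops$epsilon))
      sum(m$cF * (D %*% m$cF))
    })
    expect_true(all(diff(rough) <= 1e-10 * rough[1L]))
  })
})

test_that("scores center at the training mean and respect component structure", {
  withr::with_seed(43, {
    sc <- simulation_scenario(level = 1L, n_per_class = 8L, noise_k = 20L,
                              geom_control_m = 12L, seed = 7)
    ds <- simulate_dataset(sc)
    model <- fit_flda(ds$labels, ds$reps, ds$ops, ds$kernel,
                      fit_config(lambda1 = 1, lambda2 = 0.01,
                                 epsilon = ds$ops$epsilon))
    mean_rep <- linear_representation(model$v_mean, model$x_mean)
    expect_lt(abs(score_flda(model, mean_rep, ds$ops)), 1e-8)
    # a model with cG forced to zero scores by the map term alone
    m0 <- model
    m0$cG <- rep(0, length(m0$cG))
    r <- ds$reps[[3L]]
    xc <- r$normalized_map$values - model$x_mean$values
    expect_equal(score_flda(m0, r, ds$ops),
                 as.numeric(xc %*% (as.matrix(ds$ops$mass) %*% model$cF)),
                 tolerance = 1e-10)
    # centering invariance: shifting every map by a constant leaves scores
    # unchanged after refitting
    reps_shift <- lapply(ds$reps, function(rp) linear_representation(
      rp$velocity,
      vertex_function(rp$normalized_map$values + 3.7, ds$template)))
    m_shift <- fit_flda(ds$labels, reps_shift, ds$ops, ds$kernel,
                        fit_config(lambda1 = 1, lambda2 = 0.01,
                                   epsilon = ds$ops$epsilon))
    s1 <- predict(model, ds$reps, ds$ops)
    s2 <- predict(m_shift, reps_shift, ds$ops)
    expect_equal(s1, s2, tolerance = 1e-6)
  })
})

test_that("held-out scores separate the classes in a strong-effect scenario", {
  sc <- maps_scenario(20L, seed = 9, delta = 1.5)
  ds <- simulate_dataset(sc)
  te <- simulate_dataset(maps_scenario(20L, seed = 1009, delta = 1.5),
                         cache = scenario_cache(sc))
  model <- fit_flda(ds$labels, ds$reps, ds$ops, ds$kernel,
                    fit_config(lambda1 = 1, lambda2 = 1e-3,
                               epsilon = ds$ops$epsilon))
  scs <- predict(model, te$reps, ds$ops)
  expect_gt(mean(scs[te$labels == 2L]), mean(scs[te$labels == 1L]))
})

test_that("threshold selection handles separation, ties, and symmetry", {
  scores <- c(-3, -2, -1, 1, 2, 3)
  labels <- rep(1:2, each = 3L)
  expect_equal(choose_threshold(scores, labels), 0)
  expect_error(choose_threshold(rep(1, 6), labels), "no discriminating")
  s2 <- c(-2, -1, 0, 0.5, 1, 3)
  l2 <- c(1, 1, 2, 1, 2, 2)
  th <- choose_threshold(s2, l2)
  J <- function(th, sc, lb) {
    mean(sc[lb == 2] > th) + mean(sc[lb == 1] <= th) - 1
  }
  swapped <- ifelse(l2 == 1, 2, 1)
  th_sw <- choose_threshold(-s2, swapped)
  expect_equal(J(th, s2, l2), J(th_sw, -s2, swapped), tolerance = 1e-12)
  # fixed specificity: smallest candidate threshold achieving it
  th_sp <- choose_threshold(s2, l2, "fixed_specificity", q = 1)
  expect_gte(mean(s2[l2 == 1] <= th_sp), 1)
  expect_equal(th_sp, 0.75)   # first midpoint above every class-1 score
})

test_that("rank AUC matches its definition, symmetry, and an external oracle", {
  expect_equal(rank_auc(c(1, 2, 3, 4), c(1, 1, 2, 2)), 1)
  withr::with_seed(47, {
    scores <- rnorm(200)
    labels <- rep(1:2, 100)
    a <- rank_auc(scores, labels)
    expect_equal(rank_auc(-scores, labels), 1 - a, tolerance = 1e-12)
    expect_lt(abs(a - 0.5), 0.1)
    # permutation oracle: null distribution centered at 1/2
    perm <- replicate(200, rank_auc(scores, sample(labels)))
    expect_lt(abs(mean(perm) - 0.5), 0.02)
    if (requireNamespace("pROC", quietly = TRUE)) {
      scores2 <- rnorm(80) + rep(c(0, 1), 40)
      labels2 <- rep(1:2, 40)
      expect_equal(rank_auc(scores2, labels2),
                   as.numeric(pROC::auc(pROC::roc(labels2, scores2,
                                                  quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  })
  expect_error(rank_auc(1:5, rep(1, 5)), "two classes")
})

test_that("lambda selection returns the audit table and favors smoothing on smooth truths", {
  grid1 <- data.frame(lambda1 = 1, lambda2 = 0.01)
  sc <- maps_scenario(10L, seed = 21, level = 1L, noise_k = 20L)
  ds <- simulate_dataset(sc)
  va <- simulate_dataset(maps_scenario(10L, seed = 1021, level = 1L,
                                       noise_k = 20L),
                         cache = scenario_cache(sc))
  train <- list(labels = ds$labels, reps = ds$reps)
  valid <- list(labels = va$labels, reps = va$reps)
  one <- select_lambdas(train, valid, grid1, epsilon = ds$ops$epsilon,
                        kernel = ds$kernel, ops = ds$ops)
  expect_equal(one$best$lambda2, 0.01)
  expect_identical(nrow(one$table), 1L)
  grid <- expand.grid(lambda1 = 1, lambda2 = 10^seq(-6, 0, by = 2))
  sel <- select_lambdas(train, valid, grid, epsilon = ds$ops$epsilon,
                        kernel = ds$kernel, ops = ds$ops)
  expect_identical(nrow(sel$table), nrow(grid))
  expect_true(all(sel$table$auc >= 0 & sel$table$auc <= 1))
  # smooth generating contrast in a weak-signal, small-n regime:
  # the winner is not the roughest grid point
  grid2 <- expand.grid(lambda1 = 1, lambda2 = 10^seq(-8, 0, by = 2))
  mk <- function(seed) maps_scenario(10L, seed = seed, delta = 0.3,
                                     noise_amp = 1.5)
  cache2 <- scenario_cache(mk(1))
  picks <- sapply(1:8, function(rep) {
    tr <- simulate_dataset(mk(300 + rep), cache2)
    vl <- simulate_dataset(mk(700 + rep), cache2)
    s <- select_lambdas(list(labels = tr$labels, reps = tr$reps),
                        list(labels = vl$labels, reps = vl$reps),
                        grid2, epsilon = tr$ops$epsilon, kernel = tr$kernel,
                        ops = tr$ops)
    s$best$lambda2
  })
  expect_gt(median(picks), min(grid2$lambda2))
})
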