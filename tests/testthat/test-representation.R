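test_that("GPA removes rigid motion and scale from corresponded meshes", {
  withr::with_seed(5, {
    m <- make_template(1)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    m2 <- fos_mesh(m$vertices %*% R * 2.5 +
                     matrix(c(1, -2, 3), n_vertices(m), 3, byrow = TRUE),
                   m$faces)
    al <- gpa_align(list(m, m2))
    expect_lt(sqrt(mean(rowSums(
      (al$aligned[[1L]]$vertices - al$aligned[[2L]]$vertices)^2))), 1e-8)
    for (a in al$aligned) {
      expect_lt(max(abs(colMeans(a$vertices))), 1e-10)
      expect_equal(sum(a$vertices^2), 1, tolerance = 1e-10)
    }
    expect_identical(al$template$faces, m$faces)
  })
})

test_that("GPA pairwise alignment attains the orthogonal Procrustes optimum", {
  withr::with_seed(6, {
    m <- make_template(1)
    X <- m$vertices + matrix(rnorm(3 * nrow(m$vertices)), ncol = 3) * 0.02
    Y <- m$vertices + matrix(rnorm(3 * nrow(m$vertices)), ncol = 3) * 0.02
    norm_conf <- function(Z) {
      Z <- scale(Z, scale = FALSE)
      Z / sqrt(sum(Z^2))
    }
    Xn <- norm_conf(X)
    Yn <- norm_conf(Y)
    sv <- svd(crossprod(Yn, Xn))       # closed-form oracle rotation
    Ropt <- sv$u %*% t(sv$v)
    if (det(Ropt) < 0) {
      u <- sv$u; u[, 3L] <- -u[, 3L]; Ropt <- u %*% t(sv$v)
    }
    oracle <- sqrt(sum((Xn - Yn %*% Ropt)^2))
    al <- gpa_align(list(fos_mesh(X, m$faces, check = FALSE),
                         fos_mesh(Y, m$faces, check = FALSE)))
    ours <- sqrt(sum((al$aligned[[1L]]$vertices - al$aligned[[2L]]$vertices)^2))
    expect_lt(abs(ours - oracle), 1e-8)
    if (requireNamespace("vegan", quietly = TRUE)) {
      pr <- vegan::procrustes(Xn, Yn, scale = FALSE, symmetric = FALSE)
      expect_lt(max(abs(pr$rotation - Ropt)), 1e-8)
    }
  })
})

test_that("a single mesh aligns to its own normalization", {
  m <- make_template(1)
  al <- gpa_align(list(m))
  expect_lt(max(abs(colMeans(al$template$vertices))), 1e-12)
  expect_equal(sum(al$template$vertices^2), 1, tolerance = 1e-12)
  expect_identical(al$aligned[[1L]]$vertices, al$template$vertices)
  expect_error(gpa_align(list(m, make_template(2))), "vertex count")
})

test_that("deform_mesh reduces to identity and translation in limit cases", {
  m <- make_template(1)
  k <- default_kernel(m)
  cp <- default_control_points(m, 10L)
  vzero <- velocity_field(cp, matrix(0, 10, 3), k)
  for (st in c(1L, 4L))
    expect_identical(deform_mesh(m, vzero, st)$vertices, m$vertices)
  d <- deform_mesh(m, c(0.1, -0.2, 0.3), 1L)
  expect_equal(d$vertices,
               sweep(m$vertices, 2L, c(0.1, -0.2, 0.3), "+"),
               tolerance = 1e-15)
  expect_identical(d$faces, m$faces)
})

test_that("small smooth deformations keep topology and orientation", {
  withr::with_seed(9, {
    m <- make_template(2)
    k <- default_kernel(m)
    cp <- default_control_points(m, 16L)
    v <- velocity_field(cp, matrix(rnorm(48), 16, 3) * 0.03, k)
    flips <- sapply(c(1L, 2L, 4L, 8L), function(st) {
      d <- deform_mesh(m, v, st)
      expect_identical(euler_characteristic(d), 2L)
      attr(d, "flipped_fraction")
    })
    expect_true(all(flips == 0))
    expect_true(all(diff(flips) <= 0))
  })
})

test_that("velocity estimation recovers matching in the ridge limit", {
  withr::with_seed(13, {
    m <- make_template(1)
    k <- default_kernel(m)
    cp <- default_control_points(m, 16L)
    v <- velocity_field(cp, matrix(rnorm(48), 16, 3) * 0.02, k)
    target <- deform_mesh(m, v, 1L)
    # control points = template vertices: must match the dense ridge
    # closed form (K + gamma I) alpha = Q - Xi
    fit <- estimate_velocity(m, target, k, control_points = m$vertices,
                             gamma = 1e-8, steps = 1L)
    K <- exp(-as.matrix(dist(m$vertices))^2 / k$sigma^2)
    alpha <- solve(K + 1e-8 * diag(nrow(K)),
                   target$vertices - m$vertices)
    expect_lt(max(abs(fit$coefficients - alpha)), 1e-6 * max(abs(alpha)))
    disp <- sqrt(mean(rowSums((target$vertices - m$vertices)^2)))
    ph <- deform_mesh(m, fit, 1L)
    expect_lt(max(sqrt(rowSums((ph$vertices - target$vertices)^2))),
              1e-4 * disp)
  })
})

test_that("velocity estimation is optimal, monotone, and validates input", {
  withr::with_seed(14, {
    m <- make_template(1)
    k <- default_kernel(m)
    cp <- default_control_points(m, 12L)
    v <- velocity_field(cp, matrix(rnorm(36), 12, 3) * 0.05, k)
    target <- deform_mesh(m, v, 8L)
    fit0 <- estimate_velocity(m, m, k, control_points = cp, gamma = 1e-4,
                              steps = 1L)
    expect_lt(max(abs(fit0$coefficients)), 1e-10)
    fit <- estimate_velocity(m, target, k, control_points = cp,
                             gamma = 1e-6, steps = 8L)
    zero_resid <- sum(sqrt(rowSums((target$vertices - m$vertices)^2)))
    expect_lt(attr(fit, "residual_sum"), zero_resid)
    trace <- attr(fit, "objective_trace")
    expect_true(all(diff(trace) <= 1e-12 * max(trace)))
    expect_error(estimate_velocity(m, target, k, gamma = 0), "gamma")
  })
})

test_that("pullback is an index map and round trips through reconstruction", {
  withr::with_seed(15, {
    sc <- simulation_scenario(level = 1L, n_per_class = 2L, noise_k = 20L,
                              geom_control_m = 12L, seed = 2)
    ds <- simulate_dataset(sc)
    subj <- ds$fos[[1L]]
    x <- pullback_map(subj, ds$template)
    expect_identical(x$values, subj$map$values)
    const <- fos(subj$geometry, rep(2.5, n_vertices(subj$geometry)))
    expect_identical(unique(pullback_map(const, ds$template)$values), 2.5)
    rec <- reconstruct_fos(ds$template, ds$reps[[1L]], steps = sc$steps)
    expect_identical(rec$map$values, ds$reps[[1L]]$normalized_map$values)
    expect_lt(max(abs(rec$geometry$vertices - subj$geometry$vertices)), 1e-12)
    expect_error(pullback_map(subj, make_template(2L)), "vertex count")
  })
})

test_that("reconstruction error is bounded by the fitted matching residual", {
  withr::with_seed(16, {
    sc <- simulation_scenario(level = 1L, n_per_class = 2L, noise_k = 20L,
                              geom_control_m = 12L, seed = 5)
    ds <- simulate_dataset(sc)
    cp <- ds$reps[[1L]]$velocity$control_points
    for (i in c(1L, 3L)) {
      target <- ds$fos[[i]]$geometry
      v <- estimate_velocity(ds$template, target, ds$kernel,
                             control_points = cp, gamma = 1e-8,
                             steps = sc$steps)
      rec <- reconstruct_fos(ds$template,
                             linear_representation(v, ds$reps[[i]]$normalized_map),
                             steps = sc$steps)
      rms <- sqrt(mean(rowSums((rec$geometry$vertices - target$vertices)^2)))
      expect_lte(rms, attr(v, "residual_rms") + 1e-10)
    }
  })
})

test_that("trajectories are linear in the map coordinate and safe near zero", {
  withr::with_seed(17, {
    m <- make_template(1)
    k <- default_kernel(m)
    cp <- default_control_points(m, 10L)
    vbar <- velocity_field(cp, matrix(rnorm(30), 10, 3) * 0.02, k)
    bG <- velocity_field(cp, matrix(rnorm(30), 10, 3) * 0.02, k)
    bF <- vertex_function(rnorm(n_vertices(m)), m)
    t0 <- fos_trajectory(m, vbar, bG, bF, 0, 0, steps = 4L)
    expect_identical(t0$map$values, rep(0, n_vertices(m)))
    expect_equal(t0$geometry$vertices, deform_mesh(m, vbar, 4L)$vertices)
    tp <- fos_trajectory(m, vbar, bG, bF, 0.5, 2, steps = 4L)
    tm <- fos_trajectory(m, vbar, bG, bF, 0.5, -2, steps = 4L)
    expect_identical(tp$map$values, -tm$map$values)
    expect_identical(tp$geometry$vertices, tm$geometry$vertices)
    for (c1 in c(-0.5, 0.5)) {
      tr <- fos_trajectory(m, vbar, bG, bF, c1, 1, steps = 4L)
      expect_identical(attr(tr, "flipped_fraction"), 0)
      expect_identical(euler_characteristic(tr$geometry), 2L)
    }
    other <- velocity_field(cp, matrix(0, 10, 3), kernel_spec(99))
    expect_error(fos_trajectory(m, vbar, other, bF, 1, 1), "kernel")
  })
})
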