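# Shared fixtures: tiny meshes, quadrature oracles, scenario shorthands.

single_triangle <- function(p1 = c(0, 0, 0), p2 = c(1, 0, 0), p3 = c(0, 1, 0)) {
  fos_mesh(rbind(p1, p2, p3), rbind(c(0L, 1L, 2L)))
}

# Independent quadrature oracle on one triangle: the 3-point edge-midpoint
# rule integrates quadratics exactly, which covers products of affine basis
# functions; gradients are constant so the same rule is exact for the
# stiffness integrand.
tri_quadrature_blocks <- function(p1, p2, p3) {
  P <- rbind(p1, p2, p3)
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  area <- sqrt(sum(cr^2)) / 2
  mids <- rbind((c(1, 1, 0)) / 2, (c(0, 1, 1)) / 2, (c(1, 0, 1)) / 2)
  # barycentric values of the three hat functions at the midpoints
  Mloc <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    Mloc[a, b] <- (area / 3) * sum(mids[, a] * mids[, b])
  # constant gradients from the affine system
  Tm <- cbind(e1, e2)
  G <- matrix(0, 3, 3)          # gradients in barycentric-derivative form
  # hat gradients: solve in the triangle plane using the metric
  g <- solve(crossprod(Tm), t(Tm))            # 2 x 3, rows: d/du, d/dv
  grads <- rbind(-(g[1, ] + g[2, ]), g[1, ], g[2, ])  # 3 x 3 ambient
  Sloc <- area * grads %*% t(grads)
  list(mass = Mloc, stiffness = Sloc, area = area)
}

# Small randomly deformed icosphere that stays a valid closed mesh.
random_valid_mesh <- function(level = 1, magnitude = 0.05, seed = 1) {
  withr::with_seed(seed, {
    m <- make_template(level)
    k <- default_kernel(m)
    cp <- default_control_points(m, 16L)
    v <- velocity_field(cp, matrix(stats::rnorm(48), 16, 3) * magnitude, k)
    deform_mesh(m, v, steps = 4L)
  })
}

# Maps-only scenario (no geometric variation) used across discriminant
# tests; geometry control points kept tiny so the Gram block is cheap.
maps_scenario <- function(n_per_class, seed, level = 2L, delta = 0.5,
                          bump_width = 1.0, noise_amp = 1, decay = 2,
                          contrast_mode = "bump", noise_k = 40L) {
  simulation_scenario(level = level, n_per_class = n_per_class,
                      delta = delta, bump_width = bump_width,
                      noise_amp = noise_amp, decay = decay,
                      contrast_mode = contrast_mode, noise_k = noise_k,
                      geom_amplitude = 0, geom_noise = 0,
                      geom_control_m = 12L, seed = seed)
}

# Dense solution of the penalized normal equations the augmented system
# represents; the oracle for the iterative solver.
dense_flda_solution <- function(sigma, X, ops, lambda1, lambda2, epsilon, y,
                                jitter = TRUE) {
  n <- nrow(sigma)
  M <- as.matrix(ops$mass)
  S <- as.matrix(ops$stiffness)
  D <- S %*% diag(1 / ops$lumped_mass) %*% S + epsilon * M
  XM <- X %*% M
  Sig <- sigma
  if (jitter && sum(diag(Sig)) > 0)
    Sig <- Sig + diag(1e-10 * sum(diag(sigma)) / n, n)
  H <- rbind(cbind(sigma %*% sigma + lambda1 * Sig, sigma %*% XM),
             cbind(t(XM) %*% sigma, t(XM) %*% XM + lambda2 * D))
  g <- c(sigma %*% y, t(XM) %*% y)
  solve(H, g)
}

cosine_m <- function(ops, f, g) {
  inner_product_l2(ops, f, g) /
    sqrt(inner_product_l2(ops, f, f) * inner_product_l2(ops, g, g))
}
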