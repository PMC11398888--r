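# LSQR (Paige & Saunders) for sparse least squares min ||b - A x||_2.
# Operates on any matrix supporting %*% and crossprod-style products via
# Matrix; never forms A'A. Convergence: ||A' r|| <= atol * ||A|| * ||r||.
lsqr <- function(A, b, atol = 1e-10, itnlim = 10L * ncol(A)) {
  m <- nrow(A)
  n <- ncol(A)
  x <- numeric(n)
  beta <- sqrt(sum(b^2))
  if (beta == 0) return(list(x = x, itn = 0L, converged = TRUE,
                             relgrad = 0))
  u <- b / beta
  v <- as.numeric(Matrix::crossprod(A, u))
  alpha <- sqrt(sum(v^2))
  if (alpha == 0) return(list(x = x, itn = 0L, converged = TRUE,
                              relgrad = 0))
  v <- v / alpha
  w <- v
  phibar <- beta
  rhobar <- alpha
  anorm <- 0
  converged <- FALSE
  itn <- 0L
  relgrad <- NA_real_
  while (itn < itnlim) {
    itn <- itn + 1L
    u <- as.numeric(A %*% v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) {
      u <- u / beta
      v <- as.numeric(Matrix::crossprod(A, u)) - beta * v
      alpha <- sqrt(sum(v^2))
      if (alpha > 0) v <- v / alpha
    }
    anorm <- sqrt(anorm^2 + alpha^2 + beta^2)
    rho <- sqrt(rhobar^2 + beta^2)
    c <- rhobar / rho
    s <- beta / rho
    theta <- s * alpha
    rhobar <- -c * alpha
    phi <- c * phibar
    phibar <- s * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    # ||A' r|| = phibar * alpha * |c|; ||r|| = phibar
    arnorm <- phibar * alpha * abs(c)
    relgrad <- arnorm / max(anorm * phibar, .Machine$double.xmin)
    if (relgrad <= atol || phibar <= atol * anorm * sqrt(sum(x^2)) ||
        phibar == 0) {
      converged <- TRUE
      break
    }
  }
  list(x = x, itn = itn, converged = converged, relgrad = relgrad)
}
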