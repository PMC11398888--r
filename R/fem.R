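#' Assemble the finite-element mass matrix
#'
#' Sparse s x s matrix of pairwise surface integrals of the linear
#' finite-element hat functions, \eqn{M_{jj'} = \int_M \psi_j \psi_{j'}}.
#' Each triangle of area A contributes (A/12) [[2,1,1],[1,2,1],[1,1,2]] to
#' its three vertices; exact for affine elements, so no quadrature rule is
#' needed. The sum of all entries equals the total surface area (partition
#' of unity).
#'
#' @param mesh a valid \code{fos_mesh}.
#' @return sparse symmetric positive-definite matrix (class
#'   \code{Matrix::dsCMatrix}), units of area.
#' @export
assemble_mass <- function(mesh) {
  validate_mesh(mesh)
  f <- mesh$faces + 1L
  a <- face_areas(mesh)
  # local (A/12) * [2 on diagonal, 1 off]: emit all 9 entries per triangle
  ii <- c(f[, 1L], f[, 2L], f[, 3L], f[, 1L], f[, 2L], f[, 1L],
          f[, 2L], f[, 3L], f[, 3L])
  jj <- c(f[, 1L], f[, 2L], f[, 3L], f[, 2L], f[, 1L], f[, 3L],
          f[, 3L], f[, 2L], f[, 1L])
  xx <- c(rep(a / 6, 3L), rep(a / 12, 6L))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = rep(n_vertices(mesh), 2L))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Assemble the finite-element stiffness matrix
#'
#' Sparse s x s matrix of pairwise integrals of tangential gradients,
#' \eqn{S_{jj'} = \int_M \nabla_M \psi_j \cdot \nabla_M \psi_{j'}}. The
#' hat-function gradients are constant per triangle, so per-triangle blocks
#' are A g_a . g_b with g_a the in-plane gradient of the basis function of
#' vertex a (equivalent to the cotangent formula). Rows sum to zero and the
#' matrix is positive semi-definite and scale invariant.
#'
#' @param mesh a valid \code{fos_mesh}.
#' @return sparse symmetric PSD matrix (dimensionless).
#' @export
assemble_stiffness <- function(mesh) {
  validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces + 1L
  geo <- face_geometry(mesh)
  a <- geo$area
  nrm <- geo$normal
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  # gradient of basis at vertex a: (n x e_a) / (2A), e_a the opposite edge
  grad_of <- function(eopp) {
    cbind(nrm[, 2L] * eopp[, 3L] - nrm[, 3L] * eopp[, 2L],
          nrm[, 3L] * eopp[, 1L] - nrm[, 1L] * eopp[, 3L],
          nrm[, 1L] * eopp[, 2L] - nrm[, 2L] * eopp[, 1L]) / (2 * a)
  }
  g1 <- grad_of(p3 - p2)
  g2 <- grad_of(p1 - p3)
  g3 <- grad_of(p2 - p1)
  gl <- list(g1, g2, g3)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (aidx in 1:3) {
    for (bidx in 1:3) {
      ii <- c(ii, f[, aidx])
      jj <- c(jj, f[, bidx])
      xx <- c(xx, a * rowSums(gl[[aidx]] * gl[[bidx]]))
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = rep(n_vertices(mesh), 2L))
  Matrix::forceSymmetric((S + Matrix::t(S)) / 2)
}

#' Lump a mass matrix to its row-sum diagonal
#'
#' Returns the diagonal vector of row sums, the sparse stand-in for the
#' dense inverse mass used inside the Laplace-Beltrami penalty. The total
#' (surface area) is preserved.
#'
#' @param mass sparse symmetric mass matrix.
#' @return numeric vector of positive diagonal entries.
#' @export
lump_mass <- function(mass) {
  d <- as.numeric(Matrix::rowSums(mass))
  if (any(d <= 0)) stop("non-positive row sum in mass matrix: broken mesh")
  d
}

#' Assemble all finite-element operators and the roughness penalty
#'
#' Builds the mass matrix M, stiffness matrix S, lumped mass \eqn{\tilde M},
#' and the sparse penalty matrix \eqn{D = S \tilde M^{-1} S + \epsilon M}
#' whose quadratic form approximates the regularizer
#' \eqn{J(\beta) = \|\Delta_M \beta\|^2 + \epsilon \|\beta\|^2}.
#' The lumped inverse is used deliberately so that D stays sparse.
#'
#' @param mesh a valid \code{fos_mesh}.
#' @param epsilon non-negative shrinkage weight; for \code{epsilon > 0} and
#'   a connected mesh D is positive definite.
#' @return an object of class \code{fem_operators}: list with \code{mass},
#'   \code{stiffness}, \code{lumped_mass}, \code{penalty}, \code{epsilon},
#'   \code{mesh}.
#' @export
assemble_penalty <- function(mesh, epsilon = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("epsilon must be a non-negative scalar")
  M <- assemble_mass(mesh)
  S <- assemble_stiffness(mesh)
  ml <- lump_mass(M)
  D <- S %*% Matrix::Diagonal(x = 1 / ml) %*% S + epsilon * M
  structure(list(mass = M, stiffness = S, lumped_mass = ml,
                 penalty = Matrix::forceSymmetric(D), epsilon = epsilon,
                 mesh = mesh),
            class = "fem_operators")
}

#' @exportS3Method base::print
print.fem_operators <- function(x, ...) {
  cat(sprintf("<fem_operators> s = %d, epsilon = %.3g, area = %.4g\n",
              length(x$lumped_mass), x$epsilon, sum(x$lumped_mass)))
  invisible(x)
}

#' L2 inner product of two vertex functions
#'
#' \eqn{\langle f, g \rangle_{L^2(M)} = f^T M g} with the consistent mass
#' matrix; exact for piecewise-linear fields on the mesh.
#'
#' @param ops \code{fem_operators} of the carrying mesh.
#' @param f,g \code{vertex_function}s or plain value vectors on that mesh.
#' @return scalar inner product.
#' @export
inner_product_l2 <- function(ops, f, g) {
  s <- length(ops$lumped_mass)
  fv <- vf_values(f, s)
  gv <- vf_values(g, s)
  as.numeric(fv %*% (ops$mass %*% gv))
}

#' Laplace-Beltrami eigenpairs
#'
#' Solves the generalized symmetric problem \eqn{S \phi = \theta M \phi}
#' for the k smallest eigenvalues, with M-orthonormal eigenvectors
#' (\eqn{\phi_i^T M \phi_j = \delta_{ij}}). On a closed connected mesh the
#' smallest eigenvalue is 0 with constant eigenvector. Large meshes use an
#' ARPACK shift-invert iteration (shift -1e-8, so the null space is handled
#' robustly); small meshes fall back to a dense solve.
#'
#' @param ops \code{fem_operators} (the \code{epsilon} slot is ignored).
#' @param k number of eigenpairs, \code{k < s}.
#' @return list with \code{values} (ascending) and \code{vectors}
#'   (s x k matrix of coefficient vectors).
#' @export
lb_eigenpairs <- function(ops, k) {
  s <- length(ops$lumped_mass)
  if (k >= s) stop("k must be smaller than the number of vertices")
  M <- ops$mass
  S <- ops$stiffness
  R <- Matrix::chol(M)                       # R' R = M
  if (s <= 400L || k > s / 4) {
    Ci <- Matrix::solve(Matrix::t(R), S)
    C <- as.matrix(Matrix::solve(Matrix::t(R), Matrix::t(Ci)))
    e <- eigen((C + t(C)) / 2, symmetric = TRUE)
    idx <- order(e$values)[seq_len(k)]
    vals <- e$values[idx]
    vecs <- as.matrix(Matrix::solve(R, e$vectors[, idx, drop = FALSE]))
  } else {
    sigma <- -1e-8
    F <- Matrix::Cholesky(Matrix::forceSymmetric(S - sigma * M), LDL = FALSE)
    op <- function(x, extra) {
      y <- Matrix::t(R) %*% x
      z <- Matrix::solve(F, y, system = "A")
      as.numeric(R %*% z)
    }
    res <- tryCatch(
      igraph::arpack(op, sym = TRUE,
                     options = list(n = s, nev = k,
                                    ncv = min(s, max(2L * k + 5L, 20L)),
                                    which = "LA", maxiter = 3000)),
      error = function(e) stop("eigen-solver failed to converge: ",
                               conditionMessage(e)))
    nu <- res$values
    vals <- sigma + 1 / nu
    ord <- order(vals)
    vals <- vals[ord]
    y <- res$vectors[, ord, drop = FALSE]
    vecs <- as.matrix(Matrix::solve(R, y))
  }
  # enforce M-orthonormality exactly (Gram-Schmidt in the M inner product,
  # only matters within numerically multiple eigenvalues)
  G <- t(vecs) %*% as.matrix(M %*% vecs)
  cg <- chol((G + t(G)) / 2)
  vecs <- vecs %*% solve(cg)
  list(values = vals, vectors = vecs)
}

#' Default shrinkage weight for the roughness penalty
#'
#' \eqn{\epsilon = 10^{-3} \theta_2^2} with \eqn{\theta_2} the first
#' nonzero Laplace-Beltrami eigenvalue of the template, which keeps the
#' bending and shrinkage terms of the penalty commensurate.
#'
#' @param mesh a \code{fos_mesh} (or \code{fem_operators}).
#' @return positive scalar epsilon.
#' @export
default_epsilon <- function(mesh) {
  ops <- if (inherits(mesh, "fem_operators")) mesh
         else assemble_penalty(mesh, epsilon = 0)
  ev <- lb_eigenpairs(ops, k = 4L)$values
  theta2 <- ev[ev > 1e-8][1L]
  if (!is.finite(theta2)) stop("could not find a nonzero eigenvalue")
  1e-3 * theta2^2
}
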