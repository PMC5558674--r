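# Independent reference solver for the penalized Gaussian log-likelihood
#   max  log det(theta) - tr(S theta) - rho * sum(|theta_ij|)
# via ADMM (Boyd et al. formulation): the theta update is an eigendecomposition
# prox of -logdet + trace, the Z update an entrywise soft-threshold (diagonal
# included), with scaled dual ascent. Shares no code with the package's block
# coordinate descent solver.
admm_glasso <- function(S, rho, t = 1, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(S)
  Z <- diag(m)
  U <- matrix(0, m, m)
  soft <- function(a, k) sign(a) * pmax(abs(a) - k, 0)
  for (it in seq_len(max_iter)) {
    eig <- eigen(t * (Z - U) - S, symmetric = TRUE)
    lam <- (eig$values + sqrt(eig$values^2 + 4 * t)) / (2 * t)
    theta <- eig$vectors %*% (lam * t(eig$vectors))
    theta <- (theta + t(theta)) / 2
    Z_old <- Z
    Z <- soft(theta + U, rho / t)
    U <- U + theta - Z
    r_prim <- max(abs(theta - Z))
    r_dual <- t * max(abs(Z - Z_old))
    if (r_prim < tol && r_dual < tol) break
  }
  list(theta = Z, theta_smooth = theta, iterations = it,
       primal_residual = r_prim, dual_residual = r_dual)
}

# Objective of the penalized log-likelihood (entrywise L1, diagonal included),
# computed independently of the package internals.
penalized_loglik <- function(theta, S, rho) {
  determinant(theta, logarithm = TRUE)$modulus[1] - sum(S * theta) -
    rho * sum(abs(theta))
}

# Random covariance-like test matrix: empirical 1/n covariance of n draws
# from a random-correlation Gaussian, m features.
random_cov <- function(m, n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * m), m, m)
  sigma <- crossprod(A) / m + diag(m) * 0.5
  L <- chol(sigma)
  X <- matrix(rnorm(n * m), n, m) %*% L
  Xc <- sweep(X, 2, colMeans(X))
  crossprod(Xc) / n
}
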