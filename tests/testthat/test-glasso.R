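test_that("empirical covariance matches direct 1/n arithmetic", {
  vals <- matrix(c(1, 2, 4, 5,
                   2, 4, 6, 8,
                   1, 0, 3, 2), 4, 3)
  expr <- make_expr(vals, features = c("a", "b", "c"))
  cv <- empirical_covariance(expr, transform = "none", scale = "covariance")
  # independent oracle: elementwise mean of centered cross products
  n <- nrow(vals)
  S_hand <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    S_hand[i, j] <- mean((vals[, i] - mean(vals[, i])) *
                           (vals[, j] - mean(vals[, j])))
  }
  expect_equal(unname(cv$S), S_hand, tolerance = 1e-12)
  expect_equal(cv$n, 4L)
})

test_that("correlation scaling gives unit diagonal and collinear columns correlation 1", {
  expr <- make_expr(cbind(c(1, 2, 3), c(2, 4, 6), c(3, 1, 2)),
                    features = c("a", "b", "c"))
  cv <- empirical_covariance(expr, transform = "none", scale = "correlation")
  expect_equal(unname(diag(cv$S)), rep(1, 3))
  expect_equal(cv$S["a", "b"], 1)

  # independent large-n columns have near-zero off-diagonals
  set.seed(8)
  big <- make_expr(matrix(abs(rnorm(4000)), 2000, 2), features = c("x", "y"))
  cv2 <- empirical_covariance(big, transform = "none", scale = "correlation")
  expect_lt(abs(cv2$S["x", "y"]), 0.1)
})

test_that("constant features are removed with a report, never silently kept", {
  vals <- cbind(c(1, 2, 3), c(5, 5, 5), c(2, 1, 4))
  expr <- make_expr(vals, features = c("a", "const", "c"))
  expect_warning(cv <- empirical_covariance(expr, transform = "none",
                                            scale = "covariance"),
                 "const")
  expect_equal(cv$feature_ids, c("a", "c"))
  expect_equal(cv$dropped, "const")

  one_sample <- make_expr(matrix(1:3, 1, 3))
  expect_error(empirical_covariance(one_sample), "at least 2")
  all_const <- make_expr(matrix(1, 3, 2))
  expect_error(suppressWarnings(empirical_covariance(all_const, "none")),
               "constant")
})

test_that("analytic solutions are reproduced exactly", {
  # decoupled problem: diagonal S gives theta = diag(1/(s_ii + rho))
  s <- c(2, 0.5, 7, 1)
  fit <- graphical_lasso(covariance_input(diag(s)), rho = 1.3)
  expect_lt(max(abs(fit$theta - diag(1 / (s + 1.3)))), 1e-10)

  # p = 2 closed form: W12 is the soft-threshold of s12 by rho
  S <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  fit2 <- graphical_lasso(covariance_input(S), rho = 0.3)
  expect_lt(abs(fit2$W[1, 2] - 0.5), 1e-8)
  W_exact <- matrix(c(1.3, 0.5, 0.5, 1.3), 2, 2)
  expect_lt(max(abs(fit2$theta - solve(W_exact))), 1e-8)

  # full shrinkage: rho at the largest off-diagonal leaves theta diagonal
  for (seed in 1:5) {
    S5 <- random_cov(5, 40, seed = seed)
    rho_max <- max(abs(S5[upper.tri(S5)]))
    fit3 <- graphical_lasso(covariance_input(S5), rho = rho_max)
    expect_equal(max(abs(fit3$theta[upper.tri(fit3$theta)])), 0)
  }
})

test_that("the solver agrees with an independent convex-optimization oracle", {
  for (i in 1:10) {
    m <- 3 + (i %% 4)
    S <- random_cov(m, 100, seed = 500 + i)
    rho <- 0.1 * (1 + (i %% 3)) * max(abs(S))
    fit <- graphical_lasso(covariance_input(S), rho = rho, tol = 1e-6,
                           inner_tol = 1e-9, max_iter = 500)
    oracle <- admm_glasso(S, rho)
    expect_lt(max(abs(fit$theta - oracle$theta)), 1e-4)
    # neither solution beats the other's objective beyond numerical noise
    expect_gte(penalized_loglik(fit$theta, S, rho),
               penalized_loglik(oracle$theta_smooth, S, rho) - 1e-7)
  }
})

test_that("every converged fit is KKT-certified, positive definite, and beats the diagonal feasible point", {
  for (i in 1:20) {
    m <- 3 + (i %% 5)
    S <- random_cov(m, 60, seed = 2000 + i)
    rho <- stats::runif(1, 0.05, 0.6) * max(abs(S))
    fit <- graphical_lasso(covariance_input(S), rho = rho)
    expect_true(fit$converged)
    expect_lt(fit$kkt_residual, 1e-3)
    ev <- eigen(fit$theta, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # W is the implied covariance: W theta = I up to solver tolerance
    expect_lt(max(abs(fit$W %*% fit$theta - diag(m))), 1e-3)
    # optimality lower bound at the diagonal feasible point
    diag_obj <- penalized_loglik(diag(1 / (diag(S) + rho)), S, rho)
    expect_gte(fit$objective, diag_obj - 1e-10)
  }
})

test_that("the estimate is permutation-equivariant and scale-free on correlation input", {
  S <- random_cov(6, 80, seed = 77)
  rho <- 0.2 * max(abs(S))
  fit <- graphical_lasso(covariance_input(S), rho = rho, tol = 1e-6)
  perm <- c(3, 1, 6, 2, 5, 4)
  fitp <- graphical_lasso(covariance_input(S[perm, perm]), rho = rho,
                          tol = 1e-6)
  expect_lt(max(abs(fitp$theta - fit$theta[perm, perm])), 1e-6)

  # per-feature rescaling of the data does not change the edge set when the
  # input is correlation-scaled
  set.seed(9)
  X <- matrix(abs(rnorm(300)), 50, 6)
  expr <- make_expr(X)
  scaled <- make_expr(sweep(X, 2, c(1, 10, 0.2, 5, 100, 3), "*"))
  f1 <- graphical_lasso(empirical_covariance(expr, "none", "correlation"),
                        rho = 0.1)
  f2 <- graphical_lasso(empirical_covariance(scaled, "none", "correlation"),
                        rho = 0.1)
  expect_equal(abs(f1$theta) > 1e-8, abs(f2$theta) > 1e-8)
})

test_that("the penalty path is warm-start consistent and sparsest at its largest penalty", {
  S <- random_cov(8, 100, seed = 123)
  smax <- max(abs(S[upper.tri(S)]))
  rhos <- smax * c(1.2, 0.6, 0.3, 0.15, 0.05)
  path <- glasso_path(covariance_input(S), rhos = rhos, tol = 1e-6)
  expect_length(path, 5L)
  # largest penalty exceeds every off-diagonal: exactly diagonal
  expect_equal(glance(path)$n_edges[1], 0L)
  expect_lte(glance(path)$n_edges[1], glance(path)$n_edges[5])
  # warm starts agree with cold starts
  for (k in c(2, 4)) {
    cold <- graphical_lasso(covariance_input(S), rho = rhos[k], tol = 1e-6)
    expect_lt(max(abs(path[[k]]$theta - cold$theta)), 10 * 1e-6)
  }
  expect_error(glasso_path(covariance_input(S), rhos = c(0.5, 0)), "positive")
})

test_that("tidy and glance expose edges and fit summaries", {
  S <- matrix(c(1, 0.6, 0, 0.6, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(c("mirX", "gA", "gB"), c("mirX", "gA", "gB")))
  cv <- covariance_input(S, feature_class = c("miRNA", "mRNA", "mRNA"))
  fit <- graphical_lasso(cv, rho = 0.1)
  ed <- tidy(fit)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$feature_a, "mirX")  # matrix (input) order within the pair
  expect_equal(ed$feature_b, "gA")
  expect_equal(ed$class_a, "miRNA")
  expect_lt(ed$theta, 0)  # positive covariance implies negative precision entry
  gl <- glance(fit)
  expect_equal(gl$n_edges, 1L)
  expect_true(gl$converged)
  expect_error(graphical_lasso(cv, rho = -1), "nonnegative")
})
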