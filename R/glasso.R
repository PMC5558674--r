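#' Empirical covariance of an integrated expression matrix
#'
#' Computes the maximum-likelihood (divisor `1/n`) covariance of the joint
#' miRNA + mRNA matrix, optionally after a `log2(x + 1)` transform, and
#' optionally rescaled to a correlation matrix. The defaults (`log2p1`,
#' `correlation`) put read counts on a bounded scale where a single penalty
#' value is meaningful across features; `transform = "none"` with
#' `scale = "covariance"` gives the literal covariance of the raw values.
#' Constant columns (zero variance after transform) would make the Gaussian
#' model degenerate and are removed with a warning; their IDs are recorded in
#' the `dropped` field.
#'
#' When the samples come from two clinical groups, the features that survive
#' the differential filter carry a group-mean difference by construction.
#' Pooling the groups then adds a dense between-group component to every
#' pair of differential features, which masks the within-group
#' conditional-dependence structure the graphical model is after. Passing
#' the group assignment via `groups` centers each feature within each group
#' first, so S estimates the pooled within-group covariance.
#'
#' @param expr An [expression_matrix()], typically the integrated matrix Z.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param scale `"correlation"` (default) or `"covariance"`.
#' @param groups Optional [assign_groups()] result; if supplied, features are
#'   centered within each group before the covariance (samples outside both
#'   groups are dropped).
#' @return A `covariance_input`: list with `S` (m x m), `feature_ids`,
#'   `feature_class`, `n`, `dropped`, `transform`, `scale`.
#' @export
empirical_covariance <- function(expr, transform = c("log2p1", "none"),
                                 scale = c("correlation", "covariance"),
                                 groups = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  transform <- match.arg(transform)
  scale <- match.arg(scale)
  Z <- expr$values
  if (!is.null(groups)) {
    stopifnot(inherits(groups, "group_assignment"))
    listed <- c(groups$group_a, groups$group_b)
    missing <- setdiff(listed, rownames(Z))
    if (length(missing)) {
      stop(sprintf("group sample(s) missing from expression matrix: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    Z <- Z[listed, , drop = FALSE]
  }
  n <- nrow(Z)
  if (n < 2L) stop("need at least 2 samples for a covariance", call. = FALSE)
  if (transform == "log2p1") Z <- log2(Z + 1)
  if (!is.null(groups)) {
    for (g in list(groups$group_a, groups$group_b)) {
      Z[g, ] <- sweep(Z[g, , drop = FALSE], 2,
                      colMeans(Z[g, , drop = FALSE]))
    }
  }

  v <- apply(Z, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all features are constant", call. = FALSE)
  dropped <- expr$feature_ids[!keep]
  if (length(dropped)) {
    warning(sprintf("removed %d constant feature(s): %s", length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
    Z <- Z[, keep, drop = FALSE]
  }

  Zc <- sweep(Z, 2, colMeans(Z))
  S <- crossprod(Zc) / n
  if (scale == "correlation") {
    d <- sqrt(diag(S))
    S <- S / tcrossprod(d)
  }
  S <- (S + t(S)) / 2

  structure(
    list(S = S,
         feature_ids = colnames(Z),
         feature_class = setNames(unname(expr$feature_class[colnames(Z)]),
                                  colnames(Z)),
         n = n,
         dropped = dropped,
         transform = transform,
         scale = scale),
    class = "covariance_input"
  )
}

#' Build a covariance input from a precomputed matrix
#'
#' Mostly for testing and for problems posed directly at the covariance
#' level. The matrix is symmetrized; a strictly positive diagonal is
#' required.
#'
#' @param S Symmetric numeric matrix.
#' @param feature_class Per-feature class labels (defaults to all `"mRNA"`).
#' @param n Sample count used to form `S` (metadata only).
#' @return A `covariance_input`.
#' @export
covariance_input <- function(S, feature_class = NULL, n = NA_integer_) {
  stopifnot(is.matrix(S), is.numeric(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-10) {
    stop("S is not symmetric within 1e-10", call. = FALSE)
  }
  S <- (S + t(S)) / 2
  if (any(diag(S) <= 0)) {
    stop("S must have a strictly positive diagonal (remove constant features)",
         call. = FALSE)
  }
  ids <- colnames(S)
  if (is.null(ids)) {
    ids <- sprintf("f%0*d", nchar(nrow(S)), seq_len(nrow(S)))
    dimnames(S) <- list(ids, ids)
  }
  if (is.null(feature_class)) feature_class <- rep("mRNA", nrow(S))
  structure(
    list(S = S, feature_ids = ids,
         feature_class = setNames(feature_class, ids),
         n = n, dropped = character(),
         transform = "none", scale = "covariance"),
    class = "covariance_input"
  )
}

#' @export
print.covariance_input <- function(x, ...) {
  cat(sprintf("<covariance_input> %d features, n = %s (%s, %s)\n",
              length(x$feature_ids), x$n, x$transform, x$scale))
  invisible(x)
}

#' Sparse precision matrix by the graphical lasso
#'
#' Maximizes the L1-penalized Gaussian log-likelihood
#' \deqn{\log\det\theta - \mathrm{tr}(S\theta) - \rho\|\theta\|_1}
#' (entrywise L1 norm) by block coordinate descent: the solver cycles over
#' columns in input order, solves each column's lasso subproblem by cyclic
#' coordinate descent with soft-thresholding, and maintains the dual
#' covariance iterate W with `diag(W) = diag(S) + rho`. Runs are
#' deterministic for fixed input and tolerances.
#'
#' A zero off-diagonal in the estimated precision matrix means conditional
#' independence of the two features given the rest; nonzeros are the edges of
#' the inferred Gaussian graphical model.
#'
#' Convergence is declared when the mean absolute change of the off-diagonal
#' W entries in a sweep falls below `tol` times the mean absolute
#' off-diagonal of S. On return the KKT conditions are certified:
#' `|W - S| <= rho` off-diagonally (within tolerance), with
#' `W_ij - S_ij = rho * sign(theta_ij)` wherever `theta_ij != 0`; the maximum
#' violation is reported as `kkt_residual`.
#'
#' @param input A `covariance_input` from [empirical_covariance()] or
#'   [covariance_input()].
#' @param rho Nonnegative L1 penalty (default 2.0). `rho = 0` requires a
#'   nonsingular S.
#' @param tol Relative outer convergence tolerance (default 1e-4).
#' @param max_iter Maximum outer sweeps (default 100).
#' @param inner_tol,inner_max_iter Inner lasso tolerances (defaults 1e-6,
#'   1000).
#' @param W_init,B_init Optional warm starts (used by [glasso_path()]).
#' @return A `glasso_fit`: list with `theta`, `W`, `rho`, `objective`,
#'   `iterations`, `converged`, `kkt_residual`, `feature_ids`,
#'   `feature_class`, `n`, and the tolerances used.
#' @export
#' @examples
#' S <- matrix(c(1, .8, .8, 1), 2, 2)
#' fit <- graphical_lasso(covariance_input(S), rho = 0.3)
#' fit$W[1, 2]  # soft-threshold of 0.8 by 0.3
graphical_lasso <- function(input, rho = 2.0, tol = 1e-4, max_iter = 100L,
                            inner_tol = 1e-6, inner_max_iter = 1000L,
                            W_init = NULL, B_init = NULL) {
  stopifnot(inherits(input, "covariance_input"))
  if (rho < 0) stop("rho must be nonnegative", call. = FALSE)
  S <- input$S
  m <- nrow(S)
  if (rho == 0 && m > 1) {
    if (rcond(S) < .Machine$double.eps * m) {
      stop("rho = 0 requires a nonsingular covariance matrix", call. = FALSE)
    }
  }

  res <- .glasso_cd(S, rho, tol, as.integer(max_iter), inner_tol,
                    as.integer(inner_max_iter), W_init, B_init)
  theta <- res$theta
  W <- res$W
  dimnames(theta) <- dimnames(S)
  dimnames(W) <- dimnames(S)

  ev_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop(sprintf(
      "numerical failure: estimated precision matrix not positive definite (min eigenvalue %.3e)",
      ev_min), call. = FALSE)
  }

  obj <- glasso_objective(theta, S, rho)
  kkt <- glasso_kkt_residual(theta, W, S, rho)

  structure(
    list(theta = theta, W = W, rho = rho,
         objective = obj,
         iterations = res$iterations,
         converged = res$converged,
         kkt_residual = kkt,
         B = res$B,
         feature_ids = input$feature_ids,
         feature_class = input$feature_class,
         n = input$n,
         tol = tol, inner_tol = inner_tol),
    class = "glasso_fit"
  )
}

# Penalized log-likelihood at theta (entrywise L1, diagonal included).
glasso_objective <- function(theta, S, rho) {
  2 * sum(log(diag(chol(theta)))) - sum(S * theta) - rho * sum(abs(theta))
}

# Maximum KKT violation: off-diagonal |W - S| must not exceed rho, with
# equality (sign-consistent) where theta is nonzero; diag(W) = diag(S) + rho.
glasso_kkt_residual <- function(theta, W, S, rho, zero_tol = 1e-8) {
  D <- W - S
  m <- nrow(S)
  off <- upper.tri(D) | lower.tri(D)
  viol_box <- max(0, if (m > 1) max(abs(D[off])) - rho else 0)
  active <- off & abs(theta) > zero_tol
  viol_eq <- if (any(active)) {
    max(abs(D[active] - rho * sign(theta[active])))
  } else 0
  viol_diag <- max(abs(diag(D) - rho))
  max(viol_box, viol_eq, viol_diag)
}

#' @export
print.glasso_fit <- function(x, ...) {
  ne <- sum(abs(x$theta[upper.tri(x$theta)]) > 1e-8)
  cat(sprintf(
    "<glasso_fit> %d features, rho = %g: %d edges, objective %.4f, %d sweeps (%s)\n",
    nrow(x$theta), x$rho, ne, x$objective, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy the edges of a graphical-lasso fit
#'
#' @param x A `glasso_fit`.
#' @param edge_eps Absolute precision-matrix threshold defining an edge
#'   (default 1e-8).
#' @param ... Unused.
#' @return A tibble with one row per edge: `feature_a`, `feature_b`,
#'   `class_a`, `class_b`, `theta`, `partial_cor`.
#' @export
tidy.glasso_fit <- function(x, edge_eps = 1e-8, ...) {
  th <- x$theta
  idx <- which(upper.tri(th) & abs(th) > edge_eps, arr.ind = TRUE)
  d <- sqrt(diag(th))
  tibble(
    feature_a = x$feature_ids[idx[, 1]],
    feature_b = x$feature_ids[idx[, 2]],
    class_a = unname(x$feature_class[idx[, 1]]),
    class_b = unname(x$feature_class[idx[, 2]]),
    theta = th[idx],
    partial_cor = -th[idx] / (d[idx[, 1]] * d[idx[, 2]])
  ) |>
    dplyr::arrange(.data$feature_a, .data$feature_b)
}

#' One-row summary of a graphical-lasso fit
#'
#' @param x A `glasso_fit`.
#' @param edge_eps Edge threshold (default 1e-8).
#' @param ... Unused.
#' @return A one-row tibble: `n_features`, `n`, `rho`, `n_edges`,
#'   `objective`, `iterations`, `converged`, `kkt_residual`.
#' @export
glance.glasso_fit <- function(x, edge_eps = 1e-8, ...) {
  tibble(
    n_features = nrow(x$theta),
    n = x$n,
    rho = x$rho,
    n_edges = sum(abs(x$theta[upper.tri(x$theta)]) > edge_eps),
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged,
    kkt_residual = x$kkt_residual
  )
}

#' Graphical lasso along a penalty path
#'
#' Fits one model per penalty value, from the largest penalty down,
#' warm-starting each fit from the previous solution. Penalties are sorted
#' internally (decreasing); results are returned in that order.
#'
#' @param input A `covariance_input`.
#' @param rhos Strictly positive penalty values.
#' @param ... Passed to [graphical_lasso()].
#' @return A list of `glasso_fit` objects of class `glasso_path`, one per
#'   penalty, in decreasing penalty order.
#' @export
glasso_path <- function(input, rhos, ...) {
  if (any(rhos <= 0)) stop("path penalties must be strictly positive",
                           call. = FALSE)
  rhos <- sort(unique(rhos), decreasing = TRUE)
  fits <- vector("list", length(rhos))
  W <- NULL
  B <- NULL
  for (i in seq_along(rhos)) {
    fits[[i]] <- graphical_lasso(input, rho = rhos[i], W_init = W, B_init = B,
                                 ...)
    W <- fits[[i]]$W
    B <- fits[[i]]$B
  }
  structure(fits, class = "glasso_path", rhos = rhos)
}

#' @export
print.glasso_path <- function(x, ...) {
  cat(sprintf("<glasso_path> %d penalties: %s\n", length(x),
              paste(attr(x, "rhos"), collapse = ", ")))
  invisible(x)
}

#' Edge counts and objectives along a penalty path
#'
#' @param x A `glasso_path`.
#' @param ... Passed to [glance.glasso_fit()].
#' @return A tibble with one row per penalty.
#' @export
glance.glasso_path <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance, ...))
}

#' Sparsity profile of a penalty path
#'
#' @param object A `glasso_path`.
#' @param ... Unused.
#' @return A ggplot of edge count against penalty (log scale).
#' @export
autoplot.glasso_path <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$n_edges)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(rho), y = "edges")
}
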