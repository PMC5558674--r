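#' Plant a sparse joint precision matrix with hub miRNAs
#'
#' Builds the ground-truth precision matrix of a joint miRNA + mRNA Gaussian
#' model: 1 on the diagonal, `offdiag` (with a random sign) on each planted
#' hub-to-mRNA entry. Each hub miRNA receives `degree` target mRNAs, sampled
#' without replacement. If the raw matrix is not safely positive definite, a
#' ridge `delta * I` is added with the smallest `delta >= 0` bringing the
#' minimum eigenvalue to at least 0.1.
#'
#' @param n_mirna,n_mrna Number of miRNA and mRNA features.
#' @param hubs Data frame with columns `mirna` (index into the miRNA block,
#'   1-based) and `degree`; or `NULL` for no planted structure (identity
#'   precision).
#' @param offdiag Magnitude of planted off-diagonal entries (default 0.2).
#' @param seed Integer RNG seed (Mersenne-Twister, inversion normals).
#' @return A `synthetic_truth`: list with `theta_true`, `feature_ids`,
#'   `feature_class`, `bipartite_edges_true` (tibble `node_a`, `node_b`),
#'   `hub_degrees_true` (tibble `mirna`, `degree`), `delta`, `seed`.
#' @export
make_precision <- function(n_mirna, n_mrna, hubs = NULL, offdiag = 0.2,
                           seed = 1L) {
  stopifnot(n_mirna >= 1, n_mrna >= 1)
  mirna_ids <- sprintf("mir-%03d", seq_len(n_mirna))
  mrna_ids <- sprintf("gene-%04d", seq_len(n_mrna))
  ids <- c(mirna_ids, mrna_ids)
  m <- n_mirna + n_mrna
  theta <- diag(m)
  dimnames(theta) <- list(ids, ids)

  edges <- tibble(node_a = character(), node_b = character())
  degrees <- tibble(mirna = character(), degree = integer())

  if (!is.null(hubs) && nrow(as.data.frame(hubs)) > 0) {
    hubs <- as.data.frame(hubs)
    stopifnot(all(c("mirna", "degree") %in% colnames(hubs)))
    if (any(hubs$mirna < 1 | hubs$mirna > n_mirna)) {
      stop("hub miRNA indices out of range", call. = FALSE)
    }
    if (any(hubs$degree > n_mrna)) {
      stop("hub degree exceeds the number of mRNAs", call. = FALSE)
    }
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    for (h in seq_len(nrow(hubs))) {
      i <- hubs$mirna[h]
      targets <- sample.int(n_mrna, hubs$degree[h])
      signs <- sample(c(-1, 1), hubs$degree[h], replace = TRUE)
      for (t in seq_along(targets)) {
        j <- n_mirna + targets[t]
        theta[i, j] <- theta[j, i] <- signs[t] * offdiag
      }
      edges <- dplyr::bind_rows(edges, tibble(node_a = mirna_ids[i],
                                              node_b = mrna_ids[targets]))
    }
    degrees <- tibble(mirna = mirna_ids[hubs$mirna],
                      degree = as.integer(hubs$degree))
  }

  ev_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  delta <- max(0, 0.1 - ev_min)
  if (delta > 0) diag(theta) <- diag(theta) + delta

  structure(
    list(theta_true = theta,
         feature_ids = ids,
         feature_class = setNames(rep(c("miRNA", "mRNA"), c(n_mirna, n_mrna)),
                                  ids),
         bipartite_edges_true = dplyr::arrange(edges, .data$node_a,
                                               .data$node_b),
         hub_degrees_true = degrees,
         delta = delta,
         seed = seed),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d features, %d planted bipartite edges, %d hubs (ridge %.3g)\n",
    length(x$feature_ids), nrow(x$bipartite_edges_true),
    nrow(x$hub_degrees_true), x$delta))
  invisible(x)
}

#' Sample expression data from a planted model
#'
#' Draws `n_per_group` samples per group from
#' \eqn{N(\mu_g, \theta_{true}^{-1})}. Group A's mean is shifted by
#' `de_effect_log2` on the planted differentially expressed features; both
#' groups share the baseline mean elsewhere. With `noise = "gaussian"` the
#' latent draws are emitted directly and are interpreted as log2 expression;
#' with `noise = "nb_counts"` each latent value becomes the log2 mean of a
#' negative-binomial count with fixed dispersion 0.1 (size 10).
#'
#' The clinical table encodes the groups redundantly through all three
#' endpoints (group A: survival 100 days, ER-negative, stage III; group B:
#' survival 700 days, ER-positive, stage I), so any grouping rule
#' reconstructs the planted split.
#'
#' @param truth A [make_precision()] result.
#' @param n_per_group Samples per group (>= 2).
#' @param de_effect_log2 Mean shift on DE features for group A (default 2).
#' @param noise `"gaussian"` (default) or `"nb_counts"`.
#' @param de_features Which features carry the shift: `"network"` (default;
#'   all features incident to a planted edge), `"none"`, or a character
#'   vector of feature IDs.
#' @param baseline Baseline latent log2 expression (default 3).
#' @param seed Integer RNG seed.
#' @return A list: `expr` (joint [expression_matrix()], group A samples
#'   first), `clinical` ([clinical_table()]), `de_features` (tibble
#'   `feature_id`, `effect_log2`), `groups` (the planted assignment as
#'   sample-ID lists).
#' @export
sample_expression <- function(truth, n_per_group, de_effect_log2 = 2,
                              noise = c("gaussian", "nb_counts"),
                              de_features = "network", baseline = 3,
                              seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_per_group >= 2)
  noise <- match.arg(noise)
  m <- length(truth$feature_ids)

  de_ids <- if (identical(de_features, "network")) {
    sort(unique(c(truth$bipartite_edges_true$node_a,
                  truth$bipartite_edges_true$node_b)))
  } else if (identical(de_features, "none")) {
    character()
  } else {
    unknown <- setdiff(de_features, truth$feature_ids)
    if (length(unknown)) {
      stop(sprintf("unknown DE feature(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    as.character(de_features)
  }

  sigma <- solve(truth$theta_true)
  sigma <- (sigma + t(sigma)) / 2
  L <- chol(sigma)

  mu_b <- rep(baseline, m)
  mu_a <- mu_b
  mu_a[match(de_ids, truth$feature_ids)] <- baseline + de_effect_log2

  n <- 2L * n_per_group
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  z <- matrix(rnorm(n * m), n, m)
  latent <- z %*% L
  latent <- sweep(latent, 2, mu_b, "+")
  idx_a <- seq_len(n_per_group)
  latent[idx_a, ] <- sweep(latent[idx_a, , drop = FALSE], 2, mu_a - mu_b, "+")

  vals <- if (noise == "gaussian") {
    pmax(latent, 0)  # expression values are nonnegative by contract
  } else {
    cnt <- rnbinom(n * m, mu = 2^as.vector(latent), size = 10)
    matrix(as.numeric(cnt), n, m)
  }
  sample_ids <- sprintf("s%04d", seq_len(n))
  dimnames(vals) <- list(sample_ids, truth$feature_ids)

  group_a <- sample_ids[idx_a]
  group_b <- sample_ids[-idx_a]
  clinical <- clinical_table(
    sample_id = sample_ids,
    survival_days = rep(c(100, 700), each = n_per_group),
    er_status = rep(c("negative", "positive"), each = n_per_group),
    stage = rep(c("III", "I"), each = n_per_group)
  )

  list(
    expr = expression_matrix(vals, unname(truth$feature_class)),
    clinical = clinical,
    de_features = tibble(feature_id = de_ids,
                         effect_log2 = rep(de_effect_log2, length(de_ids))),
    groups = list(group_a = group_a, group_b = group_b)
  )
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: plants the precision structure, samples expression
#' and clinical data, and returns everything a pipeline run needs, split by
#' molecule class as the pipeline consumes it.
#'
#' @param n_mirna,n_mrna Feature counts (defaults 20 and 200).
#' @param hubs Hub specification as in [make_precision()]; default 5 hubs of
#'   degree 10 on the first five miRNAs.
#' @param offdiag Planted off-diagonal magnitude (default 0.25).
#' @param n_per_group Samples per group (default 150).
#' @param de_effect_log2,noise,de_features,baseline See
#'   [sample_expression()].
#' @param seed Integer RNG seed.
#' @return A list: `mirna`, `mrna` (per-class [expression_matrix()]s),
#'   `clinical`, `truth` (with `de_features` attached), `groups`.
#' @export
simulate_dataset <- function(n_mirna = 20, n_mrna = 200,
                             hubs = data.frame(mirna = 1:5, degree = 10),
                             offdiag = 0.25, n_per_group = 150,
                             de_effect_log2 = 2,
                             noise = c("gaussian", "nb_counts"),
                             de_features = "network", baseline = 3,
                             seed = 1L) {
  noise <- match.arg(noise)
  truth <- make_precision(n_mirna, n_mrna, hubs = hubs, offdiag = offdiag,
                          seed = seed)
  draw <- sample_expression(truth, n_per_group = n_per_group,
                            de_effect_log2 = de_effect_log2, noise = noise,
                            de_features = de_features, baseline = baseline,
                            seed = seed + 1L)
  truth$de_features <- draw$de_features
  mirna_ids <- truth$feature_ids[truth$feature_class == "miRNA"]
  mrna_ids <- truth$feature_ids[truth$feature_class == "mRNA"]
  list(
    mirna = select_features(draw$expr, mirna_ids),
    mrna = select_features(draw$expr, mrna_ids),
    clinical = draw$clinical,
    truth = truth,
    groups = draw$groups
  )
}
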