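# Small builders shared across test files.

# Expression matrix with given dimensions and deterministic values.
make_expr <- function(values, samples = NULL, features = NULL,
                      class = "mRNA") {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(values)))
  if (is.null(features)) features <- sprintf("f%d", seq_len(ncol(values)))
  dimnames(values) <- list(samples, features)
  expression_matrix(values, class)
}

# Minimal glasso_fit stand-in for network construction tests: only the
# fields build_network() consumes.
fake_fit <- function(theta, classes, converged = TRUE) {
  ids <- colnames(theta)
  structure(list(theta = theta, feature_ids = ids,
                 feature_class = stats::setNames(classes, ids),
                 converged = converged),
            class = "glasso_fit")
}

# Random mixed-class network: each possible pair becomes an edge with
# probability p_edge.
random_network <- function(n_mirna, n_mrna, p_edge, seed) {
  set.seed(seed)
  ids <- c(sprintf("mir%02d", seq_len(n_mirna)),
           sprintf("g%03d", seq_len(n_mrna)))
  classes <- rep(c("miRNA", "mRNA"), c(n_mirna, n_mrna))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  interaction_network(
    nodes = data.frame(id = ids, class = classes),
    edges = data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2])
  )
}

# Canonical unordered-pair keys of a network's edge set.
edge_keys <- function(net) {
  e <- net$edges
  sort(paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b)))
}
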