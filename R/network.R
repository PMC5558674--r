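#' Interaction network from a precision estimate
#'
#' Every feature is a node; an (unordered) edge joins features a and b when
#' `|theta_ab| > edge_eps`. The threshold exists because a solver returns
#' numerically small values rather than hard zeros; 1e-8 is far below any
#' meaningful partial association.
#'
#' @param fit A converged `glasso_fit`. Non-converged fits are refused unless
#'   `force = TRUE`.
#' @param edge_eps Absolute threshold on precision entries (default 1e-8).
#' @param force Build the network from a non-converged fit anyway.
#' @return An `interaction_network`: list with `nodes` (tibble: `id`,
#'   `class`) and `edges` (tibble: `node_a`, `node_b`, `class_a`, `class_b`,
#'   `weight` = `|theta_ab|`), edges ordered lexicographically with
#'   `node_a < node_b`.
#' @export
build_network <- function(fit, edge_eps = 1e-8, force = FALSE) {
  stopifnot(inherits(fit, "glasso_fit"))
  if (!fit$converged && !force) {
    stop("precision estimate did not converge; rerun with more iterations or use force = TRUE",
         call. = FALSE)
  }
  th <- fit$theta
  idx <- which(upper.tri(th) & abs(th) > edge_eps, arr.ind = TRUE)
  nodes <- tibble(id = fit$feature_ids,
                  class = unname(fit$feature_class))
  a <- fit$feature_ids[idx[, 1]]
  b <- fit$feature_ids[idx[, 2]]
  swap <- a > b
  edges <- tibble(
    node_a = ifelse(swap, b, a),
    node_b = ifelse(swap, a, b),
    weight = abs(th[idx])
  )
  new_interaction_network(nodes, edges, bipartite = FALSE)
}

new_interaction_network <- function(nodes, edges, bipartite) {
  cls <- setNames(nodes$class, nodes$id)
  edges <- edges |>
    dplyr::mutate(class_a = unname(cls[.data$node_a]),
                  class_b = unname(cls[.data$node_b])) |>
    dplyr::select("node_a", "node_b", "class_a", "class_b",
                  dplyr::any_of("weight")) |>
    dplyr::arrange(.data$node_a, .data$node_b)
  if (any(edges$node_a == edges$node_b)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  bad <- setdiff(c(edges$node_a, edges$node_b), nodes$id)
  if (length(bad)) {
    stop(sprintf("edge endpoint(s) not in node set: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, bipartite = bipartite),
            class = "interaction_network")
}

#' Construct an interaction network from node and edge tables
#'
#' @param nodes Tibble/data frame with columns `id`, `class`.
#' @param edges Tibble/data frame with columns `node_a`, `node_b` and
#'   optionally `weight`.
#' @return An `interaction_network`.
#' @export
interaction_network <- function(nodes, edges) {
  nodes <- tibble(id = as.character(nodes$id), class = nodes$class)
  check_unique(nodes$id, "node")
  if (!all(nodes$class %in% c("miRNA", "mRNA"))) {
    stop("node classes must be 'miRNA' or 'mRNA'", call. = FALSE)
  }
  edges <- as_tibble(edges)
  if (nrow(edges)) {
    a <- as.character(edges$node_a)
    b <- as.character(edges$node_b)
    swap <- a > b
    edges$node_a <- ifelse(swap, b, a)
    edges$node_b <- ifelse(swap, a, b)
    edges <- dplyr::distinct(edges, .data$node_a, .data$node_b,
                             .keep_all = TRUE)
  } else {
    edges <- tibble(node_a = character(), node_b = character())
  }
  new_interaction_network(nodes, edges, bipartite = FALSE)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network>%s %d nodes (%d miRNA, %d mRNA), %d edges\n",
              if (isTRUE(x$bipartite)) " [bipartite view]" else "",
              nrow(x$nodes), sum(x$nodes$class == "miRNA"),
              sum(x$nodes$class == "mRNA"), nrow(x$edges)))
  invisible(x)
}

#' @describeIn build_network The edge table of a network.
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @export
as_tibble.interaction_network <- function(x, ...) x$edges

#' Bipartite miRNA-mRNA view of a network
#'
#' Keeps only edges joining a miRNA to an mRNA; miRNA-miRNA and mRNA-mRNA
#' edges are dropped. The node set is unchanged. Idempotent.
#'
#' @param net An `interaction_network`.
#' @return An `interaction_network` flagged as bipartite.
#' @export
bipartite_view <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  edges <- dplyr::filter(net$edges, .data$class_a != .data$class_b)
  new_interaction_network(net$nodes, edges, bipartite = TRUE)
}

#' Rank hub miRNAs by bipartite degree
#'
#' Each miRNA's degree is its number of connected mRNAs in the bipartite
#' view. miRNAs are sorted by degree (decreasing), ties broken
#' lexicographically by ID; zero-degree miRNAs are excluded and the list is
#' cut at `top_k`.
#'
#' @param net A bipartite `interaction_network` (see [bipartite_view()]).
#' @param top_k Number of miRNAs to keep (default 20).
#' @return A tibble of class `hub_ranking`: `mirna`, `degree`.
#' @export
rank_hubs <- function(net, top_k = 20L) {
  stopifnot(inherits(net, "interaction_network"))
  if (!isTRUE(net$bipartite)) net <- bipartite_view(net)
  if (top_k < 1L) stop("top_k must be at least 1", call. = FALSE)
  deg <- mirna_degrees(net)
  out <- deg |>
    dplyr::filter(.data$degree > 0) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$mirna) |>
    dplyr::slice_head(n = top_k)
  class(out) <- c("hub_ranking", class(out))
  out
}

# Bipartite degree of every miRNA node (including zero).
mirna_degrees <- function(net) {
  mirnas <- net$nodes$id[net$nodes$class == "miRNA"]
  long <- c(net$edges$node_a[net$edges$class_a == "miRNA"],
            net$edges$node_b[net$edges$class_b == "miRNA"])
  cnt <- table(factor(long, levels = mirnas))
  tibble(mirna = mirnas, degree = as.integer(cnt))
}

#' Bar chart of a hub ranking
#'
#' @param object A `hub_ranking` from [rank_hubs()].
#' @param ... Unused.
#' @return A ggplot of miRNA degree, highest first.
#' @export
autoplot.hub_ranking <- function(object, ...) {
  df <- dplyr::mutate(object,
                      mirna = factor(.data$mirna, levels = rev(.data$mirna)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$mirna)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "connected mRNAs (degree)", y = NULL)
}

#' mRNAs targeted by multiple miRNAs
#'
#' Reports every mRNA whose number of connected miRNAs in the bipartite view
#' is at least `min_mirnas`, with the connected miRNA IDs, sorted by degree
#' (decreasing) then lexicographically.
#'
#' @param net A bipartite `interaction_network`.
#' @param min_mirnas Minimum miRNA degree (default 3).
#' @return A tibble: `mrna`, `n_mirnas`, `mirnas` (list column of sorted
#'   miRNA IDs).
#' @export
multi_target_genes <- function(net, min_mirnas = 3L) {
  stopifnot(inherits(net, "interaction_network"))
  if (!isTRUE(net$bipartite)) net <- bipartite_view(net)
  if (min_mirnas < 1L) stop("min_mirnas must be at least 1", call. = FALSE)
  pairs <- dplyr::bind_rows(
    dplyr::filter(net$edges, .data$class_a == "mRNA") |>
      dplyr::transmute(mrna = .data$node_a, mirna = .data$node_b),
    dplyr::filter(net$edges, .data$class_b == "mRNA") |>
      dplyr::transmute(mrna = .data$node_b, mirna = .data$node_a)
  )
  pairs |>
    dplyr::group_by(.data$mrna) |>
    dplyr::summarise(n_mirnas = dplyr::n(),
                     mirnas = list(sort(.data$mirna)), .groups = "drop") |>
    dplyr::filter(.data$n_mirnas >= min_mirnas) |>
    dplyr::arrange(dplyr::desc(.data$n_mirnas), .data$mrna)
}

#' Subnetwork induced by a set of miRNAs
#'
#' Restricts the bipartite network to the listed miRNAs plus every mRNA
#' adjacent to at least one of them, keeping only the edges among the
#' retained nodes.
#'
#' @param net A bipartite `interaction_network`.
#' @param mirna_ids miRNA node IDs; all must exist in the network.
#' @return An `interaction_network` (bipartite).
#' @export
extract_subnetwork <- function(net, mirna_ids) {
  stopifnot(inherits(net, "interaction_network"))
  if (!isTRUE(net$bipartite)) net <- bipartite_view(net)
  known <- net$nodes$id[net$nodes$class == "miRNA"]
  unknown <- setdiff(mirna_ids, known)
  if (length(unknown)) {
    stop(sprintf("unknown miRNA ID(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  edges <- dplyr::filter(net$edges,
                         (.data$class_a == "miRNA" & .data$node_a %in% mirna_ids) |
                           (.data$class_b == "miRNA" & .data$node_b %in% mirna_ids))
  keep <- union(mirna_ids, setdiff(c(edges$node_a, edges$node_b), mirna_ids))
  nodes <- dplyr::filter(net$nodes, .data$id %in% keep)
  new_interaction_network(nodes, edges, bipartite = TRUE)
}

#' Write a network edge list to TSV
#'
#' One line per edge with columns `node_a`, `node_b`, `class_a`, `class_b`,
#' ordered lexicographically (and `node_a < node_b` within each edge), so the
#' output is deterministic for a given network.
#'
#' @param net An `interaction_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  df <- as.data.frame(net$edges[, c("node_a", "node_b", "class_a", "class_b")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#'
#' @param path Path to an edge-list TSV.
#' @param nodes Optional node table (`id`, `class`) for isolated nodes; by
#'   default the node set is the union of edge endpoints.
#' @return An `interaction_network`.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", comment.char = "", quote = "")
  if (is.null(nodes)) {
    nodes <- dplyr::distinct(dplyr::bind_rows(
      tibble(id = df$node_a, class = df$class_a),
      tibble(id = df$node_b, class = df$class_b)
    )) |> dplyr::arrange(.data$id)
  }
  interaction_network(nodes, tibble(node_a = df$node_a, node_b = df$node_b))
}

#' Convert a network to an igraph object
#'
#' @param net An `interaction_network`.
#' @return An undirected `igraph` graph with a `class` vertex attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as_igraph()", call. = FALSE)
  }
  igraph::graph_from_data_frame(
    d = net$edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, class = net$nodes$class)
  )
}
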