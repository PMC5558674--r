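test_that("networks are built by thresholding the precision matrix", {
  ids <- c("mir1", "mir2", "g1", "g2")
  classes <- c("miRNA", "miRNA", "mRNA", "mRNA")
  th <- diag(4)
  dimnames(th) <- list(ids, ids)
  expect_equal(nrow(build_network(fake_fit(th, classes))$edges), 0L)

  th2 <- th
  th2["mir1", "g1"] <- th2["g1", "mir1"] <- -0.2
  net <- build_network(fake_fit(th2, classes))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$node_a, "g1")  # lexicographic within the pair
  expect_equal(net$edges$node_b, "mir1")
  expect_equal(net$edges$weight, 0.2)

  expect_error(build_network(fake_fit(th2, classes, converged = FALSE)),
               "converge")
  expect_silent(build_network(fake_fit(th2, classes, converged = FALSE),
                              force = TRUE))
})

test_that("edge counts match a brute-force scan and shrink as the threshold grows", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- 12
    ids <- sprintf("f%02d", 1:m)
    th <- matrix(0, m, m, dimnames = list(ids, ids))
    pairs <- which(upper.tri(th))
    nz <- sample(pairs, 15)
    th[nz] <- runif(15, -0.5, 0.5)
    th <- th + t(th) + diag(m)
    classes <- rep(c("miRNA", "mRNA"), length.out = m)
    for (eps in c(1e-8, 0.1, 0.3)) {
      net <- build_network(fake_fit(th, classes), edge_eps = eps)
      brute <- 0
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        if (abs(th[i, j]) > eps) brute <- brute + 1
      }
      expect_equal(nrow(net$edges), brute)
    }
    n_small <- nrow(build_network(fake_fit(th, classes), edge_eps = 1e-8)$edges)
    n_large <- nrow(build_network(fake_fit(th, classes), edge_eps = 0.3)$edges)
    expect_lte(n_large, n_small)
  }
})

test_that("the bipartite view keeps exactly the cross-class edges and is idempotent", {
  same_class <- interaction_network(
    data.frame(id = c("mir1", "mir2", "g1"),
               class = c("miRNA", "miRNA", "mRNA")),
    data.frame(node_a = "mir1", node_b = "mir2"))
  expect_equal(nrow(bipartite_view(same_class)$edges), 0L)
  expect_equal(nrow(bipartite_view(same_class)$nodes), 3L)  # nodes unchanged

  for (seed in 1:10) {
    net <- random_network(4, 8, p_edge = 0.3, seed = seed)
    bip <- bipartite_view(net)
    same <- sum(net$edges$class_a == net$edges$class_b)
    expect_equal(nrow(bip$edges), nrow(net$edges) - same)
    expect_identical(bipartite_view(bip)$edges, bip$edges)
  }
})

test_that("hub ranking is degree-sorted with lexicographic ties and excludes isolated miRNAs", {
  net <- interaction_network(
    data.frame(id = c("mirB", "mirA", "mirC", paste0("g", 1:5)),
               class = rep(c("miRNA", "mRNA"), c(3, 5))),
    data.frame(node_a = c("mirB", "mirB", "mirA", "mirA"),
               node_b = c("g1", "g2", "g3", "g4")))
  r <- rank_hubs(net)
  expect_equal(r$mirna, c("mirA", "mirB"))  # tie at degree 2 broken by ID
  expect_equal(r$degree, c(2L, 2L))         # mirC (degree 0) excluded
  expect_equal(rank_hubs(net, top_k = 1)$mirna, "mirA")
  expect_error(rank_hubs(net, top_k = 0), "at least 1")
})

test_that("multi-target query equals a brute-force degree filter", {
  net <- interaction_network(
    data.frame(id = c("m1", "m2", "m3", "gX", "gY"),
               class = rep(c("miRNA", "mRNA"), c(3, 2))),
    data.frame(node_a = c("m1", "m2", "m3", "m1", "m2"),
               node_b = c("gX", "gX", "gX", "gY", "gY")))
  out <- multi_target_genes(net, min_mirnas = 3)
  expect_equal(out$mrna, "gX")  # gY has only 2 miRNAs
  expect_equal(out$mirnas[[1]], c("m1", "m2", "m3"))
  expect_error(multi_target_genes(net, min_mirnas = 0), "at least 1")

  for (seed in 1:10) {
    rnet <- bipartite_view(random_network(5, 12, p_edge = 0.25, seed = 100 + seed))
    out <- multi_target_genes(rnet, min_mirnas = 2)
    # brute force: count miRNA neighbors of every mRNA by scanning edges
    for (g in rnet$nodes$id[rnet$nodes$class == "mRNA"]) {
      nb <- character()
      for (k in seq_len(nrow(rnet$edges))) {
        e <- rnet$edges[k, ]
        if (e$node_a == g) nb <- c(nb, e$node_b)
        if (e$node_b == g) nb <- c(nb, e$node_a)
      }
      if (length(nb) >= 2) {
        expect_true(g %in% out$mrna)
        expect_equal(sort(nb), out$mirnas[[match(g, out$mrna)]])
      } else {
        expect_false(g %in% out$mrna)
      }
    }
  }
})

test_that("subnetwork extraction is the union of per-miRNA stars", {
  net <- bipartite_view(random_network(5, 15, p_edge = 0.2, seed = 42))
  mirnas <- net$nodes$id[net$nodes$class == "miRNA"]
  s1 <- extract_subnetwork(net, mirnas[1])
  s2 <- extract_subnetwork(net, mirnas[2])
  s12 <- extract_subnetwork(net, mirnas[1:2])
  expect_setequal(union(edge_keys(s1), edge_keys(s2)), edge_keys(s12))
  expect_error(extract_subnetwork(net, "mir99"), "mir99")

  # an isolated miRNA yields itself and no edges
  iso <- interaction_network(
    data.frame(id = c("mLone", "g1"), class = c("miRNA", "mRNA")),
    data.frame(node_a = character(), node_b = character()))
  sub <- extract_subnetwork(iso, "mLone")
  expect_equal(sub$nodes$id, "mLone")
  expect_equal(nrow(sub$edges), 0L)

  # one miRNA with 3 neighbors: 4 nodes, 3 edges
  star <- interaction_network(
    data.frame(id = c("m1", "g1", "g2", "g3", "g4"),
               class = rep(c("miRNA", "mRNA"), c(1, 4))),
    data.frame(node_a = rep("m1", 3), node_b = c("g1", "g2", "g3")))
  s <- extract_subnetwork(star, "m1")
  expect_equal(nrow(s$nodes), 4L)
  expect_equal(nrow(s$edges), 3L)
})

test_that("the handshake identity holds: miRNA degrees and mRNA degrees both sum to the edge count", {
  for (seed in 1:20) {
    bip <- bipartite_view(random_network(6, 10, p_edge = 0.3, seed = 200 + seed))
    deg_mi <- rank_hubs(bip, top_k = 100)
    deg_mr <- multi_target_genes(bip, min_mirnas = 1)
    expect_equal(sum(deg_mi$degree), nrow(bip$edges))
    expect_equal(sum(deg_mr$n_mirnas), nrow(bip$edges))
  }
})

test_that("rankings and reports are deterministic across repeated calls", {
  net <- bipartite_view(random_network(6, 20, p_edge = 0.3, seed = 7))
  expect_identical(rank_hubs(net), rank_hubs(net))
  expect_identical(multi_target_genes(net), multi_target_genes(net))
})
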