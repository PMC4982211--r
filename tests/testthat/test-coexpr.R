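test_that("network edges require |rho| above threshold; sample floor enforced", {
  prof <- rbind(f1 = c(1, 2, 3, 4, 5),
                f2 = c(10, 20, 30, 40, 50),   # rho = +1 with f1
                f3 = c(5, 4, 3, 2, 1),        # rho = -1 with f1
                f4 = c(2, 9, 1, 8, 3))        # scrambled
  colnames(prof) <- sprintf("s%d", 1:5)
  meta <- rbind(data.frame(sample_id = colnames(prof), condition = "A"),
                data.frame(sample_id = sprintf("t%d", 1:5),
                           condition = "B"))
  net <- suppressWarnings(build_network(prof, meta, "A",
                                        rho_threshold = 0.9))
  e <- net$edges
  expect_equal(e$rho[e$u == "f1" & e$v == "f2"], 1, tolerance = 1e-12)
  expect_equal(e$rho[e$u == "f1" & e$v == "f3"], -1, tolerance = 1e-12)
  expect_false(any(e$u == "f4" | e$v == "f4"))  # isolated but retained
  expect_true("f4" %in% net$nodes)

  # exactly four samples: hard error citing the rule
  meta4 <- rbind(data.frame(sample_id = colnames(prof)[1:4],
                            condition = "A"),
                 data.frame(sample_id = sprintf("t%d", 1:5),
                            condition = "B"))
  expect_error(build_network(prof[, 1:4], meta4, "A"),
               "more than four")
  # 5..8 samples: warning recommending more
  expect_warning(build_network(prof, meta, "A"), "recommended")
})

test_that("Spearman edges are invariant to monotone transforms", {
  set.seed(21)
  x <- sort(runif(9))
  prof <- rbind(f1 = x, f2 = exp(3 * x), f3 = x^3 + 7)
  colnames(prof) <- sprintf("s%d", 1:9)
  meta <- rbind(data.frame(sample_id = colnames(prof), condition = "A"),
                data.frame(sample_id = sprintf("t%d", 1:9),
                           condition = "B"))
  net <- build_network(prof, meta, "A")
  expect_equal(nrow(net$edges), 3L)  # all pairs at rho = 1
  expect_equal(net$edges$rho, rep(1, 3), tolerance = 1e-12)
})

test_that("two bridged 3-cliques split into two communities (modularity oracle)", {
  g <- clique_pair_network()
  net <- detect_communities(g, seed = 1)
  memb <- net$membership
  expect_equal(sort(unique(memb)), c("C1", "C2"))
  expect_length(unique(memb[c("a", "b", "c")]), 1L)
  expect_length(unique(memb[c("d", "e", "f")]), 1L)
  expect_false(memb[["a"]] == memb[["d"]])

  # exhaustive modularity maximisation over all 203 partitions of 6 nodes
  parts <- all_partitions(6L)
  mods <- vapply(parts, function(p) {
    igraph::modularity(g, partition_to_membership(p, 6L))
  }, numeric(1))
  best <- partition_to_membership(parts[[which.max(mods)]], 6L)
  expect_equal(igraph::compare(
    best, as.integer(factor(memb[letters[1:6]])),
    method = "adjusted.rand"), 1)
})

test_that("communities smaller than 3 merge into one residual module", {
  g <- clique_pair_network(extra_nodes = c("x", "y"))
  net <- detect_communities(g, seed = 1)
  memb <- net$membership
  expect_equal(unname(memb[c("x", "y")]), c("residual", "residual"))
  expect_equal(sum(memb == "residual"), 2L)
  expect_length(setdiff(unique(memb), "residual"), 2L)

  # sizes (5, 4, 2, 1) -> (5, 4, residual 3), constructed directly
  ring5 <- igraph::make_full_graph(5)
  ring4 <- igraph::make_full_graph(4)
  g2 <- igraph::disjoint_union(ring5, ring4)
  g2 <- igraph::add_vertices(g2, 3)
  g2 <- igraph::add_edges(g2, c(10, 11))  # a 2-node community
  igraph::V(g2)$name <- sprintf("n%02d", 1:12)
  igraph::E(g2)$weight <- 1
  net2 <- detect_communities(g2, seed = 1)
  sizes <- table(net2$membership)
  expect_equal(unname(sizes[["residual"]]), 3L)
  expect_setequal(as.integer(sizes[setdiff(names(sizes), "residual")]),
                  c(5L, 4L))
})

test_that("planted two-block networks are recovered exactly in >=95% of replicates", {
  ok <- 0L
  for (r in 1:100) {
    g <- metacoman:::with_seed(9000 + r, igraph::sample_sbm(
      20, pref.matrix = matrix(c(0.8, 0.05, 0.05, 0.8), 2),
      block.sizes = c(10, 10)))
    igraph::V(g)$name <- sprintf("n%02d", 1:20)
    net <- detect_communities(g, seed = 1)
    lab <- as.integer(factor(net$membership))
    ari <- igraph::compare(lab, rep(1:2, each = 10),
                           method = "adjusted.rand")
    if (isTRUE(all.equal(ari, 1))) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("modularity of the detected partition beats all-singletons", {
  set.seed(4)
  for (i in 1:10) {
    g <- igraph::sample_gnp(15, 0.25)
    igraph::V(g)$name <- sprintf("v%02d", 1:15)
    if (igraph::ecount(g) == 0) next
    net <- detect_communities(g, seed = 1)
    memb <- as.integer(factor(net$pre_merge_membership))
    expect_gte(igraph::modularity(g, memb),
               igraph::modularity(g, seq_len(15)))
  }
})

test_that("hub detection follows the top-fraction-with-ties rule", {
  star <- igraph::make_star(10, mode = "undirected")
  igraph::V(star)$name <- c("center", sprintf("leaf%d", 1:9))
  net <- detect_communities(star, seed = 1)
  hubs <- find_hubs(net, top_fraction = 0.05)
  expect_equal(as.character(hubs), "center")
  expect_false(attr(hubs, "degenerate"))

  # regular graph: everyone ties, flagged degenerate
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- sprintf("r%d", 1:8)
  netr <- detect_communities(ring, seed = 1)
  hr <- find_hubs(netr)
  expect_length(hr, 8L)
  expect_true(attr(hr, "degenerate"))

  # top fraction of a 100-node graph returns at least 5 nodes
  set.seed(6)
  big <- igraph::sample_gnp(100, 0.1)
  igraph::V(big)$name <- sprintf("b%03d", 1:100)
  netb <- detect_communities(big, seed = 1)
  expect_gte(length(find_hubs(netb, 0.05)), 5L)

  # edgeless network has no hubs
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- c("p", "q", "r")
  nete <- detect_communities(empty, seed = 1)
  expect_length(find_hubs(nete), 0L)
})
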