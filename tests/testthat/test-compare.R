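test_that("rank-sum DE matches enumeration on the classic separated case", {
  prof <- rbind(f1 = c(1, 2, 3, 4, 5, 6) / 21)
  colnames(prof) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample_id = colnames(prof),
                     condition = rep(c("A", "B"), each = 3))
  de <- wilcoxon_de(prof, meta)
  expect_equal(de$p_value, 0.10)  # 2 / C(6,3) extreme assignments
  expect_equal(de$direction, "up")
  expect_true(de$log2_fc > 0)
})

test_that("identical groups give p = 1 and zero fold change", {
  prof <- rbind(f1 = rep(0.5, 6))
  colnames(prof) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample_id = colnames(prof),
                     condition = rep(c("A", "B"), each = 3))
  de <- wilcoxon_de(prof, meta, pseudocount = 1e-6)
  expect_equal(de$p_value, 1)
  expect_equal(de$log2_fc, 0)
})

test_that("BH adjustment is order-invariant and step-up monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(3)
  for (i in 1:10) {
    pv <- runif(20)
    adj <- stats::p.adjust(pv, "BH")
    perm <- sample(20)
    expect_equal(stats::p.adjust(pv[perm], "BH"), adj[perm])
    o <- order(pv)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("most-varied selection prefers FDR hits, falls back to top fold changes", {
  de <- data.frame(feature_id = c("a", "b", "c"),
                   log2_fc = c(2, -1, 0.5),
                   p_value = c(0.001, 0.5, 0.9),
                   fdr = c(0.05, 0.5, 0.9))
  sel <- select_most_varied(de, fdr_cutoff = 0.10)
  expect_equal(sel$features, "a")
  expect_equal(sel$selection_mode, "fdr_significant")

  # none significant: 120 up, 80 down -> 50 + 50
  set.seed(2)
  de2 <- data.frame(feature_id = sprintf("f%03d", 1:200),
                    log2_fc = c(runif(120, 0.1, 3), runif(80, -3, -0.1)),
                    p_value = runif(200, 0.2, 1),
                    fdr = runif(200, 0.5, 1))
  sel2 <- select_most_varied(de2, fdr_cutoff = 0.10)
  expect_equal(sel2$selection_mode, "top_fold_change")
  expect_length(sel2$features, 100L)
  expect_length(intersect(sel2$features, sprintf("f%03d", 1:120)), 50L)

  # 30 up / 60 down -> 30 + 50
  de3 <- de2[c(1:30, 121:180), ]
  sel3 <- select_most_varied(de3, fdr_cutoff = 0.10)
  expect_length(sel3$features, 80L)
  expect_true(all(sel3$features %in% de3$feature_id))
})

test_that("most-varied output is always a subset and capped at 100", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:300, 1)
    de <- data.frame(feature_id = sprintf("f%03d", 1:n),
                     log2_fc = rnorm(n),
                     p_value = runif(n, 0.3, 1),
                     fdr = runif(n, 0.5, 1))
    sel <- select_most_varied(de)
    expect_true(all(sel$features %in% de$feature_id))
    expect_lte(length(sel$features), 100L)
    expect_false(anyDuplicated(sel$features) > 0)
  }
})

test_that("MDS embeds collinear samples on one axis and is deterministic", {
  prof <- rbind(f1 = c(0, 1, 2), f2 = c(0, 0, 0))
  colnames(prof) <- c("s1", "s2", "s3")
  m <- mds_ordination(prof, dissimilarity = "euclidean", k = 1)
  d_emb <- as.matrix(dist(m$points))
  expect_equal(d_emb["s1", "s3"], 2, tolerance = 1e-9)
  expect_equal(d_emb["s1", "s2"], 1, tolerance = 1e-9)
  # all information on axis 1
  expect_lt(abs(m$eigenvalues[2]), 1e-9)

  # identical samples land on identical coordinates
  prof2 <- rbind(f1 = c(0.2, 0.2, 0.9, 0.3), f2 = c(0.8, 0.8, 0.1, 0.7))
  colnames(prof2) <- sprintf("s%d", 1:4)
  m2 <- mds_ordination(prof2)
  expect_lt(sqrt(sum((m2$points["s1", ] - m2$points["s2", ])^2)), 1e-6)

  # determinism
  m3 <- mds_ordination(prof2)
  expect_identical(m2$points, m3$points)

  expect_error(mds_ordination(prof2[, 1:2]), "at least 3")
})

test_that("type-I error is calibrated on null Dirichlet profiles", {
  # both conditions drawn from the same distribution; raw p < 0.05 should
  # occur for about 5% of features (within binomial sampling error)
  cfg <- simulation_config(n_samples_per_condition = 9, n_features = 200,
                           reads_per_sample = 20000, planted_de = NULL,
                           seed = 424)
  sim <- simulate_feature_counts(cfg)
  prof <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  de <- wilcoxon_de(prof, sim$metadata)
  frac <- mean(de$p_value < 0.05)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})
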