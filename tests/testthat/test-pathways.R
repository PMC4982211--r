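test_that("set cover finds minimal pathway sets with the stated tie rules", {
  defs <- data.frame(pathway_id = c("P1", "P1", "P2", "P2", "P3"),
                     function_id = c("f1", "f2", "f2", "f3", "f3"))
  res <- infer_minimal_pathways(c("f1", "f2", "f3"), defs)
  expect_setequal(res$pathways, c("P1", "P2"))
  expect_equal(res$mode, "exact")

  # single pathway covering everything wins alone
  defs2 <- data.frame(pathway_id = c("PA", "PA", "PB"),
                      function_id = c("f1", "f2", "f1"))
  expect_equal(infer_minimal_pathways(c("f1", "f2"), defs2)$pathways, "PA")

  # equal observed coverage: lexicographic tie-break
  defs3 <- data.frame(pathway_id = c("P1", "P2", "P2"),
                      function_id = c("f1", "f1", "f2"))
  expect_equal(infer_minimal_pathways("f1", defs3)$pathways, "P1")

  # observed functions outside every definition are dropped with a warning
  expect_warning(
    r4 <- infer_minimal_pathways(c("f1", "zzz"), defs3),
    "dropped")
  expect_equal(r4$dropped, "zzz")
  expect_error(infer_minimal_pathways(character(0), defs3))
  expect_error(suppressWarnings(infer_minimal_pathways("zzz", defs3)))
})

test_that("exact cover equals brute force on random small instances", {
  set.seed(17)
  for (i in 1:60) {
    n_fun <- sample(3:10, 1)
    n_path <- sample(2:8, 1)
    funs <- sprintf("f%02d", 1:n_fun)
    sets <- lapply(1:n_path, function(j) {
      sample(funs, sample(1:n_fun, 1))
    })
    names(sets) <- sprintf("P%02d", 1:n_path)
    defs <- data.frame(
      pathway_id = rep(names(sets), lengths(sets)),
      function_id = unlist(sets, use.names = FALSE))
    coverable <- intersect(funs, defs$function_id)
    if (length(coverable) == 0) next
    res <- suppressWarnings(infer_minimal_pathways(funs, defs))
    oracle <- brute_min_cover(sets, coverable)
    expect_length(res$pathways, oracle$size)
    covered <- unique(defs$function_id[defs$pathway_id %in% res$pathways])
    expect_true(all(coverable %in% covered))
  }
})

test_that("greedy mode engages above the exact limit and still covers", {
  set.seed(23)
  funs <- sprintf("f%02d", 1:20)
  sets <- lapply(1:12, function(j) sample(funs, 6))
  names(sets) <- sprintf("P%02d", 1:12)
  defs <- data.frame(pathway_id = rep(names(sets), lengths(sets)),
                     function_id = unlist(sets, use.names = FALSE))
  res <- suppressWarnings(
    infer_minimal_pathways(funs, defs, exact_limit = 5))
  expect_equal(res$mode, "greedy")
  covered <- unique(defs$function_id[defs$pathway_id %in% res$pathways])
  expect_true(all(intersect(funs, defs$function_id) %in% covered))
})

test_that("enrichment reproduces the hand-computed Welch case and guards", {
  de <- data.frame(feature_id = sprintf("f%d", 1:7),
                   log2_fc = c(1, 2, 3, 0, 0, 0, 0))
  defs <- data.frame(pathway_id = "P1", function_id = c("f1", "f2", "f3"))
  res <- pathway_enrichment(de, defs)
  expect_equal(res$statistic, 2 / sqrt(1 / 3), tolerance = 1e-9)
  expect_equal(res$p_value, 0.0741799, tolerance = 1e-4)
  expect_equal(res$direction, "enriched")

  # members identical to the background: no signal
  de0 <- data.frame(feature_id = sprintf("f%d", 1:7), log2_fc = rep(1, 7))
  res0 <- pathway_enrichment(de0, defs)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # sets below the minimum size are skipped
  small <- data.frame(pathway_id = "P2", function_id = c("f1", "f2"))
  expect_warning(res2 <- pathway_enrichment(de, small, min_set_size = 3),
                 "no pathway")
  expect_equal(nrow(res2), 0L)
})

test_that("enrichment p-values are near-uniform under label permutation", {
  # independent null fold-change draws, several random sets each;
  # the pooled p-value distribution should be close to uniform
  set.seed(31)
  ps <- numeric(0)
  for (b in 1:200) {
    fc <- rnorm(100)
    de <- data.frame(feature_id = sprintf("f%03d", 1:100), log2_fc = fc)
    sets <- lapply(1:5, function(j) sample(de$feature_id, 10))
    defs <- data.frame(pathway_id = rep(sprintf("P%d", 1:5), each = 10),
                       function_id = unlist(sets))
    ps <- c(ps, pathway_enrichment(de, defs)$p_value)
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
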