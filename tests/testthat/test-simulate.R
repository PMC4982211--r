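test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_samples_per_condition = 3, n_features = 30,
                           reads_per_sample = 2000, seed = 5,
                           planted_de = c(4, 0.25))
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1$gene_hits, b2$gene_hits)
  expect_identical(b1$ncrna_hits, b2$ncrna_hits)
  expect_identical(b1$truth, b2$truth)

  b3 <- simulate_dataset(simulation_config(
    n_samples_per_condition = 3, n_features = 30, reads_per_sample = 2000,
    seed = 6, planted_de = c(4, 0.25)))
  expect_false(identical(b1$gene_hits, b3$gene_hits))

  # generator leaves the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_dataset(cfg))
  expect_identical(.Random.seed, before)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(n_features = 5, planted_de = rep(4, 6)),
               "more planted")
  expect_error(simulation_config(planted_de = c(4, 0)), "> 0")
  expect_error(simulation_config(ncrna_fraction = 1.2))
})

test_that("profiling a simulated bundle recovers the generating proportions", {
  cfg <- simulation_config(n_samples_per_condition = 3, n_features = 40,
                           reads_per_sample = 50000, planted_de = NULL,
                           dirichlet_concentration = Inf, seed = 91)
  b <- simulate_dataset(cfg)
  # run the real pipeline path: filter ncRNA, assign genes, profile
  counts <- lapply(b$metadata$sample_id, function(s) {
    fl <- flag_ncrna_reads(b$ncrna_hits[[s]])$flagged
    assign_best_gene(b$gene_hits[[s]], exclude_reads = fl)
  })
  names(counts) <- b$metadata$sample_id
  prof <- profile_features(counts, b$maps$gene2ko, system = "KO")
  expected <- b$truth$proportions$A[rownames(prof)]
  # multinomial error at n = 35000 mRNA reads: generous 5 sd on each feature
  for (s in b$metadata$sample_id[b$metadata$condition == "A"]) {
    se <- sqrt(expected * (1 - expected) / 35000)
    expect_true(all(abs(prof[, s] - expected) < 5 * se + 1e-6))
  }
  # decoy ncRNA hits never flag true mRNA reads (their e-values are weak)
  fl <- flag_ncrna_reads(b$ncrna_hits[[1]])$flagged
  expect_false(any(grepl("_r", fl)))
  expect_true(all(grepl("_nc", fl)))
})

test_that("a planted 4x feature shows a ~4x empirical fold change at depth", {
  cfg <- simulation_config(n_samples_per_condition = 3, n_features = 100,
                           reads_per_sample = 100000, planted_de = 4,
                           ncrna_fraction = 0, dirichlet_concentration = Inf,
                           seed = 13)
  sim <- simulate_feature_counts(cfg)
  prof <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  planted <- sim$truth$feature_id
  meanA <- rowMeans(prof[, sim$metadata$condition == "A", drop = FALSE])
  meanB <- rowMeans(prof[, sim$metadata$condition == "B", drop = FALSE])
  fc <- meanB[planted] / meanA[planted]
  # one planted feature among 100: closure deflates 4x only marginally
  expect_gt(fc, 4 * 0.9)
  expect_lt(fc, 4 * 1.1)
})

test_that("null configurations produce exchangeable conditions", {
  cfg <- simulation_config(n_samples_per_condition = 9, n_features = 100,
                           reads_per_sample = 10000, planted_de = NULL,
                           seed = 29)
  sim <- simulate_feature_counts(cfg)
  expect_identical(sim$proportions$A, sim$proportions$B)
  expect_equal(nrow(sim$truth), 0L)
  prof <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  de <- wilcoxon_de(prof, sim$metadata)
  # raw p roughly uniform: no mass pile-up below 0.05 beyond noise
  expect_lt(mean(de$p_value < 0.05), 0.15)
})

test_that("written bundles are byte-identical across runs and readable back", {
  cfg <- simulation_config(n_samples_per_condition = 3, n_features = 20,
                           reads_per_sample = 1000, seed = 44,
                           planted_de = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_bundle(simulate_dataset(cfg), d1)
  write_simulated_bundle(simulate_dataset(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  # round trip through the readers
  h <- read_m8(file.path(d1, "gene_hits", "s01.m8"))
  expect_equal(h, simulate_dataset(cfg)$gene_hits$s01, ignore_attr = TRUE)
  m <- read_metadata(file.path(d1, "metadata.tsv"))
  expect_equal(m$sample_id, sprintf("s%02d", 1:6))
})
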