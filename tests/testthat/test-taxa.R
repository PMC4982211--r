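toy_taxa_inputs <- function() {
  # feature F expressed by two genes in different phyla; counts chosen so
  # per-phylum condition means are A: (5, 5) and B: (13, 7) in count units
  counts <- list(
    a1 = c(gF = 4, gB = 6), a2 = c(gF = 6, gB = 4),
    b1 = c(gF = 12, gB = 8), b2 = c(gF = 14, gB = 6))
  annot <- data.frame(gene_id = c("gF", "gB"), feature_id = "F")
  phyla <- data.frame(gene_id = c("gF", "gB"),
                      phylum = c("Firmicutes", "Bacteroidetes"))
  meta <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     condition = c("A", "A", "B", "B"))
  list(counts = counts, annot = annot, phyla = phyla, meta = meta)
}

test_that("contribution shares implement the additive phylum decomposition", {
  x <- toy_taxa_inputs()
  # per-sample totals: 10, 10, 20, 20 -> relative components
  # Firmicutes: A mean (0.4+0.6)/2 = 0.5, B mean (0.6+0.7)/2 = 0.65
  # Bacteroidetes: A mean 0.5, B mean 0.35
  res <- taxon_contribution(x$counts, x$annot, x$phyla, x$meta, "F")
  expect_equal(nrow(res), 2L)
  fir <- res[res$phylum == "Firmicutes", ]
  bac <- res[res$phylum == "Bacteroidetes", ]
  expect_equal(fir$delta, 0.15, tolerance = 1e-12)
  expect_equal(bac$delta, -0.15, tolerance = 1e-12)
  expect_equal(fir$share + bac$share, 1)
  expect_equal(unique(res$top_phylum), "Bacteroidetes")  # tie -> lexicographic
})

test_that("contribution flags no-variation features and drops zero features", {
  counts <- list(a1 = c(g1 = 5), b1 = c(g1 = 5))
  annot <- data.frame(gene_id = "g1", feature_id = "F")
  phyla <- data.frame(gene_id = "g1", phylum = "Firmicutes")
  meta <- data.frame(sample_id = c("a1", "b1"), condition = c("A", "B"))
  res <- taxon_contribution(counts, annot, phyla, meta, "F")
  expect_true(res$no_variation)
  expect_true(is.na(res$share))

  expect_warning(
    res2 <- taxon_contribution(counts, annot, phyla, meta, c("F", "G")),
    "zero reads")
  expect_false("G" %in% res2$feature_id)
})

test_that("single-phylum features concentrate the whole share", {
  # feature F carried by one phylum; feature G keeps the totals non-trivial
  counts <- list(a1 = c(g1 = 5, g2 = 5), b1 = c(g1 = 9, g2 = 1))
  annot <- data.frame(gene_id = c("g1", "g2"), feature_id = c("F", "G"))
  phyla <- data.frame(gene_id = c("g1", "g2"),
                      phylum = c("Firmicutes", "Bacteroidetes"))
  meta <- data.frame(sample_id = c("a1", "b1"), condition = c("A", "B"))
  res <- taxon_contribution(counts, annot, phyla, meta, "F")
  expect_equal(res$share, 1)
  expect_equal(res$top_phylum, "Firmicutes")
  expect_equal(res$delta, 0.9 - 0.5)
})

test_that("distribution gives per-condition phylum fractions that sum to 1", {
  x <- toy_taxa_inputs()
  res <- taxon_distribution(x$counts, x$annot, x$phyla, x$meta, "F")
  a <- res[res$condition == "A", ]
  expect_equal(sum(a$fraction), 1)
  expect_equal(a$fraction[a$phylum == "Firmicutes"], 0.5)
  b <- res[res$condition == "B", ]
  expect_equal(b$fraction[b$phylum == "Firmicutes"], 0.65)

  # permuting sample order leaves the result unchanged
  res2 <- taxon_distribution(x$counts[c(3, 1, 4, 2)], x$annot, x$phyla,
                             x$meta[c(2, 4, 1, 3), ], "F")
  expect_equal(res, res2)
})

test_that("planted phylum shift is recovered as top contributor", {
  # eight phyla so the compositional dilution of unshifted phyla stays well
  # below the planted 4x boost; planted features = those with a gene in the
  # shifted phylum
  cfg <- simulation_config(
    n_samples_per_condition = 6, n_features = 200, reads_per_sample = 60000,
    planted_de = NULL, phyla = sprintf("Phylum%02d", 1:8),
    planted_phylum_shift = list(phylum = "Phylum03", multiplier = 4),
    dirichlet_concentration = Inf, seed = 77)
  b <- simulate_dataset(cfg)
  shifted_genes <- b$truth$phylum_shift$genes
  planted_features <- unique(
    b$maps$gene2ko$feature_id[b$maps$gene2ko$gene_id %in% shifted_genes])
  expect_gte(length(planted_features), 40L)
  res <- suppressWarnings(taxon_contribution(
    b$truth$gene_counts, b$maps$gene2ko, b$maps$gene2phylum, b$metadata,
    planted_features))
  top <- unique(res[, c("feature_id", "top_phylum")])
  expect_gte(mean(top$top_phylum == "Phylum03", na.rm = TRUE), 0.95)
})

test_that("activation normalises by phylum abundance and is scale-invariant", {
  expr <- rbind(g1 = c(0.10, 0.20, 0.30, 0.40))
  colnames(expr) <- sprintf("s%d", 1:4)
  taxa <- rbind(Firmicutes = c(0.25, 0.5, 0.25, 0.5),
                Bacteroidetes = c(0.75, 0.5, 0.75, 0.5))
  colnames(taxa) <- colnames(expr)
  meta <- data.frame(sample_id = colnames(expr),
                     condition = c("A", "A", "B", "B"))
  res <- transcription_activation(expr, c(g1 = "Firmicutes"), taxa, meta)
  expect_equal(unname(res$normalized["g1", ]), c(0.4, 0.4, 1.2, 0.8))

  # scaling expression and phylum fractions together changes nothing
  # (scaled so columns still sum to <= 1 and stay in fraction units)
  res2 <- transcription_activation(0.5 * expr, c(g1 = "Firmicutes"),
                                   0.5 * taxa, meta)
  expect_equal(res2$normalized, res$normalized)

  # composition-driven change: expression follows abundance exactly
  expr3 <- taxa["Firmicutes", , drop = FALSE] * 0.4
  rownames(expr3) <- "g1"
  res3 <- transcription_activation(expr3, c(g1 = "Firmicutes"), taxa, meta)
  expect_equal(res3$table$p_value, 1)

  # zero phylum abundance with nonzero expression becomes missing
  taxa0 <- taxa
  taxa0["Firmicutes", 1] <- 0
  expect_warning(
    res4 <- transcription_activation(expr, c(g1 = "Firmicutes"), taxa0,
                                     meta),
    "zero phylum")
  expect_true(is.na(res4$normalized["g1", 1]))
})
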