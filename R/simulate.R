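#' Configuration for the synthetic metatranscriptome generator
#'
#' Bundles every knob of [simulate_dataset()] with defaults that emulate a
#' desk-scale two-condition gut-metatranscriptome study: 9 samples per
#' condition, 200 KO features over 400 genes, 20,000 reads per sample of
#' which ~30% derive from non-coding RNA, baseline feature proportions from
#' a symmetric Dirichlet, per-sample biological overdispersion with a
#' Dirichlet precision of 800 (per-feature coefficient of variation around
#' 0.5 at mean abundance), and 10 differentially expressed features planted
#' at 4-fold: five boosted in condition B and five boosted in condition A.
#' The symmetric planting keeps the unplanted features exactly null in
#' relative-abundance space (no compositional-closure shift), the standard
#' construction for benchmarking compositional differential abundance.
#'
#' @param n_samples_per_condition samples per condition (default 9).
#' @param n_features number of KO features (default 200).
#' @param genes_per_feature reference genes per feature (default 2).
#' @param reads_per_sample total reads per sample, ncRNA included
#'   (default 20000).
#' @param ncrna_fraction fraction of reads derived from non-coding RNA
#'   (default 0.3).
#' @param decoy_fraction fraction of mRNA reads that additionally receive an
#'   above-threshold (e-value > 1e-5) decoy hit, so filtering rules are
#'   exercised end to end (default 0.05).
#' @param planted_de multipliers for planted differentially expressed
#'   features (condition B relative to A). Values > 1 are applied in B,
#'   values < 1 are applied as their reciprocal in A. Default
#'   `rep(c(4, 0.25), each = 5)`. `NULL` or empty plants nothing.
#' @param baseline_alpha symmetric Dirichlet parameter for baseline feature
#'   proportions (default 10; moderately uneven community).
#' @param dirichlet_concentration per-sample Dirichlet precision for
#'   biological replicate variation (default 800). `Inf` disables
#'   overdispersion (pure multinomial sampling).
#' @param phyla phylum labels assigned round-robin to genes.
#' @param planted_phylum_shift `NULL`, or `list(phylum =, multiplier =)`:
#'   expression of that phylum's genes is multiplied in condition B.
#' @param planted_bgc_boost `NULL`, or `list(type =, multiplier =)`:
#'   expression of genes in clusters of that BGC type is multiplied in
#'   condition B.
#' @param n_pathways,pathway_size KEGG-style pathway definitions: pathways
#'   are overlapping blocks of `pathway_size` features (default 25 of 10).
#' @param n_bgc,bgc_size BGC definitions: consecutive gene blocks (default
#'   12 clusters of 6 genes, two thirds flagged biosynthetic).
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples_per_condition = 9L,
                              n_features = 200L,
                              genes_per_feature = 2L,
                              reads_per_sample = 20000L,
                              ncrna_fraction = 0.3,
                              decoy_fraction = 0.05,
                              planted_de = rep(c(4, 0.25), each = 5),
                              baseline_alpha = 10,
                              dirichlet_concentration = 800,
                              phyla = c("Actinobacteria", "Bacteroidetes",
                                        "Firmicutes", "Proteobacteria"),
                              planted_phylum_shift = NULL,
                              planted_bgc_boost = NULL,
                              n_pathways = 25L,
                              pathway_size = 10L,
                              n_bgc = 12L,
                              bgc_size = 6L,
                              seed = 1L) {
  cfg <- list(n_samples_per_condition = as.integer(n_samples_per_condition),
              n_features = as.integer(n_features),
              genes_per_feature = as.integer(genes_per_feature),
              reads_per_sample = as.integer(reads_per_sample),
              ncrna_fraction = ncrna_fraction,
              decoy_fraction = decoy_fraction,
              planted_de = planted_de,
              baseline_alpha = baseline_alpha,
              dirichlet_concentration = dirichlet_concentration,
              phyla = phyla,
              planted_phylum_shift = planted_phylum_shift,
              planted_bgc_boost = planted_bgc_boost,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_bgc = as.integer(n_bgc),
              bgc_size = as.integer(bgc_size),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_samples_per_condition >= 1L, n_features >= 1L,
              genes_per_feature >= 1L, reads_per_sample >= 1L,
              baseline_alpha > 0, dirichlet_concentration > 0,
              length(phyla) >= 1L)
  })
  stopifnot_scalar_fraction(cfg$ncrna_fraction, "ncrna_fraction",
                            open_lo = FALSE, open_hi = TRUE)
  if (length(cfg$planted_de) > cfg$n_features) {
    stop("more planted features than features", call. = FALSE)
  }
  if (!is.null(cfg$planted_de) && any(cfg$planted_de <= 0)) {
    stop("planted multipliers must be > 0", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- rep(1, length(alpha))  # degenerate guard
  x / sum(x)
}

# condition-level expected feature proportions under symmetric planting
planted_proportions <- function(base, planted_idx, multipliers) {
  pa <- pb <- base
  if (length(planted_idx)) {
    for (j in seq_along(planted_idx)) {
      m <- multipliers[j]
      i <- planted_idx[j]
      if (m >= 1) pb[i] <- pb[i] * m else pa[i] <- pa[i] / m
    }
  }
  list(A = pa / sum(pa), B = pb / sum(pb))
}

#' Simulate condition-level feature count matrices
#'
#' The light core of the generator: feature-by-sample read counts under the
#' planted design, without gene structure or alignment rows. Used directly
#' for statistical calibration studies; [simulate_dataset()] builds the full
#' input bundle on top of the same model.
#'
#' Model: baseline proportions ~ symmetric Dirichlet(`baseline_alpha`);
#' planted multipliers applied (values > 1 in condition B, reciprocals of
#' values < 1 in condition A) and renormalised; per-sample proportions ~
#' Dirichlet(`dirichlet_concentration` x condition proportions); counts ~
#' Multinomial over features.
#'
#' @param cfg a [simulation_config()].
#' @return list with `counts` (feature-by-sample matrix), `metadata`,
#'   `truth` (data.frame `feature_id`, `multiplier`, `boosted_condition`),
#'   `proportions` (list `A`, `B` of expected per-condition proportions),
#'   `features`.
#' @export
simulate_feature_counts <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, simulate_feature_counts_impl(cfg))
}

simulate_feature_counts_impl <- function(cfg) {
  K <- cfg$n_features
  features <- sprintf("KO_%04d", seq_len(K))
  base <- rdirichlet1(rep(cfg$baseline_alpha, K))
  mult <- cfg$planted_de %||% numeric(0)
  planted_idx <- if (length(mult)) sort(sample.int(K, length(mult))) else
    integer(0)
  props <- planted_proportions(base, planted_idx, mult)
  names(props$A) <- names(props$B) <- features
  n <- cfg$n_samples_per_condition
  samples <- sprintf("s%02d", seq_len(2L * n))
  condition <- rep(c("A", "B"), each = n)
  meta <- data.frame(sample_id = samples, condition = condition,
                     stringsAsFactors = FALSE)
  n_mrna <- round(cfg$reads_per_sample * (1 - cfg$ncrna_fraction))
  counts <- matrix(0, nrow = K, ncol = length(samples),
                   dimnames = list(features, samples))
  for (j in seq_along(samples)) {
    pc <- if (condition[j] == "A") props$A else props$B
    theta <- if (is.finite(cfg$dirichlet_concentration)) {
      rdirichlet1(cfg$dirichlet_concentration * pc)
    } else {
      pc
    }
    counts[, j] <- rmultinom(1L, n_mrna, theta)[, 1L]
  }
  truth <- data.frame(
    feature_id = features[planted_idx],
    multiplier = mult,
    boosted_condition = ifelse(mult >= 1, "B", "A"),
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = validate_metadata(meta), truth = truth,
       proportions = props, features = features)
}

#' Simulate a complete pipeline input bundle with planted signals
#'
#' Builds everything the pipeline consumes, entirely from one seed:
#' per-sample reads-vs-gene and reads-vs-ncRNA alignment tables in BLAST
#' tabular layout (with above-threshold decoy hits so the e-value filters
#' are exercised), gene-to-KO/COG/EC and gene-to-phylum annotation maps,
#' KEGG-style and MetaCyc-style hierarchy and pathway-definition tables, BGC
#' definitions, sample metadata, a phylum-by-sample metagenomic taxa
#' profile, and truth tables recording every planted signal.
#'
#' Gene-level structure: each feature's expression is split over its genes
#' with fixed random weights; optional phylum or BGC-type boosts multiply
#' the affected genes' expression in condition B before per-sample
#' multinomial sampling.
#'
#' @param cfg a [simulation_config()].
#' @return a list of class `sim_bundle`; see Details. Main elements:
#'   `metadata`, `gene_hits` (named list of m8 data.frames), `ncrna_hits`,
#'   `maps` (`gene2ko`, `gene2cog`, `gene2ec`, `gene2phylum`), `hierarchy`
#'   (`ko2pathway`, `pathway2class`, `cog2category`, `ec2metacyc`),
#'   `pathway_defs` (`kegg`, `metacyc`), `bgc_defs`, `taxa_profile`,
#'   `truth`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  fc <- simulate_feature_counts_impl(cfg)  # consumes RNG deterministically
  K <- cfg$n_features
  gpf <- cfg$genes_per_feature
  features <- fc$features
  genes <- sprintf("gene_%05d", seq_len(K * gpf))
  gene_feature <- rep(features, each = gpf)
  # fixed within-feature expression weights
  w <- rgamma(length(genes), shape = 5)
  w_split <- split(w, gene_feature)[features]
  w <- unlist(lapply(w_split, function(x) x / sum(x)), use.names = FALSE)

  maps <- list(
    gene2ko = data.frame(gene_id = genes, feature_id = gene_feature,
                         stringsAsFactors = FALSE),
    gene2cog = data.frame(
      gene_id = genes,
      feature_id = sprintf("COG_%04d", ((seq_along(genes) - 1L) %/% 4L) + 1L),
      stringsAsFactors = FALSE),
    gene2ec = data.frame(
      gene_id = genes,
      feature_id = sprintf("EC_%03d", ((seq_along(genes) - 1L) %/% 5L) + 1L),
      stringsAsFactors = FALSE),
    gene2phylum = data.frame(
      gene_id = genes,
      phylum = cfg$phyla[((seq_along(genes) - 1L) %% length(cfg$phyla)) + 1L],
      stringsAsFactors = FALSE))

  hierarchy <- make_hierarchies(cfg, features, maps)
  bgc_defs <- make_bgc_defs(cfg, genes)

  # per-condition gene probabilities; boosts act at the gene level
  base_gene <- function(props) props[gene_feature] * w
  pg <- list(A = base_gene(fc$proportions$A), B = base_gene(fc$proportions$B))
  shift_genes <- character(0)
  if (!is.null(cfg$planted_phylum_shift)) {
    s <- cfg$planted_phylum_shift
    shift_genes <- maps$gene2phylum$gene_id[maps$gene2phylum$phylum ==
                                              s$phylum]
    pg$B[genes %in% shift_genes] <- pg$B[genes %in% shift_genes] *
      s$multiplier
  }
  boost_genes <- character(0)
  if (!is.null(cfg$planted_bgc_boost)) {
    b <- cfg$planted_bgc_boost
    boost_genes <- bgc_defs$gene_id[bgc_defs$bgc_type == b$type]
    pg$B[genes %in% boost_genes] <- pg$B[genes %in% boost_genes] *
      b$multiplier
  }
  pg <- lapply(pg, function(x) x / sum(x))

  meta <- fc$metadata
  n_mrna <- round(cfg$reads_per_sample * (1 - cfg$ncrna_fraction))
  n_ncrna <- cfg$reads_per_sample - n_mrna
  theta_prec <- cfg$dirichlet_concentration

  gene_hits <- list()
  ncrna_hits <- list()
  gene_counts_truth <- matrix(0, nrow = length(genes), ncol = nrow(meta),
                              dimnames = list(genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    s_id <- meta$sample_id[j]
    pc <- pg[[meta$condition[j]]]
    theta <- if (is.finite(theta_prec)) rdirichlet1(theta_prec * pc) else pc
    gcount <- rmultinom(1L, n_mrna, theta)[, 1L]
    gene_counts_truth[, j] <- gcount
    gene_hits[[s_id]] <- make_gene_m8(s_id, genes, gcount,
                                      cfg$decoy_fraction)
    ncrna_hits[[s_id]] <- make_ncrna_m8(s_id, n_ncrna, n_mrna,
                                        cfg$decoy_fraction)
  }

  taxa_profile <- make_taxa_profile(maps$gene2phylum, cfg$phyla, meta)

  truth <- list(planted_de = fc$truth,
                proportions = fc$proportions,
                gene_weights = setNames(w, genes),
                gene_counts = gene_counts_truth,
                phylum_shift = if (length(shift_genes))
                  list(phylum = cfg$planted_phylum_shift$phylum,
                       multiplier = cfg$planted_phylum_shift$multiplier,
                       genes = shift_genes) else NULL,
                bgc_boost = if (length(boost_genes))
                  list(type = cfg$planted_bgc_boost$type,
                       multiplier = cfg$planted_bgc_boost$multiplier,
                       genes = boost_genes) else NULL)

  structure(list(config = cfg, metadata = meta, gene_hits = gene_hits,
                 ncrna_hits = ncrna_hits, maps = maps,
                 hierarchy = hierarchy,
                 pathway_defs = list(kegg = hierarchy$ko2pathway_defs,
                                     metacyc = hierarchy$ec2metacyc_defs),
                 bgc_defs = bgc_defs, taxa_profile = taxa_profile,
                 truth = truth),
            class = "sim_bundle")
}

make_hierarchies <- function(cfg, features, maps) {
  K <- length(features)
  # overlapping blocks of pathway_size features, stepping so every feature
  # is covered; deterministic layout
  step <- max(1L, ceiling(K / cfg$n_pathways))
  starts <- seq(1L, K, by = step)[seq_len(min(cfg$n_pathways,
                                              ceiling(K / step)))]
  ko2pathway <- do.call(rbind, lapply(seq_along(starts), function(i) {
    idx <- ((starts[i] - 1L + seq_len(cfg$pathway_size) - 1L) %% K) + 1L
    data.frame(feature_id = features[unique(idx)],
               parent_id = sprintf("PW_%03d", i), stringsAsFactors = FALSE)
  }))
  pathway2class <- data.frame(
    feature_id = sprintf("PW_%03d", seq_along(starts)),
    parent_id = sprintf("Class_%d", ((seq_along(starts) - 1L) %% 5L) + 1L),
    stringsAsFactors = FALSE)
  cogs <- sort_c(unique(maps$gene2cog$feature_id))
  cog2category <- data.frame(
    feature_id = cogs,
    parent_id = LETTERS[((seq_along(cogs) - 1L) %% 20L) + 1L],
    stringsAsFactors = FALSE)
  ecs <- sort_c(unique(maps$gene2ec$feature_id))
  n_meta <- max(1L, length(ecs) %/% 6L)
  ec2metacyc <- do.call(rbind, lapply(seq_len(n_meta), function(i) {
    idx <- ((i - 1L) * 6L + seq_len(8L) - 1L) %% length(ecs) + 1L
    data.frame(feature_id = ecs[unique(idx)],
               parent_id = sprintf("META_%03d", i), stringsAsFactors = FALSE)
  }))
  list(ko2pathway = ko2pathway,
       pathway2class = pathway2class,
       cog2category = cog2category,
       ec2metacyc = ec2metacyc,
       ko2pathway_defs = data.frame(pathway_id = ko2pathway$parent_id,
                                    function_id = ko2pathway$feature_id,
                                    stringsAsFactors = FALSE),
       ec2metacyc_defs = data.frame(pathway_id = ec2metacyc$parent_id,
                                    function_id = ec2metacyc$feature_id,
                                    stringsAsFactors = FALSE))
}

make_bgc_defs <- function(cfg, genes) {
  types <- c("NRPS", "PKS", "terpene", "bacteriocin")
  n_bgc <- min(cfg$n_bgc, length(genes) %/% cfg$bgc_size)
  do.call(rbind, lapply(seq_len(n_bgc), function(b) {
    idx <- (b - 1L) * cfg$bgc_size + seq_len(cfg$bgc_size)
    data.frame(cluster_id = sprintf("BGC_%03d", b),
               gene_id = genes[idx],
               # two thirds of member genes are biosynthetic
               biosynthetic = (seq_len(cfg$bgc_size) %% 3L) != 0L,
               bgc_type = types[((b - 1L) %% length(types)) + 1L],
               stringsAsFactors = FALSE)
  }))
}

make_taxa_profile <- function(gene2phylum, phyla, meta) {
  base <- table(factor(gene2phylum$phylum, levels = phyla))
  base <- as.numeric(base) / sum(base)
  m <- vapply(seq_len(nrow(meta)), function(j) {
    rdirichlet1(200 * base)
  }, numeric(length(phyla)))
  dimnames(m) <- list(phyla, meta$sample_id)
  m
}

# one sub-threshold m8 row per read assigned to its true gene, plus decoy
# rows: an above-threshold second hit for a fraction of reads and a worse
# sub-threshold secondary hit for a further fraction (best-hit semantics
# must pick the true gene)
make_gene_m8 <- function(sample_id, genes, gcount, decoy_fraction) {
  total <- sum(gcount)
  if (total == 0L) return(empty_m8())
  read_ids <- sprintf("%s_r%06d", sample_id, seq_len(total))
  gene_of <- rep(genes[gcount > 0], gcount[gcount > 0])
  e_true <- 10^(-runif(total, 8, 40))
  rows <- m8_rows(read_ids, gene_of, e_true)
  n_decoy <- round(decoy_fraction * total)
  if (n_decoy > 0L) {
    pick <- sample.int(total, n_decoy)
    e_decoy <- 10^(-runif(n_decoy, 0, 4.5))  # always >= 1e-4.5 > 1e-5
    decoys <- m8_rows(read_ids[pick],
                      genes[sample.int(length(genes), n_decoy,
                                       replace = TRUE)],
                      e_decoy)
    pick2 <- sample.int(total, n_decoy)
    e_worse <- pmin(e_true[pick2] * 10^runif(n_decoy, 1, 3), 1e-6)
    worse <- m8_rows(read_ids[pick2],
                     genes[sample.int(length(genes), n_decoy,
                                      replace = TRUE)],
                     e_worse)
    rows <- rbind(rows, decoys, worse)
  }
  rows <- rows[order_c(rows$read_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# ncRNA-derived reads hit rRNA/tRNA subjects below threshold; a fraction of
# mRNA reads additionally carries a weak (above-threshold) ncRNA hit that
# the filter must retain
make_ncrna_m8 <- function(sample_id, n_ncrna, n_mrna, decoy_fraction) {
  subjects <- sprintf("rRNA_%03d", 1:50)
  rows <- NULL
  if (n_ncrna > 0L) {
    read_ids <- sprintf("%s_nc%06d", sample_id, seq_len(n_ncrna))
    rows <- m8_rows(read_ids,
                    subjects[sample.int(length(subjects), n_ncrna,
                                        replace = TRUE)],
                    10^(-runif(n_ncrna, 6, 40)))
  }
  n_weak <- round(decoy_fraction * n_mrna)
  if (n_weak > 0L) {
    weak_ids <- sprintf("%s_r%06d", sample_id,
                        sample.int(n_mrna, n_weak))
    weak <- m8_rows(weak_ids,
                    subjects[sample.int(length(subjects), n_weak,
                                        replace = TRUE)],
                    10^(-runif(n_weak, 0, 4.5)))
    rows <- rbind(rows, weak)
  }
  if (is.null(rows)) return(empty_m8())
  rows <- rows[order_c(rows$read_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

m8_rows <- function(read_ids, subjects, e_values) {
  n <- length(read_ids)
  len <- sample(60:100, n, replace = TRUE)
  mism <- sample(0:5, n, replace = TRUE)
  data.frame(read_id = read_ids, subject_id = subjects,
             pct_identity = round(100 * (len - mism) / len, 2),
             aln_length = len, mismatches = mism,
             gap_opens = sample(0:1, n, replace = TRUE),
             q_start = 1, q_end = len,
             s_start = 1, s_end = len,
             e_value = signif(e_values, 3),
             bit_score = round(2 * pmin(-log10(e_values), 180) + 30, 1),
             stringsAsFactors = FALSE)
}

#' Write a simulated bundle to disk as plain-text files
#'
#' Lays the bundle out in the directory structure [pipeline_config()]
#' consumes: `metadata.tsv`, `gene_hits/<sample>.m8`,
#' `ncrna_hits/<sample>.m8`, the annotation and hierarchy maps, pathway and
#' BGC definition TSVs, `taxa_profile.tsv`, and the truth tables under
#' `truth/`.
#'
#' @param bundle a `sim_bundle` from [simulate_dataset()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulated_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  for (d in c("", "gene_hits", "ncrna_hits", "maps", "truth")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }
  wt(bundle$metadata, file.path(dir, "metadata.tsv"))
  for (s in names(bundle$gene_hits)) {
    write_m8(bundle$gene_hits[[s]], file.path(dir, "gene_hits",
                                              paste0(s, ".m8")))
    write_m8(bundle$ncrna_hits[[s]], file.path(dir, "ncrna_hits",
                                               paste0(s, ".m8")))
  }
  for (nm in names(bundle$maps)) {
    wt(bundle$maps[[nm]], file.path(dir, "maps", paste0(nm, ".tsv")))
  }
  for (nm in c("ko2pathway", "pathway2class", "cog2category",
               "ec2metacyc")) {
    wt(bundle$hierarchy[[nm]], file.path(dir, "maps", paste0(nm, ".tsv")))
  }
  wt(bundle$pathway_defs$kegg, file.path(dir, "pathway_defs_kegg.tsv"))
  wt(bundle$pathway_defs$metacyc,
     file.path(dir, "pathway_defs_metacyc.tsv"))
  wt(bundle$bgc_defs, file.path(dir, "bgc_defs.tsv"))
  taxa <- data.frame(phylum = rownames(bundle$taxa_profile),
                     bundle$taxa_profile, check.names = FALSE,
                     stringsAsFactors = FALSE)
  wt(taxa, file.path(dir, "taxa_profile.tsv"))
  wt(bundle$truth$planted_de, file.path(dir, "truth", "planted_de.tsv"))
  props <- data.frame(feature_id = names(bundle$truth$proportions$A) %||%
                        sprintf("KO_%04d", seq_along(bundle$truth$proportions$A)),
                      prop_A = bundle$truth$proportions$A,
                      prop_B = bundle$truth$proportions$B,
                      stringsAsFactors = FALSE)
  wt(props, file.path(dir, "truth", "proportions.tsv"))
  invisible(dir)
}
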