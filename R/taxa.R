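# feature x phylum x sample decomposition of relative abundance, consistent
# with profile_features(): component(f, p, s) = sum of counts of genes
# annotated to f with phylum p, divided by the per-system annotated total of
# sample s. Returns a long data.table (feature_id, phylum, sample_id, value).
feature_phylum_components <- function(counts, annot, phylum_map,
                                      features = NULL) {
  gm <- if (is.matrix(counts)) counts else gene_count_matrix(counts)
  ann <- unique(annot[, c("gene_id", "feature_id")])
  ann <- ann[ann$gene_id %in% rownames(gm), , drop = FALSE]
  ph <- phylum_lookup(phylum_map)
  dt <- data.table::as.data.table(gm, keep.rownames = "gene_id")
  dt <- data.table::melt(dt, id.vars = "gene_id", variable.name = "sample_id",
                         value.name = "count", variable.factor = FALSE)
  dt <- dt[dt$count > 0, ]
  dt <- merge(dt, data.table::as.data.table(ann), by = "gene_id",
              allow.cartesian = TRUE)
  phyla <- ph[dt$gene_id]
  phyla[is.na(phyla)] <- "Unclassified"
  dt$phylum <- phyla
  # denominator: per-sample total over all (gene, feature) pairs
  totals <- dt[, list(total = sum(count)), by = "sample_id"]
  if (!is.null(features)) dt <- dt[dt$feature_id %in% features, ]
  agg <- dt[, list(count = sum(count)),
            by = c("feature_id", "phylum", "sample_id")]
  agg <- merge(agg, totals, by = "sample_id")
  agg$value <- agg$count / agg$total
  agg[, c("feature_id", "phylum", "sample_id", "value"), with = FALSE]
}

phylum_lookup <- function(phylum_map) {
  if (is.data.frame(phylum_map)) {
    cols <- names(phylum_map)
    g <- phylum_map[[if ("gene_id" %in% cols) "gene_id" else 1L]]
    p <- phylum_map[[if ("phylum" %in% cols) "phylum" else
      if ("feature_id" %in% cols) "feature_id" else 2L]]
    setNames(as.character(p), as.character(g))
  } else {
    stopifnot(!is.null(names(phylum_map)))
    setNames(as.character(phylum_map), names(phylum_map))
  }
}

#' Attribute between-condition expression variation to phyla
#'
#' For each selected functional group, its relative abundance in each sample
#' is decomposed additively by the phylum of the contributing genes (exact,
#' since a feature's abundance is a sum over gene components). The
#' per-phylum delta is the mean over non-reference-condition samples minus
#' the mean over reference-condition samples; each phylum's contribution
#' share is its absolute delta over the total absolute delta, and the top
#' phylum is the one with the largest share (ties broken lexicographically).
#'
#' @param counts named list (by sample) of gene-count vectors, or a
#'   gene-by-sample matrix.
#' @param annot gene-to-feature annotation map for one system.
#' @param phylum_map gene-to-phylum map (2-column data.frame or named
#'   character vector); unmapped genes fall under `"Unclassified"`.
#' @param meta sample metadata (two conditions).
#' @param features character vector of feature ids (typically the most
#'   varied set), or a list with a `features` element as returned by
#'   [select_most_varied()].
#' @return data.frame (`feature_id`, `phylum`, `delta`, `share`,
#'   `top_phylum`, `no_variation`), one row per feature-phylum pair with any
#'   reads; `share` is `NA` for features whose deltas are all zero.
#'   Features with zero reads everywhere are dropped with a warning.
#' @export
taxon_contribution <- function(counts, annot, phylum_map, meta, features) {
  if (is.list(features) && !is.null(features$features)) {
    features <- features$features
  }
  meta <- validate_metadata(meta)
  conds <- attr(meta, "conditions")
  comp <- feature_phylum_components(counts, annot, phylum_map, features)
  absent <- setdiff(features, unique(comp$feature_id))
  if (length(absent)) {
    warning("feature(s) with zero reads in all samples dropped: ",
            paste(sort_c(absent), collapse = ", "), call. = FALSE)
  }
  if (nrow(comp) == 0L) {
    return(data.frame(feature_id = character(), phylum = character(),
                      delta = numeric(), share = numeric(),
                      top_phylum = character(), no_variation = logical(),
                      stringsAsFactors = FALSE))
  }
  cond_of <- setNames(meta$condition, meta$sample_id)
  n_cond <- table(factor(meta$condition, levels = conds))
  comp$condition <- cond_of[comp$sample_id]
  sums <- comp[, list(sum_value = sum(value)),
               by = c("feature_id", "phylum", "condition")]
  # mean over ALL samples of the condition (absent samples contribute 0)
  sums$mean_value <- sums$sum_value / as.numeric(n_cond[sums$condition])
  wide <- data.table::dcast(sums, feature_id + phylum ~ condition,
                            value.var = "mean_value", fill = 0)
  for (cc in conds) if (!cc %in% names(wide)) wide[[cc]] <- 0
  wide$delta <- wide[[conds[2L]]] - wide[[conds[1L]]]
  out_list <- lapply(split(wide, wide$feature_id), function(d) {
    tot <- sum(abs(d$delta))
    d <- d[order_c(d$phylum), , drop = FALSE]
    if (tot > 0) {
      d$share <- abs(d$delta) / tot
      top <- d$phylum[order(-d$share, d$phylum, method = "radix")][1L]
      d$top_phylum <- top
      d$no_variation <- FALSE
    } else {
      d$share <- NA_real_
      d$top_phylum <- NA_character_
      d$no_variation <- TRUE
    }
    d
  })
  out <- data.table::rbindlist(out_list)
  out <- as.data.frame(out)[, c("feature_id", "phylum", "delta", "share",
                                "top_phylum", "no_variation")]
  out <- out[order_c(paste(out$feature_id, out$phylum, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-condition taxonomic distribution of feature expression
#'
#' For each (feature, condition) with any reads, the fraction of the
#' feature's summed read counts contributed by each phylum.
#'
#' @inheritParams taxon_contribution
#' @return data.frame (`feature_id`, `condition`, `phylum`, `fraction`);
#'   fractions sum to 1 within each (feature, condition); pairs with no
#'   reads have no rows.
#' @export
taxon_distribution <- function(counts, annot, phylum_map, meta, features) {
  if (is.list(features) && !is.null(features$features)) {
    features <- features$features
  }
  meta <- validate_metadata(meta)
  comp <- feature_phylum_components(counts, annot, phylum_map, features)
  if (nrow(comp) == 0L) {
    return(data.frame(feature_id = character(), condition = character(),
                      phylum = character(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  cond_of <- setNames(meta$condition, meta$sample_id)
  comp$condition <- cond_of[comp$sample_id]
  # raw read counts, not normalised values: recover via value * total is
  # unnecessary — fractions within a feature are identical either way
  sums <- comp[, list(v = sum(value)),
               by = c("feature_id", "condition", "phylum")]
  tot <- sums[, list(tot = sum(v)), by = c("feature_id", "condition")]
  sums <- merge(sums, tot, by = c("feature_id", "condition"))
  sums$fraction <- sums$v / sums$tot
  out <- as.data.frame(sums)[, c("feature_id", "condition", "phylum",
                                 "fraction")]
  out <- out[order_c(paste(out$feature_id, out$condition, out$phylum,
                           sep = "\r")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcription activation analysis
#'
#' Divides expression by the metagenomic abundance of the expressing taxon,
#' sample by sample, to separate genuine transcriptional activation or
#' repression from mere shifts in community composition: if expression and
#' taxon abundance move together, the normalised values are flat across
#' conditions. Normalised values are compared between the two conditions
#' with a Wilcoxon rank-sum test and BH adjustment.
#'
#' @param expr expression matrix, rows = genes (or features attributable to
#'   a single phylum), columns = samples; typically relative abundances.
#' @param phylum_of named character vector mapping each row of `expr` to its
#'   phylum.
#' @param taxa_profile phylum-by-sample metagenomic abundance matrix.
#'   Accepted as fractions (columns summing to <= 1) or counts (normalised
#'   per sample).
#' @param meta sample metadata.
#' @return list with `normalized` (matrix like `expr`, `NA` where the
#'   phylum's abundance is zero) and `table` (per-row Wilcoxon comparison:
#'   `feature_id`, `phylum`, `mean_ref`, `mean_alt`, `p_value`, `fdr`).
#' @export
transcription_activation <- function(expr, phylum_of, taxa_profile, meta) {
  meta <- validate_metadata(meta)
  conds <- attr(meta, "conditions")
  stopifnot(is.matrix(expr), is.matrix(taxa_profile))
  samples <- colnames(expr)
  if (!all(samples %in% colnames(taxa_profile))) {
    stop("taxa profile lacks sample(s): ",
         paste(setdiff(samples, colnames(taxa_profile)), collapse = ", "),
         call. = FALSE)
  }
  taxa <- taxa_profile[, samples, drop = FALSE]
  cs <- colSums(taxa)
  if (any(cs > 1 + 1e-6)) taxa <- sweep(taxa, 2L, cs, "/")
  rows <- rownames(expr)
  ph <- unname(phylum_of[rows])
  if (anyNA(ph)) {
    stop("phylum unknown for row(s): ",
         paste(rows[is.na(ph)], collapse = ", "), call. = FALSE)
  }
  missing_ph <- setdiff(unique(ph), rownames(taxa))
  if (length(missing_ph)) {
    stop("taxa profile lacks phylum(s): ",
         paste(missing_ph, collapse = ", "), call. = FALSE)
  }
  denom <- taxa[ph, samples, drop = FALSE]
  norm <- expr / denom
  zero_denom <- denom == 0
  if (any(zero_denom & expr > 0)) {
    warning(sum(zero_denom & expr > 0), " value(s) with zero phylum ",
            "abundance but nonzero expression set to NA", call. = FALSE)
  }
  norm[zero_denom] <- NA_real_
  dimnames(norm) <- dimnames(expr)

  cond_of <- setNames(meta$condition, meta$sample_id)[samples]
  ref_cols <- samples[cond_of == conds[1L]]
  alt_cols <- samples[cond_of == conds[2L]]
  p <- m_ref <- m_alt <- rep(NA_real_, nrow(norm))
  for (i in seq_len(nrow(norm))) {
    x <- norm[i, alt_cols]
    y <- norm[i, ref_cols]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) next
    m_ref[i] <- mean(y)
    m_alt[i] <- mean(x)
    if (length(unique(c(x, y))) == 1L) {
      p[i] <- 1
    } else {
      p[i] <- suppressWarnings(wilcox.test(x, y)$p.value)
    }
  }
  tab <- data.frame(feature_id = rows, phylum = ph, mean_ref = m_ref,
                    mean_alt = m_alt, p_value = p,
                    fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  tab <- tab[order_c(tab$feature_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(normalized = norm, table = tab)
}
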