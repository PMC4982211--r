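#' Assign each read to its best-hit reference gene
#'
#' Reads-vs-reference-gene hits for one sample are reduced to one gene per
#' read: the gene of the best hit (minimum e-value, ties by maximum bit
#' score then lexicographic subject id) provided that best e-value is
#' strictly below `threshold`. Reads whose best hit fails the cutoff are left
#' unassigned; each retained read contributes exactly one count.
#'
#' @param hits reads-vs-gene alignment table for one sample.
#' @param threshold e-value cutoff, strict (default `1e-5`).
#' @param exclude_reads optional character vector of read ids to drop before
#'   assignment (e.g. reads flagged as ncRNA-derived).
#' @return named numeric vector of read counts per gene (names sorted
#'   ascending); zero-length when nothing is assignable.
#' @export
assign_best_gene <- function(hits, threshold = 1e-5, exclude_reads = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive e-value", call. = FALSE)
  }
  if (!is.null(exclude_reads) && nrow(hits) > 0L) {
    hits <- hits[!(hits$read_id %in% exclude_reads), , drop = FALSE]
  }
  bh <- best_hits(hits)
  bh <- bh[bh$e_value < threshold, , drop = FALSE]
  if (nrow(bh) == 0L) return(setNames(numeric(0), character(0)))
  tab <- table(bh$subject_id)
  counts <- setNames(as.numeric(tab), names(tab))
  counts[sort_c(names(counts))]
}

#' Stack per-sample gene counts into a gene-by-sample matrix
#'
#' @param counts named list (by sample id) of named count vectors as
#'   returned by [assign_best_gene()].
#' @return numeric matrix, genes in rows (union of all genes, sorted),
#'   samples in columns (list order).
#' @export
gene_count_matrix <- function(counts) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  genes <- sort_c(unique(unlist(lapply(counts, names), use.names = FALSE)))
  m <- matrix(0, nrow = length(genes), ncol = length(counts),
              dimnames = list(genes, names(counts)))
  for (s in names(counts)) {
    v <- counts[[s]]
    if (length(v)) m[names(v), s] <- as.numeric(v)
  }
  m
}

#' Relative-abundance profile of functional features
#'
#' Aggregates best-hit gene counts into feature counts for one annotation
#' system (COG, KO or EC) and normalises each sample to relative abundances.
#' A gene annotated to k features contributes its full read count to each of
#' the k features (counts stay integral before normalisation); the
#' denominator is the per-system annotated total of that sample, so every
#' non-degenerate column sums to one.
#'
#' @param counts named list (by sample) of named gene-count vectors, or a
#'   gene-by-sample matrix.
#' @param annot annotation map: data.frame with columns `gene_id`,
#'   `feature_id` (one row per pair; see [read_annotation_map()]).
#' @param system optional label stored in the `"system"` attribute of the
#'   result (e.g. `"KO"`).
#' @return feature-by-sample numeric matrix of relative abundances; columns
#'   of samples with no annotated reads are all zero (with a warning).
#' @export
profile_features <- function(counts, annot, system = NULL) {
  stopifnot(is.data.frame(annot),
            all(c("gene_id", "feature_id") %in% names(annot)))
  gm <- if (is.matrix(counts)) counts else gene_count_matrix(counts)
  ann <- unique(annot[, c("gene_id", "feature_id")])
  ann <- ann[ann$gene_id %in% rownames(gm), , drop = FALSE]
  features <- sort_c(unique(ann$feature_id))
  prof <- matrix(0, nrow = length(features), ncol = ncol(gm),
                 dimnames = list(features, colnames(gm)))
  if (nrow(ann) > 0L) {
    # sum gene counts into features: one pass over (gene, feature) pairs
    contrib <- gm[ann$gene_id, , drop = FALSE]
    prof <- rowsum(contrib, group = ann$feature_id, reorder = TRUE)
    prof <- prof[features, colnames(gm), drop = FALSE]
  }
  totals <- colSums(prof)
  zero <- totals == 0
  if (any(zero)) {
    warning("sample(s) with no annotated reads: ",
            paste(colnames(prof)[zero], collapse = ", "), call. = FALSE)
    totals[zero] <- 1  # keep the column at exact zero
  }
  prof <- sweep(prof, 2L, totals, "/")
  attr(prof, "system") <- system
  prof
}

#' Roll a profile up one hierarchy level
#'
#' Parent abundance is the sum of the relative abundances of the child
#' features mapped to it; a child with several parents contributes fully to
#' each, and children with no parent are collected under `"Unclassified"`.
#' Because multi-parent children inflate the column total, each column is
#' re-normalised to one afterwards (a no-op when the hierarchy is a
#' partition).
#'
#' @param profile feature-by-sample relative abundance matrix from
#'   [profile_features()] (or a previous rollup).
#' @param hier hierarchy map: data.frame with columns `feature_id`,
#'   `parent_id` ([read_hierarchy_map()]).
#' @param level optional label stored in the result's `"system"` attribute.
#' @return parent-by-sample relative abundance matrix.
#' @export
rollup <- function(profile, hier, level = NULL) {
  stopifnot(is.matrix(profile), is.data.frame(hier),
            all(c("feature_id", "parent_id") %in% names(hier)))
  hier <- unique(hier[, c("feature_id", "parent_id")])
  children <- rownames(profile)
  orphan <- setdiff(children, hier$feature_id)
  if (length(orphan)) {
    hier <- rbind(hier, data.frame(feature_id = orphan,
                                   parent_id = "Unclassified",
                                   stringsAsFactors = FALSE))
  }
  hier <- hier[hier$feature_id %in% children, , drop = FALSE]
  contrib <- profile[hier$feature_id, , drop = FALSE]
  up <- rowsum(contrib, group = hier$parent_id, reorder = TRUE)
  totals <- colSums(up)
  totals[totals == 0] <- 1
  up <- sweep(up, 2L, totals, "/")
  attr(up, "system") <- level
  up
}
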