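#' Score biosynthetic gene cluster activity in one sample
#'
#' A cluster is called transcriptionally detected when at least `min_cov`
#' (default 50%) of its biosynthetic genes (non-biosynthetic members are
#' excluded first) carry at least one assigned read. The abundance score of
#' a detected cluster is the mean abundance over its biosynthetic genes;
#' by default uncovered genes enter the mean as zero (penalising partially
#' expressed clusters), with `score_genes = "covered"` averaging over the
#' covered genes only.
#'
#' @param abund named numeric vector of gene abundances for one sample
#'   (read counts or per-sample fractions — the score inherits the unit).
#' @param defs BGC definition table (`cluster_id`, `gene_id`,
#'   `biosynthetic`, `bgc_type`; see [read_bgc_defs()]).
#' @param min_cov detection threshold on the covered fraction (default 0.5).
#' @param score_genes `"all"` (default) or `"covered"`.
#' @return data.frame, one row per cluster with >= 1 biosynthetic gene:
#'   `cluster_id`, `bgc_type`, `n_biosynthetic`, `n_covered`,
#'   `covered_fraction`, `detected`, `score` (`NA` when not detected).
#'   Clusters without biosynthetic genes are skipped with a warning.
#' @export
#' @examples
#' defs <- data.frame(cluster_id = "c1", gene_id = paste0("g", 1:4),
#'                    biosynthetic = TRUE, bgc_type = "NRPS")
#' score_bgc(c(g1 = 10, g2 = 6), defs)  # covered 0.5, detected, score 4
score_bgc <- function(abund, defs, min_cov = 0.5,
                      score_genes = c("all", "covered")) {
  score_genes <- match.arg(score_genes)
  stopifnot_scalar_fraction(min_cov, "min_cov", open_lo = TRUE,
                            open_hi = FALSE)
  stopifnot(is.data.frame(defs),
            all(c("cluster_id", "gene_id", "biosynthetic", "bgc_type") %in%
                  names(defs)))
  bio <- defs[as.logical(defs$biosynthetic), , drop = FALSE]
  skipped <- setdiff(unique(defs$cluster_id), unique(bio$cluster_id))
  if (length(skipped)) {
    warning("cluster(s) without biosynthetic genes skipped: ",
            paste(sort_c(skipped), collapse = ", "), call. = FALSE)
  }
  ids <- sort_c(unique(bio$cluster_id))
  get_abund <- function(g) {
    v <- abund[g]
    v[is.na(v)] <- 0
    unname(v)
  }
  rows <- lapply(ids, function(cid) {
    d <- bio[bio$cluster_id == cid, , drop = FALSE]
    genes <- unique(d$gene_id)
    a <- get_abund(genes)
    n_cov <- sum(a > 0)
    frac <- n_cov / length(genes)
    detected <- frac >= min_cov
    score <- if (!detected) {
      NA_real_
    } else if (score_genes == "all") {
      mean(a)
    } else {
      mean(a[a > 0])
    }
    data.frame(cluster_id = cid, bgc_type = d$bgc_type[1L],
               n_biosynthetic = length(genes), n_covered = n_cov,
               covered_fraction = frac, detected = detected, score = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(cluster_id = character(), bgc_type = character(),
               n_biosynthetic = integer(), n_covered = integer(),
               covered_fraction = numeric(), detected = logical(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Score BGC activity across all samples
#'
#' Applies [score_bgc()] to every sample, by default on gene abundances
#' normalised to the sample's total assigned reads (matching the profiling
#' convention, so scores are comparable across samples).
#'
#' @param counts named list (by sample) of gene-count vectors, or a
#'   gene-by-sample matrix.
#' @param defs BGC definition table.
#' @param min_cov,score_genes passed to [score_bgc()].
#' @param normalize divide each sample's counts by its total before scoring
#'   (default `TRUE`).
#' @return data.frame of per-cluster rows for every sample, with a
#'   `sample_id` column.
#' @export
bgc_abundance <- function(counts, defs, min_cov = 0.5,
                          score_genes = c("all", "covered"),
                          normalize = TRUE) {
  score_genes <- match.arg(score_genes)
  gm <- if (is.matrix(counts)) counts else gene_count_matrix(counts)
  rows <- lapply(colnames(gm), function(s) {
    v <- gm[, s]
    if (normalize && sum(v) > 0) v <- v / sum(v)
    sc <- withCallingHandlers(
      score_bgc(v, defs, min_cov = min_cov, score_genes = score_genes),
      warning = function(w) {
        # per-cluster skip warnings repeat identically per sample
        if (grepl("without biosynthetic genes", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    if (nrow(sc)) sc$sample_id <- s
    sc
  })
  out <- data.table::rbindlist(rows, fill = TRUE)
  as.data.frame(out)
}

#' Compare BGC-type abundance between conditions
#'
#' Per sample, a type's abundance is the sum of the scores of its detected
#' clusters; types detected in no sample are dropped. Each type is then
#' compared between the two conditions with a two-sided Wilcoxon rank-sum
#' test and BH adjustment, and a per-sample type-proportion table is
#' produced for plotting.
#'
#' @param abundances per-cluster, per-sample scores from [bgc_abundance()].
#' @param meta sample metadata.
#' @return list with `type_abundance` (type-by-sample matrix), `de`
#'   (per-type comparison: `bgc_type`, `mean_ref`, `mean_alt`, `log2_fc`,
#'   `p_value`, `fdr`, `direction`), and `proportions` (type-by-sample,
#'   columns summing to 1 where any type is detected).
#' @export
compare_bgc_types <- function(abundances, meta) {
  meta <- validate_metadata(meta)
  conds <- attr(meta, "conditions")
  stopifnot(is.data.frame(abundances),
            all(c("cluster_id", "bgc_type", "sample_id", "detected",
                  "score") %in% names(abundances)))
  if (!any(abundances$detected)) {
    stop("no detected cluster in any sample", call. = FALSE)
  }
  det <- abundances[abundances$detected, , drop = FALSE]
  samples <- meta$sample_id
  types <- sort_c(unique(det$bgc_type))
  ta <- matrix(0, nrow = length(types), ncol = length(samples),
               dimnames = list(types, samples))
  agg <- aggregate(score ~ bgc_type + sample_id, data = det, FUN = sum)
  agg <- agg[agg$sample_id %in% samples, , drop = FALSE]
  ta[cbind(agg$bgc_type, agg$sample_id)] <- agg$score

  cond_of <- setNames(meta$condition, meta$sample_id)[samples]
  ref_cols <- samples[cond_of == conds[1L]]
  alt_cols <- samples[cond_of == conds[2L]]
  eps <- default_pseudocount(ta)
  p <- numeric(length(types))
  m_ref <- rowMeans(ta[, ref_cols, drop = FALSE])
  m_alt <- rowMeans(ta[, alt_cols, drop = FALSE])
  for (i in seq_along(types)) {
    x <- ta[i, alt_cols]
    y <- ta[i, ref_cols]
    if (length(unique(c(x, y))) == 1L) {
      p[i] <- 1
    } else {
      p[i] <- suppressWarnings(wilcox.test(x, y)$p.value)
    }
  }
  lfc <- log2((m_alt + eps) / (m_ref + eps))
  de <- data.frame(bgc_type = types, mean_ref = m_ref, mean_alt = m_alt,
                   log2_fc = lfc, p_value = p,
                   fdr = p.adjust(p, method = "BH"),
                   direction = ifelse(lfc >= 0, "up", "down"),
                   stringsAsFactors = FALSE, row.names = NULL)
  totals <- colSums(ta)
  totals[totals == 0] <- 1
  prop <- sweep(ta, 2L, totals, "/")
  list(type_abundance = ta, de = de, proportions = prop)
}
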