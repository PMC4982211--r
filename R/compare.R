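#' Wilcoxon rank-sum differential expression between two conditions
#'
#' Per feature, a two-sided Wilcoxon rank-sum test of the relative abundance
#' values between the two conditions (exact null distribution when both
#' groups are small and tie-free, otherwise the normal approximation with
#' tie correction — the `stats::wilcox.test` defaults), Benjamini-Hochberg
#' adjustment across all features of the system, and a log2 fold change of
#' condition means with a pseudocount to avoid infinities.
#'
#' The reference condition (fold-change denominator) defaults to the
#' lexicographically smaller condition label; `direction` is `"up"` when the
#' non-reference mean is higher.
#'
#' @param profile feature-by-sample relative abundance matrix.
#' @param meta metadata data.frame (`sample_id`, `condition`); every profile
#'   column must appear in it.
#' @param fdr_cutoff FDR threshold in (0, 1) recorded in the output
#'   attributes and used by [select_most_varied()]; default 0.10.
#' @param pseudocount additive constant for the fold change. Defaults to
#'   half the smallest nonzero value of `profile` (scale-adaptive).
#' @param reference optional condition label to use as reference; must be
#'   one of the two labels.
#' @return data.frame with columns `feature_id`, `mean_ref`, `mean_alt`,
#'   `log2_fc`, `p_value`, `fdr`, `direction`, sorted by feature id.
#'   Attributes: `"conditions"` (`c(ref = ..., alt = ...)`),
#'   `"pseudocount"`, `"fdr_cutoff"`.
#' @export
wilcoxon_de <- function(profile, meta, fdr_cutoff = 0.10,
                        pseudocount = NULL, reference = NULL) {
  stopifnot_scalar_fraction(fdr_cutoff, "fdr_cutoff", open_lo = TRUE,
                            open_hi = TRUE)
  meta <- validate_metadata(meta)
  conds <- attr(meta, "conditions")
  ref <- reference %||% conds[1L]
  if (!ref %in% conds) stop("unknown reference condition: ", ref,
                            call. = FALSE)
  alt <- setdiff(conds, ref)
  samples <- colnames(profile)
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing)) {
    stop("profile samples absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cond_of <- setNames(meta$condition, meta$sample_id)[samples]
  ref_cols <- samples[cond_of == ref]
  alt_cols <- samples[cond_of == alt]
  if (length(ref_cols) == 0L || length(alt_cols) == 0L) {
    stop("each condition needs at least one sample in the profile",
         call. = FALSE)
  }
  eps <- pseudocount %||% default_pseudocount(profile)
  features <- rownames(profile)
  n <- length(features)
  p <- numeric(n)
  m_ref <- rowMeans(profile[, ref_cols, drop = FALSE])
  m_alt <- rowMeans(profile[, alt_cols, drop = FALSE])
  for (i in seq_len(n)) {
    x <- profile[i, alt_cols]
    y <- profile[i, ref_cols]
    if (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L]) {
      p[i] <- 1
    } else {
      p[i] <- suppressWarnings(wilcox.test(x, y)$p.value)
    }
  }
  lfc <- log2((m_alt + eps) / (m_ref + eps))
  out <- data.frame(
    feature_id = features,
    mean_ref = m_ref,
    mean_alt = m_alt,
    log2_fc = lfc,
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order_c(out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conditions") <- c(ref = ref, alt = alt)
  attr(out, "pseudocount") <- eps
  attr(out, "fdr_cutoff") <- fdr_cutoff
  out
}

default_pseudocount <- function(profile) {
  nz <- profile[profile > 0]
  if (length(nz) == 0L) return(1e-9)
  min(nz) / 2
}

#' Select the most varied functional groups
#'
#' If any feature passes the FDR cutoff, all such features are returned
#' (mode `"fdr_significant"`, ordered by increasing FDR then feature id).
#' Otherwise the up-to-50 largest positive and up-to-50 most negative log2
#' fold changes are returned (mode `"top_fold_change"`), with ties on |log2
#' FC| broken by smaller raw p, then feature id.
#'
#' @param de a table from [wilcoxon_de()].
#' @param fdr_cutoff FDR threshold; defaults to the cutoff recorded in `de`,
#'   or 0.10.
#' @param n_top number of features to take per direction in fold-change mode
#'   (default 50 each way).
#' @return list with `features` (character vector, selection order) and
#'   `selection_mode`.
#' @export
select_most_varied <- function(de, fdr_cutoff = NULL, n_top = 50L) {
  stopifnot(is.data.frame(de), nrow(de) > 0L,
            all(c("feature_id", "log2_fc", "p_value", "fdr") %in% names(de)))
  cutoff <- fdr_cutoff %||% attr(de, "fdr_cutoff") %||% 0.10
  sig <- de[de$fdr < cutoff, , drop = FALSE]
  if (nrow(sig) > 0L) {
    sig <- sig[order(sig$fdr, sig$p_value, sig$feature_id,
                     method = "radix"), , drop = FALSE]
    return(list(features = sig$feature_id,
                selection_mode = "fdr_significant"))
  }
  pick <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    o <- order(-abs(d$log2_fc), d$p_value, d$feature_id, method = "radix")
    d$feature_id[o][seq_len(min(n_top, nrow(d)))]
  }
  up <- pick(de[de$log2_fc > 0, , drop = FALSE])
  down <- pick(de[de$log2_fc < 0, , drop = FALSE])
  list(features = c(up, down), selection_mode = "top_fold_change")
}

#' MDS ordination of samples
#'
#' Classical (metric) multidimensional scaling of the sample-by-sample
#' dissimilarity matrix computed from a relative-abundance profile.
#' Bray-Curtis is the default dissimilarity (the field's convention for
#' compositional profiles); Euclidean is available. Axis signs are fixed by
#' making the largest-magnitude coordinate on each axis positive, so the
#' embedding is fully deterministic.
#'
#' @param profile feature-by-sample matrix (>= 3 samples).
#' @param dissimilarity `"bray"` or `"euclidean"`.
#' @param k number of dimensions requested (default 2; truncated to the
#'   number of positive eigenvalues available).
#' @return list with `points` (sample-by-axis coordinate matrix),
#'   `eigenvalues`, and `dissimilarity`.
#' @export
mds_ordination <- function(profile, dissimilarity = c("bray", "euclidean"),
                           k = 2L) {
  dissimilarity <- match.arg(dissimilarity)
  n <- ncol(profile)
  if (n < 3L) stop("MDS needs at least 3 samples, got ", n, call. = FALSE)
  d <- vegan::vegdist(t(profile), method = dissimilarity)
  k_eff <- min(k, n - 1L)
  fit <- suppressWarnings(cmdscale(d, k = k_eff, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (length(i_max) && pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- colnames(profile)
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = fit$eig, dissimilarity = dissimilarity)
}
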