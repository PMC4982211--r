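#' Parsimony pathway inference by minimum set cover
#'
#' Infers the smallest set of pathways that jointly explain every observed
#' function (KO for KEGG, EC for MetaCyc), the parsimony alternative to
#' naive one-hit-per-pathway mapping, which inflates the number of inferred
#' pathways. Observed functions that belong to no pathway definition are
#' dropped with a warning; the cover is computed over the remainder.
#'
#' When at most `exact_limit` candidate pathways contain an observed
#' function, the minimum cover is found exactly (exhaustive search over
#' subsets of increasing size, bounded above by the greedy solution);
#' otherwise the classical greedy set-cover heuristic is used and the result
#' flagged accordingly. Ties among optimal covers are broken by preferring
#' the cover whose pathways individually explain more observed functions,
#' then by lexicographic pathway ids, so the answer is unique.
#'
#' @param observed_functions character vector of observed function ids
#'   (non-empty).
#' @param defs pathway definitions: data.frame with columns `pathway_id`,
#'   `function_id` ([read_pathway_defs()]).
#' @param exact_limit maximum number of candidate pathways for exact search
#'   (default 20).
#' @return list with `pathways` (sorted character vector), `mode`
#'   (`"exact"` or `"greedy"`), `n_covered`, `dropped` (observed functions
#'   in no definition).
#' @export
infer_minimal_pathways <- function(observed_functions, defs,
                                   exact_limit = 20L) {
  stopifnot(is.data.frame(defs),
            all(c("pathway_id", "function_id") %in% names(defs)))
  obs <- unique(as.character(observed_functions))
  if (length(obs) == 0L) stop("no observed functions", call. = FALSE)
  defs <- unique(defs[, c("pathway_id", "function_id")])
  coverable <- intersect(obs, defs$function_id)
  dropped <- setdiff(obs, coverable)
  if (length(dropped)) {
    warning(length(dropped), " observed function(s) belong to no pathway ",
            "definition and were dropped", call. = FALSE)
  }
  if (length(coverable) == 0L) {
    stop("none of the observed functions belongs to any pathway definition",
         call. = FALSE)
  }
  hit <- defs[defs$function_id %in% coverable, , drop = FALSE]
  sets <- split(hit$function_id, hit$pathway_id)
  ids <- sort_c(names(sets))
  sets <- lapply(sets[ids], unique)
  cover_sizes <- lengths(sets)

  greedy <- greedy_cover(sets, ids, cover_sizes, coverable)
  if (length(ids) <= exact_limit) {
    chosen <- exact_cover(sets, ids, cover_sizes, coverable,
                          ub = length(greedy))
    mode <- "exact"
  } else {
    chosen <- greedy
    mode <- "greedy"
  }
  list(pathways = sort_c(chosen), mode = mode,
       n_covered = length(coverable), dropped = dropped)
}

# greedy set cover: repeatedly take the pathway covering most uncovered
# functions; ties by larger total observed coverage, then lexicographic id
greedy_cover <- function(sets, ids, cover_sizes, universe) {
  uncovered <- universe
  chosen <- character(0)
  avail <- rep(TRUE, length(ids))
  while (length(uncovered) > 0L) {
    gain <- vapply(seq_along(ids), function(i) {
      if (!avail[i]) -1L else length(intersect(sets[[i]], uncovered))
    }, integer(1L))
    if (max(gain) <= 0L) break
    best <- which(gain == max(gain))
    if (length(best) > 1L) {
      best <- best[cover_sizes[best] == max(cover_sizes[best])]
      if (length(best) > 1L) best <- best[order_c(ids[best])[1L]]
    }
    best <- best[1L]
    chosen <- c(chosen, ids[best])
    uncovered <- setdiff(uncovered, sets[[best]])
    avail[best] <- FALSE
  }
  chosen
}

# exhaustive minimum cover over subsets of increasing cardinality, upper
# bounded by the greedy solution size; deterministic tie-break
exact_cover <- function(sets, ids, cover_sizes, universe, ub) {
  p <- length(ids)
  # bitmask representation over the coverable universe
  uni_idx <- seq_along(universe)
  names(uni_idx) <- universe
  masks <- lapply(sets, function(s) sort(unname(uni_idx[s])))
  full <- uni_idx
  for (k in seq_len(ub)) {
    combos <- utils::combn(p, k, simplify = FALSE)
    sols <- Filter(function(cmb) {
      length(unique(unlist(masks[cmb], use.names = FALSE))) ==
        length(full)
    }, combos)
    if (length(sols) > 0L) {
      return(ids[pick_best_cover(sols, ids, cover_sizes)])
    }
  }
  # unreachable in practice: greedy always provides a feasible upper bound
  stop("no cover found within the greedy bound", call. = FALSE)
}

# among equal-cardinality covers, prefer larger per-pathway observed
# coverage (sorted decreasing, compared lexicographically), then smaller
# sorted id string
pick_best_cover <- function(sols, ids, cover_sizes) {
  keys <- vapply(sols, function(cmb) {
    cov <- sort(cover_sizes[cmb], decreasing = TRUE)
    paste0(paste(sprintf("%09d", 1e8 - cov), collapse = ","), "|",
           paste(sort_c(ids[cmb]), collapse = ","))
  }, character(1L))
  sols[[order_c(keys)[1L]]]
}

#' Gene-set enrichment of pathways on fold changes
#'
#' Tests, per pathway, whether its member functions' log2 fold changes shift
#' coordinately relative to all non-member functions: a two-sample Welch t
#' test of member vs non-member log2 fold changes, two-sided, with the sign
#' of t giving the direction (`enriched` when members are up relative to the
#' background) and Benjamini-Hochberg adjustment across tested pathways.
#' This is the core two-sample-t-on-fold-changes form of gene-set
#' enrichment; no sample-permutation step is applied (recorded in the
#' `"method"` attribute).
#'
#' @param de a feature-level table from [wilcoxon_de()] (needs `feature_id`
#'   and `log2_fc`).
#' @param defs pathway definitions (`pathway_id`, `function_id`).
#' @param min_set_size pathways with fewer than this many members present in
#'   `de` are skipped (default 3).
#' @return data.frame (`pathway_id`, `set_size`, `statistic`, `p_value`,
#'   `fdr`, `direction`), sorted by pathway id; zero rows with a warning if
#'   no pathway reaches `min_set_size`.
#' @export
pathway_enrichment <- function(de, defs, min_set_size = 3L) {
  stopifnot(is.data.frame(de),
            all(c("feature_id", "log2_fc") %in% names(de)),
            is.data.frame(defs),
            all(c("pathway_id", "function_id") %in% names(defs)))
  fc <- setNames(de$log2_fc, de$feature_id)
  defs <- unique(defs[defs$function_id %in% names(fc), , drop = FALSE])
  members <- split(defs$function_id, defs$pathway_id)
  members <- members[lengths(members) >= min_set_size]
  # pathways containing every scored feature leave no background to test
  members <- members[lengths(members) < length(fc)]
  if (length(members) == 0L) {
    warning("no pathway has >= ", min_set_size,
            " members (and a non-empty background) among the scored features",
            call. = FALSE)
    out <- data.frame(pathway_id = character(), set_size = integer(),
                      statistic = numeric(), p_value = numeric(),
                      fdr = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
    attr(out, "method") <- "welch_t_fold_changes"
    return(out)
  }
  ids <- sort_c(names(members))
  stat <- p <- numeric(length(ids))
  sizes <- integer(length(ids))
  for (i in seq_along(ids)) {
    m <- fc[members[[ids[i]]]]
    b <- fc[setdiff(names(fc), members[[ids[i]]])]
    sizes[i] <- length(m)
    if (stats::sd(c(m, b)) == 0) {
      # members identical to the background: no coordinated shift
      stat[i] <- 0
      p[i] <- 1
    } else if (stats::sd(m) == 0 && stats::sd(b) == 0) {
      # two distinct constants: infinitely strong separation
      stat[i] <- sign(mean(m) - mean(b)) * Inf
      p[i] <- 0
    } else {
      tt <- t.test(m, b, var.equal = FALSE)
      stat[i] <- unname(tt$statistic)
      p[i] <- tt$p.value
    }
  }
  out <- data.frame(pathway_id = ids, set_size = sizes, statistic = stat,
                    p_value = p, fdr = p.adjust(p, method = "BH"),
                    direction = ifelse(stat >= 0, "enriched", "depleted"),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "welch_t_fold_changes"
  out
}
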