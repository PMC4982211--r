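# in-code fixtures shared across the suite

# build an m8 hit row (or several, vectorised over the arguments)
make_hits <- function(read_id, subject_id, e_value, bit_score = 100,
                      pct_identity = 98, aln_length = 100) {
  n <- length(read_id)
  rp <- function(x) rep_len(x, n)
  data.frame(read_id = read_id, subject_id = rp(subject_id),
             pct_identity = rp(pct_identity), aln_length = rp(aln_length),
             mismatches = rp(1), gap_opens = rp(0),
             q_start = rp(1), q_end = rp(aln_length),
             s_start = rp(1), s_end = rp(aln_length),
             e_value = rp(e_value), bit_score = rp(bit_score),
             stringsAsFactors = FALSE)
}

make_meta <- function(n_per_cond = 2, conditions = c("A", "B")) {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(2 * n_per_cond)),
    condition = rep(conditions, each = n_per_cond),
    stringsAsFactors = FALSE)
}

# two 3-cliques joined by one bridge edge, as an igraph object
clique_pair_network <- function(extra_nodes = character(0)) {
  ed <- data.frame(u = c("a", "a", "b", "d", "d", "e", "c"),
                   v = c("b", "c", "c", "e", "f", "f", "d"),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = c(letters[1:6], extra_nodes)))
  igraph::E(g)$weight <- 1
  g
}

# exhaustive two-sided rank-sum p-value by enumerating all group
# assignments (independent of stats::wilcox.test)
enumerate_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2L, function(idx) {
    sum(ranks[idx]) - m * (m + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# hand step-up Benjamini-Hochberg, independent of stats::p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force minimum set cover over all subsets (bitmask), for <= ~15 sets
brute_min_cover <- function(sets, universe) {
  p <- length(sets)
  best_size <- Inf
  best <- NULL
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (length(idx) >= best_size) next
    covered <- unique(unlist(sets[idx], use.names = FALSE))
    if (all(universe %in% covered)) {
      best_size <- length(idx)
      best <- idx
    }
  }
  list(idx = best, size = best_size)
}

# all set partitions of 1..n (for exhaustive modularity maximisation)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

partition_to_membership <- function(p, n) {
  memb <- integer(n)
  for (i in seq_along(p)) memb[p[[i]]] <- i
  memb
}
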