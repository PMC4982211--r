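#' Build a Spearman co-expression network within one condition
#'
#' Pairwise Spearman correlations between features over the samples of one
#' condition; an edge connects every pair with `|rho| >= rho_threshold`
#' (default 0.7). Isolated nodes are retained. A meaningful network needs
#' more than four samples in the condition (hard floor); more than eight is
#' recommended and smaller sizes trigger a warning.
#'
#' @param profile feature-by-sample abundance matrix, typically restricted
#'   to the most varied functional groups.
#' @param meta sample metadata.
#' @param condition which condition's samples to use.
#' @param rho_threshold edge threshold on `|rho|` (default 0.7).
#' @return an object of class `coexpr_network`: list with `graph` (igraph,
#'   undirected, edge attributes `rho` and `weight = |rho|`), `nodes`,
#'   `edges` (data.frame `u`, `v`, `rho`), `condition`, `samples`,
#'   `rho_threshold`.
#' @export
build_network <- function(profile, meta, condition, rho_threshold = 0.7) {
  stopifnot_scalar_fraction(rho_threshold, "rho_threshold", open_lo = FALSE,
                            open_hi = FALSE)
  meta <- validate_metadata(meta)
  if (!condition %in% attr(meta, "conditions")) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  samples <- intersect(colnames(profile),
                       meta$sample_id[meta$condition == condition])
  n <- length(samples)
  if (n <= 4L) {
    stop("co-expression analysis requires more than four samples per ",
         "condition; condition '", condition, "' has ", n, call. = FALSE)
  }
  if (n <= 8L) {
    warning("condition '", condition, "' has only ", n, " samples; more ",
            "than eight is recommended to limit false-positive edges",
            call. = FALSE)
  }
  if (nrow(profile) < 2L) {
    stop("need at least two features to build a network", call. = FALSE)
  }
  sub <- profile[, samples, drop = FALSE]
  rho <- suppressWarnings(cor(t(sub), method = "spearman"))
  if (anyNA(rho)) {
    warning("constant feature(s) produce undefined correlations; treated ",
            "as 0", call. = FALSE)
    rho[is.na(rho)] <- 0
  }
  nodes <- rownames(sub)
  keep <- which(upper.tri(rho) & abs(rho) >= rho_threshold, arr.ind = TRUE)
  edges <- data.frame(u = nodes[keep[, 1L]], v = nodes[keep[, 2L]],
                      rho = rho[keep], stringsAsFactors = FALSE)
  edges <- edges[order_c(paste(edges$u, edges$v, sep = "\r")), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$weight <- abs(edges$rho)
    igraph::E(g)$rho <- edges$rho
  }
  structure(list(graph = g, nodes = nodes, edges = edges,
                 condition = condition, samples = samples,
                 rho_threshold = rho_threshold),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("Co-expression network (condition '", x$condition, "'): ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges (|rho| >= ",
      x$rho_threshold, ")\n", sep = "")
  if (!is.null(x$membership)) {
    sizes <- table(x$membership)
    cat("  communities: ", sum(names(sizes) != "residual"),
        if (any(names(sizes) == "residual")) {
          paste0(" + residual module of ", sizes[["residual"]])
        } else "", "\n", sep = "")
  }
  invisible(x)
}

#' Random-walk community detection with residual-module merging
#'
#' Partitions the network into densely connected communities by
#' agglomerative random-walk (Walktrap) clustering on edge weights `|rho|`,
#' cutting the merge tree at maximum modularity. Isolated nodes form
#' singleton communities. All communities with fewer than 3 members are then
#' merged into one residual module labelled `"residual"`.
#'
#' @param net a `coexpr_network` from [build_network()], or a bare igraph
#'   graph (then wrapped with default metadata).
#' @param walk_steps random-walk length (default 4).
#' @param seed integer seed; the algorithm is deterministic, the seed is
#'   accepted for interface stability and reproducibility guarantees.
#' @param min_size communities smaller than this are merged into the
#'   residual module (default 3).
#' @return the network with added elements `membership` (named character
#'   vector: community label per node, `"C1"`, `"C2"`, ... by decreasing
#'   size, or `"residual"`) and `pre_merge_membership`.
#' @export
detect_communities <- function(net, walk_steps = 4L, seed = 1L,
                               min_size = 3L) {
  if (inherits(net, "igraph")) {
    nodes <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
    if (is.null(igraph::V(net)$name)) {
      igraph::V(net)$name <- nodes
    }
    ed <- igraph::as_data_frame(net, what = "edges")
    net <- structure(list(graph = net, nodes = nodes,
                          edges = data.frame(u = ed$from, v = ed$to,
                                             rho = ed$weight %||%
                                               rep(1, nrow(ed))),
                          condition = NA_character_, samples = character(0),
                          rho_threshold = NA_real_),
                     class = "coexpr_network")
  }
  stopifnot(inherits(net, "coexpr_network"))
  g <- net$graph
  nodes <- net$nodes
  if (length(nodes) == 0L) {
    net$membership <- setNames(character(0), character(0))
    net$pre_merge_membership <- net$membership
    return(net)
  }
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  deg <- igraph::degree(g)
  connected <- names(deg)[deg > 0]
  memb <- integer(0)
  if (length(connected) >= 2L) {
    sub <- igraph::induced_subgraph(g, connected)
    wt <- with_seed(seed, igraph::cluster_walktrap(
      sub, weights = igraph::E(sub)$weight, steps = walk_steps))
    memb <- setNames(igraph::membership(wt), igraph::V(sub)$name)
  }
  # isolated nodes: singleton communities, numbered after the detected ones
  iso <- setdiff(nodes, names(memb))
  if (length(iso)) {
    base <- if (length(memb)) max(memb) else 0L
    memb <- c(memb, setNames(base + seq_along(iso), iso))
  }
  memb <- memb[nodes]
  pre <- memb
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < min_size])
  labels <- character(length(memb))
  names(labels) <- names(memb)
  keep_ids <- setdiff(unique(memb), small)
  if (length(keep_ids)) {
    keep_sizes <- sizes[as.character(keep_ids)]
    ord <- keep_ids[order(-as.integer(keep_sizes), keep_ids)]
    for (i in seq_along(ord)) {
      labels[memb == ord[i]] <- paste0("C", i)
    }
  }
  labels[memb %in% small] <- "residual"
  net$membership <- labels
  net$pre_merge_membership <- setNames(paste0("P", pre), names(pre))
  net$walk_steps <- walk_steps
  net
}

#' Identify hub nodes by connectivity
#'
#' Hubs are the nodes whose degree lies in the top `top_fraction` of the
#' network (at least one node), ties included. An edgeless network has no
#' hubs; if every node has the same (positive) degree the whole network ties
#' and all nodes are returned, flagged degenerate.
#'
#' @param net a `coexpr_network`.
#' @param top_fraction fraction of nodes to call hubs (default 0.05).
#' @return character vector of hub node ids (sorted), with attributes
#'   `"degree"` (their degrees) and `"degenerate"` (all-tied flag).
#' @export
find_hubs <- function(net, top_fraction = 0.05) {
  stopifnot(inherits(net, "coexpr_network"))
  stopifnot_scalar_fraction(top_fraction, "top_fraction", open_lo = TRUE,
                            open_hi = FALSE)
  deg <- igraph::degree(net$graph)
  if (length(deg) == 0L || max(deg) == 0L) {
    out <- character(0)
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  n_top <- max(1L, ceiling(top_fraction * length(deg)))
  cutoff <- sort(deg, decreasing = TRUE)[n_top]
  hubs <- names(deg)[deg >= cutoff & deg > 0]
  degenerate <- length(unique(deg)) == 1L
  out <- sort_c(hubs)
  attr(out, "degree") <- deg[out]
  attr(out, "degenerate") <- degenerate
  out
}

#' Export a network's node and edge tables
#'
#' @param net a `coexpr_network`, ideally after [detect_communities()].
#' @param hubs optional result of [find_hubs()].
#' @return list of data.frames `nodes` (`feature_id`, `degree`,
#'   `community`, `hub`) and `edges` (`u`, `v`, `rho`).
#' @export
network_tables <- function(net, hubs = NULL) {
  stopifnot(inherits(net, "coexpr_network"))
  deg <- igraph::degree(net$graph)
  memb <- net$membership %||% setNames(rep(NA_character_,
                                           length(net$nodes)), net$nodes)
  nodes <- data.frame(feature_id = net$nodes,
                      degree = as.integer(deg[net$nodes]),
                      community = unname(memb[net$nodes]),
                      hub = net$nodes %in% (hubs %||% character(0)),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order_c(nodes$feature_id), , drop = FALSE]
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = net$edges)
}
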