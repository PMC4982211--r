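#' Configuration for the end-to-end pipeline
#'
#' Collects input locations and thresholds. `input_dir` may point at a
#' directory laid out by [write_simulated_bundle()], in which case every
#' path is filled in automatically; individual paths can be overridden or
#' set to `NULL` to disable the stage that needs them (e.g. no taxa profile
#' skips the transcription activation stage).
#'
#' @param input_dir optional bundle directory.
#' @param metadata path to the metadata TSV (required).
#' @param gene_hits_dir directory of per-sample reads-vs-gene m8 files named
#'   `<sample_id>.m8` (required).
#' @param ncrna_hits_dir directory of per-sample reads-vs-ncRNA m8 files;
#'   `NULL` skips ncRNA depletion.
#' @param gene2ko,gene2cog,gene2ec,gene2phylum annotation map TSVs
#'   (gene2ko required; the others optional).
#' @param ko2pathway,pathway2class,cog2category,ec2metacyc hierarchy map
#'   TSVs (optional).
#' @param pathway_defs_kegg,pathway_defs_metacyc pathway definition TSVs
#'   (optional).
#' @param bgc_defs BGC definition TSV (optional).
#' @param taxa_profile phylum-by-sample metagenomic profile TSV (optional).
#' @param evalue e-value cutoff for both filters (default 1e-5).
#' @param fdr FDR cutoff for DE and the most-varied rule (default 0.10).
#' @param rho_threshold co-expression edge threshold (default 0.7).
#' @param bgc_min_cov BGC detection coverage threshold (default 0.5).
#' @param seed integer seed for the stochastic-free stages' interfaces
#'   (community detection).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            metadata = NULL,
                            gene_hits_dir = NULL,
                            ncrna_hits_dir = NULL,
                            gene2ko = NULL,
                            gene2cog = NULL,
                            gene2ec = NULL,
                            gene2phylum = NULL,
                            ko2pathway = NULL,
                            pathway2class = NULL,
                            cog2category = NULL,
                            ec2metacyc = NULL,
                            pathway_defs_kegg = NULL,
                            pathway_defs_metacyc = NULL,
                            bgc_defs = NULL,
                            taxa_profile = NULL,
                            evalue = 1e-5,
                            fdr = 0.10,
                            rho_threshold = 0.7,
                            bgc_min_cov = 0.5,
                            seed = 1L) {
  pick <- function(given, default) {
    if (!is.null(given)) return(given)
    if (!is.null(input_dir) && file.exists(default)) return(default)
    NULL
  }
  if (!is.null(input_dir)) {
    p <- function(...) file.path(input_dir, ...)
    metadata <- pick(metadata, p("metadata.tsv"))
    gene_hits_dir <- pick(gene_hits_dir, p("gene_hits"))
    ncrna_hits_dir <- pick(ncrna_hits_dir, p("ncrna_hits"))
    gene2ko <- pick(gene2ko, p("maps", "gene2ko.tsv"))
    gene2cog <- pick(gene2cog, p("maps", "gene2cog.tsv"))
    gene2ec <- pick(gene2ec, p("maps", "gene2ec.tsv"))
    gene2phylum <- pick(gene2phylum, p("maps", "gene2phylum.tsv"))
    ko2pathway <- pick(ko2pathway, p("maps", "ko2pathway.tsv"))
    pathway2class <- pick(pathway2class, p("maps", "pathway2class.tsv"))
    cog2category <- pick(cog2category, p("maps", "cog2category.tsv"))
    ec2metacyc <- pick(ec2metacyc, p("maps", "ec2metacyc.tsv"))
    pathway_defs_kegg <- pick(pathway_defs_kegg, p("pathway_defs_kegg.tsv"))
    pathway_defs_metacyc <- pick(pathway_defs_metacyc,
                                 p("pathway_defs_metacyc.tsv"))
    bgc_defs <- pick(bgc_defs, p("bgc_defs.tsv"))
    taxa_profile <- pick(taxa_profile, p("taxa_profile.tsv"))
  }
  if (is.null(metadata) || is.null(gene_hits_dir) || is.null(gene2ko)) {
    stop("`metadata`, `gene_hits_dir` and `gene2ko` are required",
         call. = FALSE)
  }
  stopifnot(evalue > 0)
  stopifnot_scalar_fraction(fdr, "fdr", open_lo = TRUE, open_hi = TRUE)
  structure(list(metadata = metadata, gene_hits_dir = gene_hits_dir,
                 ncrna_hits_dir = ncrna_hits_dir, gene2ko = gene2ko,
                 gene2cog = gene2cog, gene2ec = gene2ec,
                 gene2phylum = gene2phylum, ko2pathway = ko2pathway,
                 pathway2class = pathway2class, cog2category = cog2category,
                 ec2metacyc = ec2metacyc,
                 pathway_defs_kegg = pathway_defs_kegg,
                 pathway_defs_metacyc = pathway_defs_metacyc,
                 bgc_defs = bgc_defs, taxa_profile = taxa_profile,
                 evalue = evalue, fdr = fdr,
                 rho_threshold = rho_threshold, bgc_min_cov = bgc_min_cov,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order — ncRNA depletion, best-hit gene assignment,
#' functional profiling with hierarchy rollups, differential expression and
#' MDS, most-varied selection, parsimony pathway inference and enrichment,
#' taxonomic contribution/distribution and transcription activation, BGC
#' scoring and type comparison, and per-condition co-expression networks —
#' writing each stage's tables plus a cumulative `README.txt` manifest under
#' `out_dir`. Stages whose optional inputs are absent are skipped with a
#' message; a stage failure stops the pipeline naming the stage, with the
#' outputs of completed stages retained on disk. Outputs are byte-identical
#' across re-runs with the same inputs and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `manifest` (data.frame of files written),
#'   `skipped` (named character vector of skip reasons), and the main
#'   in-memory results (`de`, `most_varied`, `counts`, `profiles`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  skipped <- character(0)
  manifest <- NULL
  t0 <- Sys.time()
  stage_msg <- function(s) message(sprintf("[%s] stage: %s",
                                           format(Sys.time(), "%H:%M:%S"), s))
  run_stage <- function(name, expr) {
    stage_msg(name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(results, descriptions) {
    m <- write_tab_outputs(results, out_dir, descriptions,
                           append = !is.null(manifest))
    manifest <<- rbind(manifest, m)
  }

  meta <- run_stage("metadata", read_metadata(config$metadata))
  samples <- meta$sample_id

  # --- ncRNA depletion -------------------------------------------------
  flagged <- setNames(vector("list", length(samples)), samples)
  if (!is.null(config$ncrna_hits_dir)) {
    reports <- run_stage("ncrna_filter", {
      out <- lapply(samples, function(s) {
        f <- file.path(config$ncrna_hits_dir, paste0(s, ".m8"))
        if (!file.exists(f)) {
          return(list(flagged = character(0),
                      report = data.frame(n_input_reads = 0L,
                                          n_flagged_ncrna = 0L,
                                          n_retained = 0L,
                                          threshold = config$evalue)))
        }
        flag_ncrna_reads(read_m8(f), threshold = config$evalue)
      })
      names(out) <- samples
      out
    })
    for (s in samples) flagged[[s]] <- reports[[s]]$flagged
    rep_df <- do.call(rbind, lapply(samples, function(s) {
      cbind(sample_id = s, reports[[s]]$report)
    }))
    emit(list(ncrna_filter_report = rep_df),
         c(ncrna_filter_report =
             "Per-sample non-coding-RNA depletion counts (best-hit e-value filter)"))
  } else {
    skipped["ncrna_filter"] <- "no ncRNA hit directory supplied"
    message("skipping ncrna_filter: ", skipped[["ncrna_filter"]])
  }

  # --- gene assignment -------------------------------------------------
  counts <- run_stage("gene_assignment", {
    out <- lapply(samples, function(s) {
      f <- file.path(config$gene_hits_dir, paste0(s, ".m8"))
      if (!file.exists(f)) stop("missing gene hit file for sample ", s)
      assign_best_gene(read_m8(f), threshold = config$evalue,
                       exclude_reads = flagged[[s]])
    })
    names(out) <- samples
    out
  })
  gm <- gene_count_matrix(counts)
  emit(list(gene_counts = gm),
       c(gene_counts = "Best-hit read counts per reference gene and sample"))

  # --- profiling + rollups --------------------------------------------
  maps <- list(KO = config$gene2ko, COG = config$gene2cog,
               EC = config$gene2ec)
  profiles <- list()
  for (sys_name in names(maps)) {
    if (is.null(maps[[sys_name]])) {
      skipped[paste0("profile_", sys_name)] <- "no annotation map supplied"
      next
    }
    profiles[[sys_name]] <- run_stage(paste0("profile_", sys_name), {
      ann <- read_annotation_map(maps[[sys_name]])
      profile_features(gm, ann, system = sys_name)
    })
    nm <- paste0("profile_", sys_name)
    desc <- sprintf("Relative abundance of %s features per sample",
                    sys_name)
    emit(setNames(list(profiles[[sys_name]]), nm), setNames(desc, nm))
  }
  rollups <- list(
    list(from = "KO", map = config$ko2pathway, name = "profile_kegg_pathway",
         desc = "KO profile rolled up to KEGG pathways"),
    list(from = "COG", map = config$cog2category,
         name = "profile_cog_category",
         desc = "COG profile rolled up to COG categories"),
    list(from = "EC", map = config$ec2metacyc,
         name = "profile_metacyc_pathway",
         desc = "EC profile rolled up to MetaCyc pathways"))
  pathway_profile <- NULL
  for (r in rollups) {
    if (is.null(r$map) || is.null(profiles[[r$from]])) next
    rolled <- run_stage(r$name, {
      rollup(profiles[[r$from]], read_hierarchy_map(r$map), level = r$name)
    })
    if (r$name == "profile_kegg_pathway") pathway_profile <- rolled
    emit(setNames(list(rolled), r$name), setNames(r$desc, r$name))
  }
  if (!is.null(pathway_profile) && !is.null(config$pathway2class)) {
    classes <- run_stage("profile_kegg_class", {
      rollup(pathway_profile, read_hierarchy_map(config$pathway2class),
             level = "kegg_class")
    })
    emit(list(profile_kegg_class = classes),
         c(profile_kegg_class = "KEGG pathway profile rolled up to pathway classes"))
  }

  # --- DE + MDS --------------------------------------------------------
  de_tables <- list()
  for (sys_name in intersect(c("KO", "COG"), names(profiles))) {
    de_tables[[sys_name]] <- run_stage(paste0("de_", sys_name), {
      wilcoxon_de(profiles[[sys_name]], meta, fdr_cutoff = config$fdr)
    })
    nm <- paste0("de_", sys_name)
    emit(setNames(list(de_tables[[sys_name]]), nm),
         setNames(sprintf(
           "Wilcoxon rank-sum differential expression of %s features (BH FDR)",
           sys_name), nm))
  }
  if (length(samples) >= 3L && !is.null(profiles$KO)) {
    mds <- run_stage("mds", mds_ordination(profiles$KO))
    emit(list(mds_coordinates = data.frame(
      sample_id = rownames(mds$points), mds$points, check.names = FALSE,
      stringsAsFactors = FALSE)),
      c(mds_coordinates =
          "Classical MDS sample ordination (Bray-Curtis on the KO profile)"))
  }

  # --- most varied -----------------------------------------------------
  most_varied <- NULL
  if (!is.null(de_tables$KO)) {
    most_varied <- run_stage("most_varied", {
      select_most_varied(de_tables$KO, fdr_cutoff = config$fdr)
    })
    emit(list(most_varied = data.frame(
      feature_id = most_varied$features,
      selection_mode = most_varied$selection_mode,
      stringsAsFactors = FALSE)),
      c(most_varied = "Most varied functional groups (FDR-significant, or top fold changes)"))
  }

  # --- pathways --------------------------------------------------------
  for (pd in list(list(defs = config$pathway_defs_kegg, de = "KO",
                       tag = "kegg"),
                  list(defs = config$pathway_defs_metacyc, de = "EC",
                       tag = "metacyc"))) {
    if (is.null(pd$defs)) {
      skipped[paste0("pathways_", pd$tag)] <- "no pathway definitions supplied"
      next
    }
    defs <- read_pathway_defs(pd$defs)
    cond_of <- setNames(meta$condition, meta$sample_id)
    prof <- profiles[[pd$de]]
    if (!is.null(prof)) {
      inferred <- run_stage(paste0("minpath_", pd$tag), {
        do.call(rbind, lapply(attr(meta, "conditions"), function(cc) {
          cols <- samples[cond_of[samples] == cc]
          observed <- rownames(prof)[rowSums(prof[, cols, drop = FALSE]) > 0]
          res <- suppressWarnings(infer_minimal_pathways(observed, defs))
          data.frame(condition = cc, pathway_id = res$pathways,
                     mode = res$mode, stringsAsFactors = FALSE)
        }))
      })
      nm <- paste0("pathways_inferred_", pd$tag)
      emit(setNames(list(inferred), nm),
           setNames(sprintf(
             "Minimum-set-cover pathway inference per condition (%s)",
             pd$tag), nm))
    }
    de_for <- de_tables[[pd$de]]
    if (is.null(de_for) && pd$de == "EC" && !is.null(profiles$EC)) {
      de_for <- run_stage("de_EC", {
        wilcoxon_de(profiles$EC, meta, fdr_cutoff = config$fdr)
      })
    }
    if (!is.null(de_for)) {
      enr <- run_stage(paste0("enrichment_", pd$tag), {
        suppressWarnings(pathway_enrichment(de_for, defs))
      })
      nm <- paste0("pathway_enrichment_", pd$tag)
      emit(setNames(list(enr), nm),
           setNames(sprintf(
             "Gene-set enrichment of %s pathways on log2 fold changes",
             pd$tag), nm))
    }
  }

  # --- taxonomy --------------------------------------------------------
  if (!is.null(config$gene2phylum) && !is.null(most_varied) &&
      !is.null(config$gene2ko)) {
    ann <- read_annotation_map(config$gene2ko)
    phylum_map <- read_pair_map(config$gene2phylum,
                                c("gene_id", "phylum"))
    contrib <- run_stage("taxon_contribution", {
      suppressWarnings(taxon_contribution(gm, ann, phylum_map, meta,
                                          most_varied$features))
    })
    distrib <- run_stage("taxon_distribution", {
      taxon_distribution(gm, ann, phylum_map, meta, most_varied$features)
    })
    emit(list(taxon_contribution = contrib, taxon_distribution = distrib),
         c(taxon_contribution =
             "Per-phylum contribution to between-condition variation of the most varied features",
           taxon_distribution =
             "Per-condition phylum distribution of each most varied feature"))
    if (!is.null(config$taxa_profile)) {
      activation <- run_stage("transcription_activation", {
        taxa <- read_taxa_profile(config$taxa_profile)
        totals <- colSums(gm)
        totals[totals == 0] <- 1
        gene_expr <- sweep(gm, 2L, totals, "/")
        ph <- phylum_lookup(phylum_map)
        keep <- rownames(gene_expr)[rownames(gene_expr) %in% names(ph)]
        suppressWarnings(transcription_activation(
          gene_expr[keep, , drop = FALSE], ph, taxa, meta))
      })
      emit(list(transcription_activation = activation$table),
           c(transcription_activation =
               "Gene expression normalised by phylum metagenomic abundance, compared across conditions"))
    } else {
      skipped["transcription_activation"] <- "no metagenomic taxa profile supplied"
      message("skipping transcription_activation: ",
              skipped[["transcription_activation"]])
    }
  } else {
    skipped["taxonomy"] <- "gene-to-phylum map, KO map or most-varied set unavailable"
  }

  # --- BGC -------------------------------------------------------------
  if (!is.null(config$bgc_defs)) {
    bgc <- run_stage("bgc", {
      defs <- read_bgc_defs(config$bgc_defs)
      ab <- bgc_abundance(gm, defs, min_cov = config$bgc_min_cov)
      cmp <- compare_bgc_types(ab, meta)
      list(ab = ab, cmp = cmp)
    })
    emit(list(bgc_scores = bgc$ab, bgc_type_de = bgc$cmp$de,
              bgc_type_proportions = bgc$cmp$proportions),
         c(bgc_scores = "Per-cluster BGC coverage and abundance score per sample",
           bgc_type_de = "Wilcoxon comparison of BGC-type abundance between conditions",
           bgc_type_proportions = "Relative proportion of BGC types per sample"))
  } else {
    skipped["bgc"] <- "no BGC definitions supplied"
    message("skipping bgc: ", skipped[["bgc"]])
  }

  # --- co-expression ---------------------------------------------------
  if (!is.null(most_varied) && length(most_varied$features) >= 2L &&
      !is.null(profiles$KO)) {
    for (cc in attr(meta, "conditions")) {
      net <- run_stage(paste0("coexpr_", cc), {
        prof <- profiles$KO[intersect(most_varied$features,
                                      rownames(profiles$KO)), ,
                            drop = FALSE]
        n <- suppressWarnings(build_network(prof, meta, cc,
                                            config$rho_threshold))
        n <- detect_communities(n, seed = config$seed)
        hubs <- find_hubs(n)
        network_tables(n, hubs)
      })
      nms <- paste0(c("coexpr_nodes_", "coexpr_edges_"), cc)
      emit(setNames(list(net$nodes, net$edges), nms),
           setNames(c(sprintf(
             "Co-expression network nodes for condition %s (degree, community, hub flag)", cc),
             sprintf("Co-expression network edges for condition %s (Spearman rho)", cc)),
             nms))
    }
  } else {
    skipped["coexpr"] <- "most-varied set or KO profile unavailable"
  }

  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(manifest = manifest, skipped = skipped, de = de_tables,
                 most_varied = most_varied, counts = counts,
                 profiles = profiles))
}
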