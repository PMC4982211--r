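M8_COLUMNS <- c("read_id", "subject_id", "pct_identity", "aln_length",
                "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end", "e_value", "bit_score")

#' Read a BLAST tabular (outfmt 6 / "m8") alignment file
#'
#' Parses the fixed 12-column tab-separated BLAST tabular format. Scientific
#' notation is accepted for the e-value. Files with more than 12 columns
#' (some aligners emit extras) are read with a warning and the extra columns
#' dropped; rows with fewer than 12 columns or unparseable numeric fields are
#' an error naming the offending line.
#'
#' @param path path to a tab-separated alignment file. An empty file yields a
#'   zero-row table, not an error.
#' @return a `data.frame` with columns `read_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`, one row per
#'   alignment, in file order.
#' @seealso [write_m8()], [flag_ncrna_reads()], [assign_best_gene()]
#' @export
#' @examples
#' f <- tempfile()
#' writeLines("r1\tg1\t98.5\t100\t1\t0\t1\t100\t5\t104\t1e-30\t180", f)
#' read_m8(f)
read_m8 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(empty_m8())
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) return(empty_m8())
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop(sprintf("malformed m8 row at line %d of %s: %d column(s), expected 12",
                 bad, path, nf[bad]), call. = FALSE)
  }
  if (any(nf > 12L)) {
    warning(sprintf("%s: %d row(s) carry more than 12 columns; extras ignored",
                    path, sum(nf > 12L)), call. = FALSE)
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          select = seq_len(12L),
                          colClasses = list(character = c(1L, 2L)),
                          data.table = FALSE, showProgress = FALSE)
  names(dt) <- M8_COLUMNS
  num_cols <- M8_COLUMNS[-(1:2)]
  for (cc in num_cols) {
    v <- dt[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) {
        bad <- which(is.na(vn))[1L]
        stop(sprintf("malformed m8 row at line %d of %s: non-numeric '%s' in column %s",
                     bad, path, v[bad], cc), call. = FALSE)
      }
      dt[[cc]] <- vn
    } else if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("malformed m8 row at line %d of %s: missing value in column %s",
                   bad, path, cc), call. = FALSE)
    }
  }
  validate_m8(dt, path)
  dt
}

empty_m8 <- function() {
  out <- data.frame(read_id = character(), subject_id = character(),
                    pct_identity = numeric(), aln_length = numeric(),
                    mismatches = numeric(), gap_opens = numeric(),
                    q_start = numeric(), q_end = numeric(),
                    s_start = numeric(), s_end = numeric(),
                    e_value = numeric(), bit_score = numeric(),
                    stringsAsFactors = FALSE)
  out
}

validate_m8 <- function(hits, path = "<in-memory>") {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$e_value < 0)) {
    stop("invalid m8 (", path, "): negative e-value", call. = FALSE)
  }
  if (any(hits$aln_length < 1)) {
    stop("invalid m8 (", path, "): alignment length < 1", call. = FALSE)
  }
  coord <- c("q_start", "q_end", "s_start", "s_end")
  if (any(vapply(coord, function(cc) any(hits[[cc]] < 1), logical(1L)))) {
    stop("invalid m8 (", path, "): coordinates must be >= 1 (1-based inclusive)",
         call. = FALSE)
  }
  invisible(hits)
}

#' Write alignment hits in BLAST tabular format
#'
#' Inverse of [read_m8()]: writing then re-reading is the identity on all
#' parsed fields.
#'
#' @param hits a hit table as returned by [read_m8()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_m8 <- function(hits, path) {
  stopifnot(is.data.frame(hits), all(M8_COLUMNS %in% names(hits)))
  data.table::fwrite(hits[, M8_COLUMNS, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE, scipen = 0)
  invisible(path)
}

#' Read the sample metadata table
#'
#' A two-column tab-separated file mapping sample id to condition label. A
#' header line `sample_id<TAB>condition` is recognised and skipped if
#' present. Exactly two distinct condition labels are required (the
#' comparative analyses are two-condition by design) and sample ids must be
#' unique.
#'
#' @param path path to the metadata TSV.
#' @return a `data.frame` with columns `sample_id` and `condition`. The
#'   attribute `"conditions"` holds the two labels sorted ascending; the
#'   first (lexicographically smaller) is used as the reference condition for
#'   fold-change orientation unless overridden downstream.
#' @export
read_metadata <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  if (ncol(raw) != 2L) {
    stop("metadata must be a 2-column TSV (sample_id, condition); got ",
         ncol(raw), " columns", call. = FALSE)
  }
  names(raw) <- c("sample_id", "condition")
  if (nrow(raw) > 0L && identical(tolower(unname(unlist(raw[1L, ]))),
                                  c("sample_id", "condition"))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  validate_metadata(raw)
}

#' Validate an in-memory metadata table
#'
#' @param meta a data.frame with columns `sample_id` and `condition`.
#' @return the validated data.frame with a `"conditions"` attribute.
#' @export
validate_metadata <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "condition") %in% names(meta)))
  meta <- data.frame(sample_id = as.character(meta$sample_id),
                     condition = as.character(meta$condition),
                     stringsAsFactors = FALSE)
  if (nrow(meta) == 0L) stop("metadata has no samples", call. = FALSE)
  if (anyDuplicated(meta$sample_id)) {
    dup <- meta$sample_id[duplicated(meta$sample_id)][1L]
    stop("duplicate sample id in metadata: ", dup, call. = FALSE)
  }
  conds <- sort_c(unique(meta$condition))
  if (length(conds) != 2L) {
    stop("metadata must define exactly two conditions; found ",
         length(conds), ": ", paste(conds, collapse = ", "), call. = FALSE)
  }
  attr(meta, "conditions") <- conds
  meta
}

#' Read a two-column child-to-parent map
#'
#' The common on-disk layout for annotation maps (gene to COG/KO/EC, gene to
#' phylum), functional hierarchies (KO to KEGG pathway, pathway to class, COG
#' to category, EC to MetaCyc level) and pathway definitions (pathway to
#' member function, column order reversed via `swap`): one tab-separated row
#' per (child, parent) pair. A child may appear on several rows (multiple
#' annotations / parents).
#'
#' @param path path to the TSV.
#' @param col_names length-2 character, names for the two columns.
#' @param swap if `TRUE`, the file's columns are (parent, child) and are
#'   swapped on read (used for pathway definition files laid out
#'   `pathway_id<TAB>function_id`).
#' @return a `data.frame` with the requested two character columns,
#'   duplicate rows removed.
#' @export
read_pair_map <- function(path, col_names = c("child", "parent"),
                          swap = FALSE) {
  stopifnot(length(col_names) == 2L)
  raw <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  if (ncol(raw) != 2L) {
    stop(basename(path), ": expected a 2-column TSV, got ", ncol(raw),
         " columns", call. = FALSE)
  }
  if (swap) raw <- raw[, 2:1, drop = FALSE]
  names(raw) <- col_names
  if (nrow(raw) > 0L && identical(tolower(unname(unlist(raw[1L, ]))),
                                  tolower(col_names))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (any(!nzchar(raw[[1L]])) || any(!nzchar(raw[[2L]]))) {
    stop(basename(path), ": empty identifier in map", call. = FALSE)
  }
  unique(raw)
}

#' @rdname read_pair_map
#' @export
read_annotation_map <- function(path) {
  read_pair_map(path, c("gene_id", "feature_id"))
}

#' @rdname read_pair_map
#' @export
read_hierarchy_map <- function(path) {
  read_pair_map(path, c("feature_id", "parent_id"))
}

#' @rdname read_pair_map
#' @export
read_pathway_defs <- function(path) {
  read_pair_map(path, c("pathway_id", "function_id"))
}

#' Read a BGC definition table
#'
#' Tab-separated, four columns: `cluster_id`, `gene_id`, `biosynthetic`
#' (0/1), `bgc_type` (antiSMASH-style class label). A header row is
#' recognised and skipped.
#'
#' @param path path to the TSV.
#' @return a `data.frame` with columns `cluster_id`, `gene_id`,
#'   `biosynthetic` (logical), `bgc_type`.
#' @export
read_bgc_defs <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                           colClasses = "character", data.table = FALSE,
                           showProgress = FALSE)
  if (ncol(raw) != 4L) {
    stop(basename(path), ": BGC definitions need 4 columns ",
         "(cluster_id, gene_id, biosynthetic, bgc_type)", call. = FALSE)
  }
  names(raw) <- c("cluster_id", "gene_id", "biosynthetic", "bgc_type")
  if (identical(tolower(unname(unlist(raw[1L, 1:2]))), c("cluster_id", "gene_id"))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  flag <- raw$biosynthetic
  ok <- flag %in% c("0", "1", "TRUE", "FALSE", "true", "false")
  if (any(!ok)) {
    stop(basename(path), ": biosynthetic flag must be 0/1, got '",
         flag[!ok][1L], "'", call. = FALSE)
  }
  raw$biosynthetic <- flag %in% c("1", "TRUE", "true")
  if (any(!nzchar(raw$bgc_type))) {
    stop(basename(path), ": empty bgc_type", call. = FALSE)
  }
  raw
}

#' Read a taxon (phylum) abundance profile
#'
#' Phylum-by-sample matrix as TSV with a header row of sample ids and the
#' phylum name in the first column. Values may be fractions or counts;
#' consumers normalise counts per sample.
#'
#' @param path path to the TSV.
#' @return a numeric matrix, phyla in rows, samples in columns.
#' @export
read_taxa_profile <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                           data.table = FALSE, showProgress = FALSE)
  rn <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (any(m < 0)) stop(basename(path), ": negative abundance", call. = FALSE)
  m
}

#' Write stage outputs as TSV files plus a README manifest
#'
#' Each element of `results` is written as a tab-separated file with a header
#' row, rows sorted ascending (C collation) on the first column so output is
#' byte-identical across runs; matrices are written with their row names as a
#' leading `id` column. A `README.txt` manifest lists every file written with
#' its one-line description.
#'
#' @param results named list of data.frames or matrices. Names become file
#'   names (`<name>.tsv`).
#' @param dir output directory, created if needed.
#' @param descriptions optional named character vector of one-line
#'   descriptions keyed like `results`.
#' @param append if `TRUE`, extend an existing `README.txt` instead of
#'   overwriting it.
#' @return invisibly, a data.frame manifest (`file`, `description`).
#' @export
write_tab_outputs <- function(results, dir, descriptions = NULL,
                              append = FALSE) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  if (file.access(dir, 2L) != 0L) {
    stop("output directory not writable: ", dir, call. = FALSE)
  }
  files <- character(0)
  descs <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) {
      df <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                       as.data.frame(x, check.names = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      df <- as.data.frame(x, stringsAsFactors = FALSE)
    }
    if (nrow(df) > 1L) {
      df <- df[order_c(as.character(df[[1L]])), , drop = FALSE]
    }
    fn <- paste0(nm, ".tsv")
    write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    files <- c(files, fn)
    descs <- c(descs, (descriptions[[nm]] %||% nm))
  }
  manifest <- data.frame(file = files, description = descs,
                         stringsAsFactors = FALSE)
  readme <- file.path(dir, "README.txt")
  lines <- sprintf("%s\t%s", manifest$file, manifest$description)
  if (append && file.exists(readme)) {
    old <- readLines(readme)
    lines <- c(old, lines)
  } else {
    lines <- c("file\tdescription", lines)
  }
  writeLines(lines, readme)
  invisible(manifest)
}
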