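#' Reduce an alignment table to one best hit per read
#'
#' Best-hit semantics shared by the ncRNA filter and the gene assignment
#' step: for each read, keep the hit with the minimum e-value; ties are
#' broken by maximum bit score, then by lexicographically smallest subject
#' id. The tie rules are total, so the result is invariant to the input row
#' order.
#'
#' @param hits an alignment table as returned by [read_m8()].
#' @return one row per distinct `read_id`, best hit first by the rule above.
#' @export
best_hits <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("read_id", "subject_id", "e_value", "bit_score") %in%
                  names(hits)))
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$read_id, hits$e_value, -hits$bit_score, hits$subject_id,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$read_id), , drop = FALSE]
}
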