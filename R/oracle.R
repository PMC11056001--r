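#' Brute-force reference anchor matcher
#'
#' Independent reference implementation of the anchor search, used for
#' equivalence checking against [find_anchor_hits()] in the test suite. It
#' deliberately works by a different mechanism: each strand is doubled
#' end-to-end (so origin-spanning windows become ordinary substrings), the
#' window at every offset is extracted with [substring()] and compared
#' character by character with a full count -- no modular indexing, no
#' early exit -- and only starts within the original length are kept.
#' It shares no matching code with the scanning implementation, so the two
#' can fail independently.
#'
#' @param record A [sequence_record()].
#' @param query An [anchor_query()].
#' @param search_reverse Also search the reverse complement (default TRUE).
#' @return List of [anchor_hit()]s in the same order contract as
#'   [find_anchor_hits()].
#' @keywords internal
#' @export
brute_force_hits <- function(record, query, search_reverse = TRUE) {
  stopifnot(inherits(record, "sequence_record"), inherits(query, "anchor_query"))
  L <- record$length
  if (L < 1L)
    stop_record_error("rotate_empty_record", record$name,
                      sprintf("record '%s' is empty", record$name))
  if (query$width > L)
    stop_record_error("rotate_anchor_too_long", record$name,
                      sprintf("anchor (%d bp) is longer than record '%s' (%d bp)",
                              query$width, record$name, L))
  pat_chars <- strsplit(toupper(query$anchor), "")[[1L]]
  count_strand <- function(seq, strand) {
    doubled <- toupper(paste0(seq, seq))
    hits <- list()
    for (p in seq_len(L)) {
      window <- strsplit(substring(doubled, p, p + query$width - 1L), "")[[1L]]
      d <- sum(window != pat_chars)
      if (d <= query$max_mismatches)
        hits[[length(hits) + 1L]] <- anchor_hit(p, strand, d)
    }
    hits
  }
  hits <- count_strand(record$residues, "forward")
  if (isTRUE(search_reverse))
    hits <- c(hits, count_strand(reverse_complement(record$residues), "reverse"))
  hits
}
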