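# Complement lookup over the full byte range. Watson-Crick pairs and IUPAC
# ambiguity codes map to their complements with case preserved; the
# alignment gap '-' maps to itself; every other byte maps to N (n if the
# input byte was a lowercase letter).
.complement_lut <- local({
  lut <- rep.int(charToRaw("N"), 256L)
  lut[98:123] <- charToRaw("n")  # lowercase letter bytes 97..122 default to n
  pairs <- c(A = "T", C = "G", G = "C", T = "A",
             R = "Y", Y = "R", K = "M", M = "K",
             S = "S", W = "W", B = "V", V = "B",
             D = "H", H = "D", N = "N")
  for (from in names(pairs)) {
    to <- pairs[[from]]
    lut[utf8ToInt(from) + 1L] <- charToRaw(to)
    lut[utf8ToInt(tolower(from)) + 1L] <- charToRaw(tolower(to))
  }
  lut[utf8ToInt("-") + 1L] <- charToRaw("-")
  lut
})

#' Reverse complement of a residue string
#'
#' Reverses the string and complements each residue. Case is preserved, so
#' soft-masking survives. IUPAC ambiguity codes map to their complements
#' (R/Y, K/M, S, W, B/V, D/H, N); the alignment gap `-` is its own
#' complement; any other character becomes `N` (`n` if it was a lowercase
#' letter).
#'
#' @param seq Residue string (may be empty).
#' @return The reverse complement, same length as `seq`.
#' @examples
#' reverse_complement("AAACg")  # "cGTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  rawToChar(rev(.complement_lut[as.integer(charToRaw(seq)) + 1L]))
}

# Uppercase byte codes of a residue string, for case-insensitive literal
# comparison. Matching is byte-literal: N only matches N, '-' only '-'.
.match_codes <- function(seq) {
  as.integer(charToRaw(toupper(seq)))
}

#' Mismatches between a pattern and a circular window
#'
#' Hamming distance between `pattern` and the window of `nchar(pattern)`
#' residues starting at 1-based position `pos` on `seq`, with indices read
#' modulo `nchar(seq)` so the window may wrap past the end (the circular
#' origin). Comparison is case-insensitive and literal: `N` matches only
#' `N`, a gap matches only a gap; ambiguity codes are not expanded.
#'
#' @param seq Subject residue string, treated as circular.
#' @param pos 1-based window start, in `[1, nchar(seq)]`.
#' @param pattern Pattern string, no longer than `seq`.
#' @return Integer mismatch count in `[0, nchar(pattern)]`.
#' @examples
#' circular_window_mismatches("ACGTAC", 5, "ACAC")  # wraps: 0
#' @export
circular_window_mismatches <- function(seq, pos, pattern) {
  L <- nchar(seq)
  w <- nchar(pattern)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > L)
    stop(sprintf("pos must be in [1, %d], got %s", L, pos), call. = FALSE)
  if (w > L)
    stop("pattern is longer than the sequence", call. = FALSE)
  if (w == 0L) return(0L)
  codes <- .match_codes(seq)
  pat <- .match_codes(pattern)
  idx <- ((pos - 1L + seq_len(w) - 1L) %% L) + 1L
  sum(codes[idx] != pat)
}

# Column-wise scan for all windows within m mismatches of pat_codes on a
# circular subject given as uppercase byte codes. Accumulates mismatch
# counts one pattern column at a time, pruning start positions whose count
# has already exceeded m (the vectorised analogue of an early exit).
# Returns a list(start, mismatches) of 1-based starts in ascending order.
.scan_circular <- function(codes, pat_codes, m) {
  L <- length(codes)
  w <- length(pat_codes)
  mism <- integer(L)
  active <- seq_len(L)
  for (j in seq_len(w)) {
    idx <- ((active - 1L + j - 1L) %% L) + 1L
    mism[active] <- mism[active] + (codes[idx] != pat_codes[j])
    active <- active[mism[active] <= m]
    if (length(active) == 0L) break
  }
  list(start = active, mismatches = mism[active])
}

#' Find all anchor occurrences on a circular sequence
#'
#' Enumerates every 1-based start position whose circular window is within
#' the query's mismatch budget of the anchor, on the forward strand and
#' (optionally) on the reverse complement. Windows may span the circular
#' origin; only starts in `[1, L]` are reported, so no duplicates arise.
#'
#' @param record A [sequence_record()].
#' @param query An [anchor_query()].
#' @param search_reverse Also search the reverse complement (default TRUE).
#' @return List of [anchor_hit()]s, forward strand first, then reverse,
#'   each in ascending start order. Empty list when there is no hit.
#'   Reverse-strand starts are positions on the reverse-complemented
#'   sequence.
#' @seealso [rotate_to_anchor()] for the uniqueness-enforcing rotation.
#' @export
find_anchor_hits <- function(record, query, search_reverse = TRUE) {
  stopifnot(inherits(record, "sequence_record"), inherits(query, "anchor_query"))
  L <- record$length
  if (L < 1L)
    stop_record_error("rotate_empty_record", record$name,
                      sprintf("record '%s' is empty", record$name))
  if (query$width > L)
    stop_record_error("rotate_anchor_too_long", record$name,
                      sprintf("anchor (%d bp) is longer than record '%s' (%d bp)",
                              query$width, record$name, L))
  pat <- .match_codes(query$anchor)
  m <- query$max_mismatches
  fwd <- .scan_circular(.match_codes(record$residues), pat, m)
  hits <- mapply(anchor_hit, fwd$start, "forward", fwd$mismatches,
                 SIMPLIFY = FALSE)
  if (isTRUE(search_reverse)) {
    rev <- .scan_circular(.match_codes(reverse_complement(record$residues)),
                          pat, m)
    hits <- c(hits, mapply(anchor_hit, rev$start, "reverse", rev$mismatches,
                           SIMPLIFY = FALSE))
  }
  hits
}

#' Rotate a record by a fixed offset
#'
#' Shifts the linearisation start of a circular sequence by `x` residues:
#' the input's 1-based position `(x mod L) + 1` becomes the output's first
#' residue. `x = 0` is the identity; negative and full-turn offsets are
#' normalised modulo the length. Works on any alphabet, including alignment
#' gaps, so it can re-offset gapped multiple-alignment output.
#'
#' @param record A [sequence_record()] of length >= 1.
#' @param x Integer shift in residues (any sign).
#' @return A `rotation_outcome`: list with the rotated `record` (header
#'   preserved verbatim), `applied_offset` (`x mod L`), `flipped = FALSE`
#'   and `hit = NULL`.
#' @examples
#' rotate_by_offset(sequence_record("a", "ABCDEF"), 2)$record$residues
#' @export
rotate_by_offset <- function(record, x) {
  stopifnot(inherits(record, "sequence_record"))
  L <- record$length
  if (L < 1L)
    stop_record_error("rotate_empty_record", record$name,
                      sprintf("record '%s' is empty: a zero-length circle has no rotation",
                              record$name))
  k <- as.integer(((as.numeric(x) %% L) + L) %% L)
  residues <- if (k == 0L) record$residues else
    paste0(substr(record$residues, k + 1L, L), substr(record$residues, 1L, k))
  rotation_outcome(
    sequence_record(record$name, residues, record$description),
    applied_offset = k, flipped = FALSE, hit = NULL
  )
}

rotation_outcome <- function(record, applied_offset, flipped, hit) {
  structure(list(record = record, applied_offset = as.integer(applied_offset),
                 flipped = flipped, hit = hit),
            class = "rotation_outcome")
}

#' @export
print.rotation_outcome <- function(x, ...) {
  cat(sprintf("<rotation_outcome> %s: offset=%d flipped=%s\n",
              x$record$name, x$applied_offset, x$flipped))
  invisible(x)
}

#' Rotate a record so a unique anchor becomes its start
#'
#' Searches both strands for the anchor within the mismatch budget and
#' rotates the record so the (unique) matched window begins at position 1.
#' For a reverse-strand hit the record is first reverse-complemented, so
#' all outputs present the anchor on the forward strand -- the semantics a
#' downstream multiple alignment needs.
#'
#' Uniqueness is strict: the rotation is performed only if exactly one
#' (position, strand) pair lies within the budget. Zero hits raise a
#' `rotate_not_found` error; two or more raise `rotate_ambiguous`, whose
#' condition carries the full hit list (there is no best-hit selection --
#' two hits with different mismatch counts are still ambiguous).
#'
#' @param record A [sequence_record()].
#' @param query An [anchor_query()].
#' @param search_reverse Search the reverse complement too (default TRUE).
#' @return A `rotation_outcome` whose record starts within
#'   `query$max_mismatches` of the anchor; `applied_offset` is the 0-based
#'   shift applied (to the flipped sequence when `flipped`), `hit` the
#'   [anchor_hit()] used.
#' @export
rotate_to_anchor <- function(record, query, search_reverse = TRUE) {
  hits <- find_anchor_hits(record, query, search_reverse = search_reverse)
  if (length(hits) == 0L)
    stop_record_error("rotate_not_found", record$name,
                      sprintf("anchor not found in record '%s' within %d mismatch(es)",
                              record$name, query$max_mismatches))
  if (length(hits) > 1L) {
    locs <- vapply(hits, format, character(1L))
    cond <- structure(
      class = c("rotate_ambiguous", "rotate_record_error", "error", "condition"),
      list(message = sprintf(
             "anchor is not unique in record '%s': %d hits (%s)",
             record$name, length(hits), paste(locs, collapse = ", ")),
           call = NULL, record_name = record$name, hits = hits))
    stop(cond)
  }
  hit <- hits[[1L]]
  base <- if (hit$strand == "reverse")
    sequence_record(record$name, reverse_complement(record$residues),
                    record$description)
  else record
  out <- rotate_by_offset(base, hit$start - 1L)
  out$flipped <- hit$strand == "reverse"
  out$hit <- hit
  out
}

# Per-record error with a condition class, carrying the record name so the
# CLI can report which sequence failed.
stop_record_error <- function(class, record_name, message) {
  stop(structure(
    class = c(class, "rotate_record_error", "error", "condition"),
    list(message = message, call = NULL, record_name = record_name)))
}
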