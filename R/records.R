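#' Construct a sequence record
#'
#' A `sequence_record` is one FASTA entry treated as a linearisation of a
#' circular molecule: a name (first whitespace-delimited token of the
#' header), the full header line, and the residue string. Residues are kept
#' verbatim -- DNA letters in either case, `N`, IUPAC ambiguity codes and
#' alignment gaps (`-`) all survive a read/rotate/write round trip.
#'
#' @param name Record identifier. If missing, derived from `description`.
#' @param residues Residue string (single character scalar).
#' @param description Full header text after `>`; defaults to `name`.
#' @return An object of class `sequence_record` with fields `name`,
#'   `description`, `residues` and `length`.
#' @examples
#' sequence_record("chrM", "ACGTACGT")
#' @export
sequence_record <- function(name, residues, description = name) {
  if (missing(name)) name <- sub("\\s.*$", "", description)
  stopifnot(is.character(name), length(name) == 1L,
            is.character(residues), length(residues) == 1L,
            is.character(description), length(description) == 1L)
  if (grepl("[>\n\r]", residues))
    stop("residues must not contain newlines or '>'", call. = FALSE)
  structure(
    list(name = name, description = description, residues = residues,
         length = nchar(residues)),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  preview <- if (x$length > 60L) paste0(substr(x$residues, 1L, 57L), "...")
             else x$residues
  cat(sprintf("<sequence_record> %s (%d bp)\n  %s\n", x$name, x$length, preview))
  invisible(x)
}

#' Construct an anchor query
#'
#' An anchor query is the search specification for [rotate_to_anchor()]: a
#' short anchor string (typically a conserved region or barcode primer,
#' around 20 bp) and the maximum number of mismatches tolerated when
#' locating it. A budget of `max_mismatches >= nchar(anchor)` would let
#' every window match and is rejected here.
#'
#' @param anchor Anchor string; alphabetic characters only, length >= 1.
#' @param max_mismatches Non-negative mismatch budget, strictly less than
#'   the anchor length. Default 0 (exact matching).
#' @return An object of class `anchor_query`.
#' @examples
#' anchor_query("TACGACCTCGATGTTGGATCA", max_mismatches = 4)
#' @export
anchor_query <- function(anchor, max_mismatches = 0L) {
  stopifnot(is.character(anchor), length(anchor) == 1L)
  w <- nchar(anchor)
  if (w < 1L)
    stop("anchor must have length >= 1", call. = FALSE)
  if (!grepl("^[A-Za-z]+$", anchor))
    stop("anchor must contain only alphabetic characters", call. = FALSE)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be a non-negative integer", call. = FALSE)
  if (max_mismatches >= w)
    stop(sprintf(
      "max_mismatches (%d) must be smaller than the anchor length (%d): %s",
      max_mismatches, w,
      "a budget covering every position makes every window a hit"),
      call. = FALSE)
  structure(list(anchor = anchor, max_mismatches = max_mismatches, width = w),
            class = "anchor_query")
}

#' @export
print.anchor_query <- function(x, ...) {
  cat(sprintf("<anchor_query> %s (w=%d, m=%d)\n",
              x$anchor, x$width, x$max_mismatches))
  invisible(x)
}

#' Construct an anchor hit
#'
#' One candidate anchor occurrence. `start` is 1-based: the position on the
#' searched strand where the matched window begins, before any rotation.
#' For `strand = "reverse"` the position refers to the reverse-complemented
#' sequence, so `start - 1` is directly the rotation offset that would be
#' applied after flipping the record.
#'
#' @param start 1-based window start on the searched strand.
#' @param strand `"forward"` or `"reverse"`.
#' @param mismatches Hamming distance of the matched window to the anchor.
#' @return An object of class `anchor_hit`.
#' @export
anchor_hit <- function(start, strand = c("forward", "reverse"), mismatches = 0L) {
  strand <- match.arg(strand)
  structure(list(start = as.integer(start), strand = strand,
                 mismatches = as.integer(mismatches)),
            class = "anchor_hit")
}

#' @export
print.anchor_hit <- function(x, ...) {
  cat(sprintf("<anchor_hit> %s:%d (%d mismatch%s)\n",
              x$strand, x$start, x$mismatches,
              if (x$mismatches == 1L) "" else "es"))
  invisible(x)
}

#' @export
format.anchor_hit <- function(x, ...) {
  sprintf("%s:%d:%d", x$strand, x$start, x$mismatches)
}
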