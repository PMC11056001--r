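#' Test a file for gzip compression
#'
#' Detection is by the gzip magic bytes (`0x1f 0x8b`) at the start of the
#' file, never by extension, so renamed files are handled correctly.
#'
#' @param path File path.
#' @return TRUE if the file starts with the gzip magic bytes.
#' @export
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Open a FASTA source for streaming
#'
#' Opens a plain or gzip-compressed FASTA file (compression autodetected
#' from magic bytes) or standard input (`path = "-"`) and returns a stream
#' handle from which [fasta_next()] pulls one record at a time, so a large
#' multi-record file is never fully resident.
#'
#' @param path File path, or `"-"` for standard input.
#' @return A `fasta_stream` handle; close with [fasta_close()].
#' @seealso [read_fasta()] to slurp a whole file at once.
#' @export
fasta_open <- function(path) {
  if (identical(path, "-")) {
    raw_in <- readBin(file("stdin", "rb"), "raw", n = .Machine$integer.max)
    gz <- length(raw_in) >= 2L &&
      raw_in[1L] == as.raw(0x1f) && raw_in[2L] == as.raw(0x8b)
    con <- rawConnection(raw_in, "rb")
    if (gz) con <- gzcon(con)
    con <- textConnection(readLines(con, warn = FALSE))
  } else {
    if (!file.exists(path))
      stop(sprintf("input file not found: %s", path), call. = FALSE)
    con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  }
  env <- new.env(parent = emptyenv())
  env$con <- con
  env$pending_header <- NULL   # header line of the next record, if seen
  env$saw_any <- FALSE
  env$done <- FALSE
  class(env) <- "fasta_stream"
  env
}

#' Close a FASTA stream
#' @param stream A `fasta_stream` from [fasta_open()].
#' @export
fasta_close <- function(stream) {
  if (!is.null(stream$con)) {
    close(stream$con)
    stream$con <- NULL
  }
  invisible(NULL)
}

#' Pull the next record from a FASTA stream
#'
#' Reads lines until the following header (or end of file), concatenating
#' multi-line bodies. CRLF endings and stray whitespace around body lines
#' are stripped; the header text after `>` is preserved verbatim as the
#' record description. Content before the first header is an error.
#'
#' @param stream A `fasta_stream` from [fasta_open()].
#' @return A [sequence_record()], or `NULL` at end of input.
#' @export
fasta_next <- function(stream) {
  if (stream$done) return(NULL)
  header <- stream$pending_header
  if (is.null(header)) {
    repeat {
      line <- readLines(stream$con, n = 1L, warn = FALSE)
      if (length(line) == 0L) { stream$done <- TRUE; return(NULL) }
      line <- sub("\r$", "", line)
      if (!nzchar(trimws(line))) next
      if (!startsWith(line, ">"))
        stop("malformed FASTA: content before first '>' header", call. = FALSE)
      header <- line
      break
    }
  }
  stream$saw_any <- TRUE
  body <- character()
  stream$pending_header <- NULL
  repeat {
    line <- readLines(stream$con, n = 1L, warn = FALSE)
    if (length(line) == 0L) { stream$done <- TRUE; break }
    line <- sub("\r$", "", line)
    if (startsWith(line, ">")) { stream$pending_header <- line; break }
    line <- trimws(line)
    if (nzchar(line)) body <- c(body, line)
  }
  desc <- sub("^>", "", header)
  sequence_record(description = desc,
                  residues = paste(body, collapse = ""))
}

#' Read a whole FASTA file
#'
#' Convenience wrapper around [fasta_open()]/[fasta_next()] that collects
#' every record into a list. For record-at-a-time processing of large
#' files, use the stream interface directly.
#'
#' @param path File path (plain or gzipped FASTA), or `"-"` for stdin.
#' @return List of [sequence_record()]s, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b desc", "GG", "GG"), tf)
#' recs <- read_fasta(tf)
#' recs[[2]]$residues  # "GGGG"
#' @export
read_fasta <- function(path) {
  stream <- fasta_open(path)
  on.exit(fasta_close(stream))
  records <- list()
  repeat {
    rec <- fasta_next(stream)
    if (is.null(rec)) break
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Write records as FASTA
#'
#' Writes `>` + description, then the residues wrapped at `width` columns.
#' Headers are never reformatted, and line endings are always LF, so
#' reading the output back reproduces names, descriptions and residues
#' exactly.
#'
#' @param records A [sequence_record()] or list of them.
#' @param con Output connection or file path (default standard output).
#' @param width Wrap width in columns, >= 1 (default 60).
#' @export
write_fasta <- function(records, con = stdout(), width = 60L) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L)
    stop("width must be a positive integer", call. = FALSE)
  if (inherits(records, "sequence_record")) records <- list(records)
  if (is.character(con)) {
    con <- file(con, "wt")
    on.exit(close(con))
  }
  for (rec in records) {
    lines <- c(paste0(">", rec$description), .wrap_residues(rec$residues, width))
    writeLines(lines, con)
  }
  invisible(NULL)
}

.wrap_residues <- function(residues, width) {
  L <- nchar(residues)
  if (L == 0L) return(character())
  starts <- seq.int(1L, L, by = width)
  substring(residues, starts, pmin(starts + width - 1L, L))
}
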