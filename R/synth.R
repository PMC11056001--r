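# Run code with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Specification of a synthetic circular genome
#'
#' Parameters for [make_genome()]: a random circular background of the
#' requested length and GC content, with the anchor spliced in, mutated by
#' a known number of substitutions, placed on a chosen strand, and rotated
#' by a known amount. The defaults mimic a mitochondrial genome
#' (~16.5 kb, GC 0.45); pass `genome_length = 150000` for a
#' chloroplast-sized one.
#'
#' @param genome_length Total length, >= anchor length.
#' @param anchor Anchor string planted in the genome.
#' @param n_mutations Substitutions applied to the planted anchor copy;
#'   must be < anchor length.
#' @param rotation Offset (0-based shift, in `[0, genome_length)`) by which
#'   the anchored genome is rotated away from the anchor-first layout.
#' @param strand `"forward"` or `"reverse"`: the strand the deposited
#'   record presents (reverse means the record is the reverse complement
#'   of the anchor-forward molecule).
#' @param seed Integer seed; identical specs give byte-identical genomes.
#' @param gc_fraction Background GC content in (0, 1), default 0.45.
#' @param max_mismatches Search budget under which the planted anchor must
#'   be the unique hit (defaults to `n_mutations`).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(genome_length, anchor, n_mutations = 0L, rotation = 0L,
                       strand = c("forward", "reverse"), seed = 1L,
                       gc_fraction = 0.45, max_mismatches = n_mutations) {
  strand <- match.arg(strand)
  genome_length <- as.integer(genome_length)
  n_mutations <- as.integer(n_mutations)
  rotation <- as.integer(rotation)
  max_mismatches <- as.integer(max_mismatches)
  w <- nchar(anchor)
  stopifnot(genome_length >= w, n_mutations >= 0L, n_mutations < w,
            rotation >= 0L, rotation < genome_length,
            max_mismatches >= n_mutations, max_mismatches < w,
            gc_fraction > 0, gc_fraction < 1)
  structure(list(genome_length = genome_length, anchor = anchor,
                 n_mutations = n_mutations, rotation = rotation,
                 strand = strand, seed = as.integer(seed),
                 gc_fraction = gc_fraction, max_mismatches = max_mismatches),
            class = "synth_spec")
}

.random_bases <- function(n, gc_fraction) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Substitute the anchor at n seeded positions, always to a different base.
.mutate_anchor <- function(anchor, n) {
  if (n == 0L) return(anchor)
  chars <- strsplit(anchor, "")[[1L]]
  at <- sample(length(chars), n)
  for (i in at) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), toupper(chars[i])), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic circular genome with a planted anchor
#'
#' Draws an i.i.d. background, splices in the anchor mutated by exactly
#' `n_mutations` substitutions, verifies that the planted copy is the
#' unique hit on either strand within `max_mismatches` (redrawing the
#' background up to `max_retries` times otherwise, so uniqueness is
#' guaranteed by construction), then applies the strand flip and rotation.
#' The returned `expected` hit is what [rotate_to_anchor()] must recover:
#' start `rotation + 1` (1-based, on the searched strand), the planted
#' strand, and exactly `n_mutations` mismatches.
#'
#' @param spec A [synth_spec()].
#' @param name Record name (default derived from the seed).
#' @param max_retries Background redraws allowed before giving up.
#' @return List with `record` (a [sequence_record()]) and `expected`
#'   (an [anchor_hit()]).
#' @export
make_genome <- function(spec, name = sprintf("synth_%d", spec$seed),
                        max_retries = 25L) {
  stopifnot(inherits(spec, "synth_spec"))
  query <- anchor_query(spec$anchor,
                        max(spec$max_mismatches, spec$n_mutations))
  with_seed(spec$seed, {
    planted <- .mutate_anchor(spec$anchor, spec$n_mutations)
    for (attempt in seq_len(max_retries + 1L)) {
      background <- .random_bases(spec$genome_length - nchar(spec$anchor),
                                  spec$gc_fraction)
      g0 <- sequence_record(name, paste0(planted, background))
      hits <- find_anchor_hits(g0, query, search_reverse = TRUE)
      ok <- length(hits) == 1L && hits[[1L]]$strand == "forward" &&
        hits[[1L]]$start == 1L
      if (ok) break
      if (attempt > max_retries)
        stop("could not build a genome with a unique planted anchor; ",
             "spec is pathological (retry budget exhausted)", call. = FALSE)
    }
    # place the anchor so that a shift of `rotation` (after any flip)
    # brings it back to position 1
    rec <- rotate_by_offset(g0, -spec$rotation)$record
    if (spec$strand == "reverse")
      rec <- sequence_record(name, reverse_complement(rec$residues))
    list(record = rec,
         expected = anchor_hit(spec$rotation + 1L, spec$strand,
                               spec$n_mutations))
  })
}

#' Generate a cohort of synthetic genomes plus a truth table
#'
#' Writes `n` records built from `base_spec` with per-record derived
#' seeds, rotations uniform over the genome, strands uniform, and
#' mutation counts uniform in `[0, base_spec$n_mutations]`, together with
#' a tab-separated truth table (`name`, `rotation`, `strand`,
#' `mutations`) for downstream assertions. Identical arguments produce
#' byte-identical files.
#'
#' @param n Number of records, >= 1.
#' @param base_spec A [synth_spec()] providing length, anchor, mutation
#'   ceiling, GC content and search budget.
#' @param seed Cohort-level seed.
#' @param fasta_path Output FASTA path; written gzip-compressed if
#'   `gzip = TRUE`.
#' @param truth_path Output TSV path (default `<fasta_path>.truth.tsv`).
#' @param gzip Compress the FASTA output.
#' @return Invisibly, the truth table as a data.frame.
#' @export
make_cohort <- function(n, base_spec, seed, fasta_path,
                        truth_path = paste0(fasta_path, ".truth.tsv"),
                        gzip = FALSE) {
  stopifnot(inherits(base_spec, "synth_spec"), n >= 1L)
  n <- as.integer(n)
  L <- base_spec$genome_length
  draws <- with_seed(seed, data.frame(
    name = sprintf("synth_%03d", seq_len(n)),
    rotation = sample.int(L, n, replace = TRUE) - 1L,
    strand = sample(c("forward", "reverse"), n, replace = TRUE),
    mutations = sample.int(base_spec$n_mutations + 1L, n, replace = TRUE) - 1L,
    seed = (as.integer(seed) %% 100000L) * 10000L + seq_len(n),
    stringsAsFactors = FALSE
  ))
  con <- if (gzip) gzfile(fasta_path, "wt") else file(fasta_path, "wt")
  on.exit(close(con))
  for (i in seq_len(n)) {
    spec_i <- synth_spec(L, base_spec$anchor,
                         n_mutations = draws$mutations[i],
                         rotation = draws$rotation[i],
                         strand = draws$strand[i],
                         seed = draws$seed[i],
                         gc_fraction = base_spec$gc_fraction,
                         max_mismatches = base_spec$max_mismatches)
    g <- make_genome(spec_i, name = draws$name[i])
    write_fasta(g$record, con)
  }
  truth <- draws[, c("name", "rotation", "strand", "mutations")]
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth)
}
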