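# Random fixtures shared across test files. All randomness in tests is
# wrapped in local_seed() so files are order-independent.

local_seed <- function(seed, env = parent.frame()) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = env)
  } else {
    withr::defer(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                 envir = env)
  }
  set.seed(seed)
}

random_residues <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_record <- function(min_len = 1L, max_len = 200L,
                          alphabet = c("A", "C", "G", "T")) {
  L <- sample(min_len:max_len, 1L)
  sequence_record(paste0("r", sample.int(1e6, 1L)), random_residues(L, alphabet))
}

# Flatten a hit list for order-sensitive equality checks.
hits_table <- function(hits) {
  data.frame(
    start = vapply(hits, `[[`, integer(1L), "start"),
    strand = vapply(hits, `[[`, character(1L), "strand"),
    mismatches = vapply(hits, `[[`, integer(1L), "mismatches")
  )
}

PAPER_MITO_ANCHOR <- "TACGACCTCGATGTTGGATCA"
PAPER_CHLORO_ANCHOR <- "CGAAATCGGTAGACGCTACG"
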