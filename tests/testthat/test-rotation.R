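test_that("rotate_by_offset shifts, normalises, and preserves headers", {
  r <- sequence_record("a", "ABCDEF", "a some description")
  expect_equal(rotate_by_offset(r, 2)$record$residues, "CDEFAB")
  expect_equal(rotate_by_offset(r, 0)$record$residues, "ABCDEF")
  expect_equal(rotate_by_offset(r, 6)$record$residues, "ABCDEF")
  expect_equal(rotate_by_offset(r, -1)$record$residues, "FABCDE")
  out <- rotate_by_offset(r, 8)
  expect_equal(out$applied_offset, 2L)
  expect_false(out$flipped)
  expect_null(out$hit)
  expect_equal(out$record$description, "a some description")
  # gapped alignment rows rotate like any other residues
  g <- sequence_record("g", "AC--GT")
  expect_equal(rotate_by_offset(g, 3)$record$residues, "-GTAC-")
  expect_error(rotate_by_offset(sequence_record("e", ""), 1),
               class = "rotate_empty_record")
})

test_that("offset rotations satisfy the group laws", {
  local_seed(201)
  for (i in 1:500) {
    r <- random_record(min_len = 1, max_len = 120)
    L <- r$length
    a <- sample(seq(-2L * L, 2L * L), 1)
    b <- sample(seq(0L, 3L * L), 1)
    # inverse: rotating by a then L - a is the identity
    expect_identical(
      rotate_by_offset(rotate_by_offset(r, a)$record, L - a)$record$residues,
      r$residues)
    # composition: rotating by a then b equals rotating by a + b
    expect_identical(
      rotate_by_offset(rotate_by_offset(r, a)$record, b)$record$residues,
      rotate_by_offset(r, a + b)$record$residues)
  }
})

test_that("rotation conserves length and residue multiset", {
  local_seed(202)
  alphabet <- strsplit("ACGTacgtN-", "")[[1]]
  for (i in 1:100) {
    r <- random_record(min_len = 1, max_len = 150, alphabet = alphabet)
    out <- rotate_by_offset(r, sample(-300:300, 1))
    expect_equal(out$record$length, r$length)
    expect_equal(sort(strsplit(out$record$residues, "")[[1]]),
                 sort(strsplit(r$residues, "")[[1]]))
  }
})

test_that("rotate_to_anchor recovers a planted rotation", {
  local_seed(203)
  body <- paste0(PAPER_MITO_ANCHOR, random_residues(979))
  rec0 <- sequence_record("p", body)
  rec <- rotate_by_offset(rec0, -500)$record  # anchor now at position 501
  out <- rotate_to_anchor(rec, anchor_query(PAPER_MITO_ANCHOR, 0))
  expect_equal(substr(out$record$residues, 1, 21), PAPER_MITO_ANCHOR)
  expect_equal(out$applied_offset, 500L)
  expect_false(out$flipped)
  expect_identical(out$record$residues, body)
})

test_that("rotate_to_anchor flips reverse-strand hits to read forward", {
  local_seed(204)
  body <- paste0(PAPER_CHLORO_ANCHOR, random_residues(400))
  rec <- sequence_record("q", reverse_complement(
    rotate_by_offset(sequence_record("q", body), -77)$record$residues))
  out <- rotate_to_anchor(rec, anchor_query(PAPER_CHLORO_ANCHOR, 0))
  expect_true(out$flipped)
  expect_equal(out$applied_offset, 77L)
  expect_identical(out$record$residues, body)
  expect_equal(out$hit$strand, "reverse")
})

test_that("rotate_to_anchor enforces uniqueness and reports all locations", {
  two <- sequence_record("dup", paste0("TACGA", "TACGA", strrep("C", 90)))
  err <- expect_error(rotate_to_anchor(two, anchor_query("TACGA", 0)),
                      class = "rotate_ambiguous")
  expect_equal(err$record_name, "dup")
  expect_equal(hits_table(err$hits),
               data.frame(start = c(1L, 6L), strand = "forward",
                          mismatches = c(0L, 0L)))

  # two hits with different mismatch counts are still ambiguous: no best-hit
  near <- sequence_record("near", paste0("TACGA", "TACTA", strrep("C", 90)))
  err2 <- expect_error(rotate_to_anchor(near, anchor_query("TACGA", 1)),
                       class = "rotate_ambiguous")
  expect_equal(vapply(err2$hits, `[[`, integer(1), "mismatches"), c(0L, 1L))

  absent <- sequence_record("none", strrep("G", 100))
  err3 <- expect_error(rotate_to_anchor(absent, anchor_query("TACGA", 0)),
                       class = "rotate_not_found")
  expect_equal(err3$record_name, "none")
})

test_that("planting on either strand yields the same rotated output", {
  local_seed(205)
  anchor <- "TACGACCTCGATG"
  for (i in 1:25) {
    g <- paste0(anchor, random_residues(180))
    shift <- sample(0:192, 1)
    fwd_rec <- rotate_by_offset(sequence_record("f", g), -shift)$record
    rev_rec <- sequence_record("r", reverse_complement(fwd_rec$residues))
    out_f <- rotate_to_anchor(fwd_rec, anchor_query(anchor, 0))
    out_r <- rotate_to_anchor(rev_rec, anchor_query(anchor, 0))
    expect_identical(out_r$record$residues, out_f$record$residues)
    expect_true(out_r$flipped)
    expect_false(out_f$flipped)
  }
})
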