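---
title: "Rotating circular DNA sequences: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotating circular DNA sequences: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circrotate)
```

## The problem

A circular DNA molecule — a mitochondrion, plastome, plasmid, or most
bacterial and viral chromosomes — has no intrinsic start. When such a
molecule is deposited as a linear string, a start position and an
orientation are chosen, and different accessions choose differently.
Multiple sequence aligners assume linearity *and* a shared start, so a set
of circular assemblies must first be standardised: every sequence rotated
(and, where needed, reverse-complemented) to the same landmark.

`circrotate` standardises by one of two user-controlled rules: rotation to
a short **anchor string** located approximately on either strand, or
rotation by a fixed **offset**. It deliberately does *not* compute an
"optimal" rotation by any global objective, does not detect *dnaA* or other
genes, and does not canonicalise to the lexicographically minimal rotation:
a user-defined landmark is what lets new sequences be added to an existing
standardised set without re-processing everything.

## The matching model

Let the subject sequence have length $L$ and the anchor length $w$. The
subject is treated as circular: the window of length $w$ starting at
position $p \in \{1, \dots, L\}$ is read at indices
$((p - 1 + j) \bmod L) + 1$ for $j = 0, \dots, w-1$, so windows may span
the linearisation origin. A window is a **hit** when its Hamming distance
to the anchor is at most the budget $m$; substitutions only, no indels.
Searching the reverse strand means running the same scan on the
reverse complement of the subject and labelling those hits `reverse`.

Three deliberate choices shape the semantics:

* **Literal, case-insensitive comparison.** `a` equals `A`, but `N`
  matches only `N`, a gap only a gap, and IUPAC ambiguity codes are not
  expanded. Wildcard matching would quietly change what "the anchor is
  unique" means, and uniqueness is the safety property the whole tool
  rests on.
* **Strict uniqueness, not best-hit.** A sequence is rotated only when
  exactly one (position, strand) pair across both strands lies within the
  budget. Two hits with different mismatch counts are still ambiguous —
  selecting the better one would hide a genuine ambiguity in the data (a
  repeated primer site, an inverted repeat) from the user.
* **Budget bound $m < w$.** A budget equal to the anchor length makes
  every window a hit; `anchor_query()` rejects it at construction.

The mismatch budget is in residues (default 0); anchors are typically
conserved regions or barcode primers of roughly 20 bp, and budgets of 1–4
cover within-clade variation at such sites while keeping a ~20-mer unique
in a genome of tens to hundreds of kb.

## Rotation semantics and coordinates

All reported positions are 1-based, the convention sequence-analysis users
expect in diagnostics. The offset in `rotate_by_offset()` and the CLI's
`-x` is a **shift amount**, not a position: `-x 0` is the identity, the
input's residue at position $x \bmod L + 1$ becomes the output's first
residue, and negative or full-turn values are normalised modulo $L$. Shift
semantics with identity at zero was an open design choice; it is the least
surprising reading of "offset in base pairs" and is stated in the CLI help
so scripts are not written against a guessed convention.

For a reverse-strand hit, the output is the reverse complement of the
input rotated so the anchor reads forward from position 1 — every
successful output presents the anchor on the forward strand, which is the
only semantics under which the downstream alignment columns correspond.
Reverse-strand hit positions are reported on the reverse-complemented
sequence, so `position - 1` is directly the offset applied after the flip.

Rotations by offset form a cyclic group: rotating by $a$ then $b$ equals
rotating by $a + b$, and $L - a$ inverts $a$. These laws, plus
conservation of length and residue multiset and the involution property of
the reverse complement, are checked as properties on hundreds of random
cases in the test suite.

## The failure contract

A sequence whose anchor search fails is a hard error, not a warning:

* zero hits → `not-found`;
* two or more hits → `ambiguous`, with every location reported as
  `strand:position:mismatches`;
* an anchor longer than the record, or an empty record, are likewise
  per-record errors.

The command-line front end is all-or-nothing in anchor mode: rotated
records are buffered and the output FASTA is written only if *every*
record succeeds; on failure it reports **all** failing records (not just
the first) on stderr and emits no FASTA at all, exiting 1. A partially
rotated file fed to an aligner is a silent foot-gun; an empty output is
not. Offset mode streams record by record, since it can only fail on an
empty record. Exit codes are total: 0 success, 1 per-record failure,
2 usage error, 3 I/O error.

## Algorithm and implementation choices

The matcher is a naive $O(L \cdot w)$ scan, implemented column-wise: for
each anchor position $j$ the whole vector of candidate starts is compared
at once, accumulating per-start mismatch counts, and starts whose count
already exceeds $m$ are pruned from the candidate set — the vectorised
analogue of an early exit. With primer-sized anchors ($w \approx 20$) and
genomes up to a few hundred kb this rotates hundreds of organelle-sized
sequences per second in pure R; bit-parallel or index-based matching would
buy nothing at these sizes.

The test suite keeps an independent **brute-force oracle**
(`brute_force_hits()`) that finds the same hits by a different mechanism:
it doubles each strand end-to-end so origin-spanning windows become plain
substrings, extracts every window, and counts mismatches in full with no
pruning. The two implementations share no matching code, so agreement on
thousands of seeded random instances — including instances whose only hit
spans the origin, reverse-only hits, zero-hit instances and saturated
budgets $m = w - 1$ — is a meaningful check, not a tautology.

FASTA I/O is implemented in-package as a streaming reader (one record
resident at a time), because the record model here is deliberately
permissive: residues are arbitrary single-byte text (mixed case, `N`,
IUPAC codes, gaps) that must survive a read–rotate–write round trip
byte-for-byte, and headers are never reformatted. Gzip input is detected
from the magic bytes `1f 8b`, never from the file name. Output is wrapped
at 60 columns by default (`--line-width` to change), always LF-terminated;
CRLF input is tolerated.

Degenerate inputs are decided explicitly: an empty sequence has no
rotation (error); an anchor equal in length to the whole sequence is legal
and can yield both a forward and a reverse hit on a self-reverse-
complementary sequence (ambiguous, correctly); unknown residue characters
reverse-complement to `N`/`n` rather than erroring, so dirty records still
round-trip.

## What the synthetic generator emulates — and what it does not

`make_genome()`/`make_cohort()` build the validation inputs: a circular
genome of chosen length and GC content (defaults 16.5 kb and 0.45,
mitochondrion-like; 150 kb for a chloroplast-like setting) with the anchor
spliced in, mutated by an exact number of substitutions at seeded
positions, placed on a chosen strand, and rotated by a known amount. The
generator *guarantees uniqueness by construction*: it verifies the planted
copy is the only hit within the search budget on either strand and redraws
the background otherwise, so ambiguity tests must plant duplicates
explicitly and recovery tests have a single well-defined truth. All
randomness is seeded; identical specifications produce byte-identical
files, and each cohort ships a truth table (name, rotation, strand,
mutation count) for assertions.

The background is i.i.d. — it has no repeats, no inverted repeats, no
gene structure, no compositional skew, and mutations are substitutions
only, matching the Hamming matcher's model. Passing the recovery suite
therefore demonstrates that the *algorithm* recovers planted rotations
exactly under its stated model; it does not demonstrate that a given
biological anchor is unique in real genomes (chloroplast inverted repeats,
for instance, are exactly the situation the ambiguity error exists for),
nor anything about indel variation at anchor sites, which the Hamming
model deliberately does not absorb.

Validation problem sizes were fixed once at field-realistic scales: 1,000+
random oracle-equivalence instances ($L \le 200$, $w \le 20$, $m \le 5$,
at least 50 with an origin-spanning sole hit); a 200-record
mitochondria-like cohort (16.5 kb, budget 4) and a 50-record
chloroplast-like cohort (150 kb, budget 1) rotated end-to-end through the
CLI with exact truth-table recovery required; 500-case property suites for
the group laws and involution; and a 200- vs 100-record timing ratio as a
linear-scaling sanity check.

## Known limitations

* Substitution-only tolerance: an indel inside the anchor site shifts the
  register and will read as multiple mismatches; choose anchors in
  indel-poor regions or raise the budget.
* Anchor mode buffers the rotated set in memory to honour the
  all-or-nothing output contract; for organelle-scale data this is a few
  hundred MB at worst. Offset mode streams.
* No alignment, no canonical rotation, no gene-based start detection —
  by design, these stay in the surrounding pipeline.
* Uniqueness is per-record: the tool cannot tell you whether the *same*
  anchor orientation was chosen across records beyond what uniqueness
  implies (it is, whenever each record has exactly one hit).
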