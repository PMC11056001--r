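Package: circrotate
Title: Rotate Linearised Circular DNA Sequences to a Common Start
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rotates linearised circular DNA sequences (organelle, bacterial,
    viral genomes) in FASTA files to a common start position, either by a
    fixed base-pair offset or by locating a user-supplied anchor string with
    a bounded number of mismatches on either strand, including matches that
    span the circular origin. Enforces that the anchor is unique in each
    sequence within the mismatch budget, reporting all candidate locations
    otherwise. Includes streaming FASTA input (plain or gzip), a command-line
    entry point, and a deterministic generator of synthetic circular genomes
    with planted anchors for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
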