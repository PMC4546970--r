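Package: fusionscan
Title: Sequence, Disorder and PTM Characterization of Tumor Fusion-Gene Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the breakpoints of tumor fusion genes and
    the proteins they encode. Extracts fixed-width nucleotide windows around
    breakpoints, computes positional nucleotide preferences and junction
    dinucleotide/trinucleotide spectra against a user-supplied genomic
    background with exact binomial enrichment tests, constructs and translates
    fusion sequences with codon-aware mapping of the nucleotide junction to a
    protein residue, calls intrinsically disordered regions from per-residue
    disorder scores (bundled hydropathy/charge scorer or ingested external
    predictor tracks) with multi-predictor consensus summaries, and quantifies
    phosphorylation and methylation site enrichment in disordered versus
    structured regions and around the breakpoint. A seeded synthetic
    fusion-event generator with known ground truth supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
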