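random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# codons that never translate to stop, for codon-aligned fusion properties
random_stopfree_cds <- function(n_codons) {
  codons <- c("GCT", "TGC", "GAT", "GAA", "TTC", "GGT", "CAT", "ATT",
              "AAA", "CTG", "ATG", "AAT", "CCG", "CAG", "CGT", "TCT",
              "ACC", "GTT", "TGG", "TAT")
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}
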