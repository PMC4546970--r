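test_that("config validation rejects malformed parameters", {
  expect_error(synthetic_config(base_composition = c(A = 1, C = 0, G = 0)),
               "base_composition")
  expect_error(synthetic_config(junction_dinucleotide_bias = c(GX = 0.3)),
               "invalid 2-mer")
  expect_error(synthetic_config(junction_dinucleotide_bias = c(GG = 0.7,
                                                               GA = 0.6)))
  expect_error(synthetic_config(ptm_density_disorder = c(Q = 0.1)))
  expect_error(synthetic_config(p_breakpoint_in_disorder = 1.2))
})

test_that("a bias of 1 plants its dinucleotide at every junction", {
  cfg <- synthetic_config(seed = 5, n_partners = 40,
                          junction_dinucleotide_bias = c(GG = 1),
                          pre_break_trinucleotide_bias = numeric(0))
  gen <- gen_partner_genes(cfg)
  w <- extract_windows(gen$sequences, gen$breakpoints)
  expect_true(all(junction_dinucleotide(w) == "GG"))
})

test_that("a trinucleotide bias of 1 plants the pre-break 3-mer", {
  cfg <- synthetic_config(seed = 6, n_partners = 40,
                          junction_dinucleotide_bias = numeric(0),
                          pre_break_trinucleotide_bias = c(TAG = 1))
  gen <- gen_partner_genes(cfg)
  w <- extract_windows(gen$sequences, gen$breakpoints)
  expect_true(all(pre_break_trinucleotide(w) == "TAG"))
})

test_that("with no bias the junction spectrum matches the i.i.d. product", {
  cfg <- synthetic_config(seed = 8, n_partners = 2500, gene_length = 60,
                          breakpoints_per_gene = 2,
                          junction_dinucleotide_bias = numeric(0),
                          pre_break_trinucleotide_bias = numeric(0))
  gen <- gen_partner_genes(cfg)
  w <- extract_windows(gen$sequences, gen$breakpoints)
  sp <- junction_spectrum(w, k = 2)
  n <- sp$n
  se <- sqrt((1 / 16) * (15 / 16) / n)
  expect_true(all(abs(sp$freq - 1 / 16) < 3 * se))
})

test_that("generation is byte-identical under the same seed", {
  cfg <- synthetic_config(seed = 9, n_partners = 30, n_fusions = 20)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  stage_simulate(cfg, d1)
  stage_simulate(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generated corpora pass the file-format validators", {
  cfg <- synthetic_config(seed = 10, n_partners = 20, n_fusions = 15)
  d <- withr::local_tempdir()
  stage_simulate(cfg, d)
  genes <- read_fasta(file.path(d, "partner_genes.fasta"), "nucleotide")
  expect_silent(bp <- read_breakpoints(file.path(d, "partner_breakpoints.tsv"),
                                       genes))
  expect_equal(nrow(bp), 40L)
  prot <- read_fasta(file.path(d, "fusion_proteins.fasta"), "protein")
  expect_silent(read_breakpoints(file.path(d, "protein_breakpoints.tsv"),
                                 prot))
  expect_silent(read_ptm_sites(file.path(d, "ptm_sites.tsv"), prot))
})

test_that("p = 1 places every junction inside the planted disordered tract", {
  cfg <- synthetic_config(seed = 14, n_fusions = 50,
                          p_breakpoint_in_disorder = 1)
  fus <- gen_fusion_proteins(cfg)
  for (i in seq_len(50)) {
    tr <- truth_region_set(fus$truth, fus$breakpoints$sequence_id[i])
    expect_true(breakpoint_in_disorder(tr, fus$breakpoints$offset[i]))
  }
})

test_that("p = 0 places every junction in an ordered tract, strictly inside", {
  cfg <- synthetic_config(seed = 15, n_fusions = 50,
                          p_breakpoint_in_disorder = 0)
  fus <- gen_fusion_proteins(cfg)
  lens <- fusionscan:::sequence_lengths(fus$proteins)
  for (i in seq_len(50)) {
    tr <- truth_region_set(fus$truth, fus$breakpoints$sequence_id[i])
    expect_false(breakpoint_in_disorder(tr, fus$breakpoints$offset[i]))
  }
  expect_true(all(fus$breakpoints$offset >= 1 &
                    fus$breakpoints$offset < lens[fus$breakpoints$sequence_id]))
})

test_that("extreme PTM densities plant no or all eligible sites", {
  zero <- synthetic_config(seed = 16, n_fusions = 10,
                           ptm_density_disorder = c(S = 0),
                           ptm_density_structural = c(S = 0))
  fus <- gen_fusion_proteins(zero)
  expect_equal(nrow(gen_ptm_sites(fus$proteins, fus$truth, zero)), 0L)

  all_s <- synthetic_config(seed = 16, n_fusions = 10,
                            ptm_density_disorder = c(S = 1),
                            ptm_density_structural = c(S = 0))
  sites <- gen_ptm_sites(fus$proteins, fus$truth, all_s)
  chars <- as.character(fus$proteins)
  for (id in names(chars)) {
    res <- strsplit(chars[[id]], "")[[1]]
    tr <- truth_region_set(fus$truth, id)
    dis <- region_indicator(tr, length(res))
    expected <- which(res == "S" & dis)
    got <- sort(sites$position[sites$sequence_id == id &
                                 sites$residue == "S"])
    expect_equal(got, expected)
  }
})

test_that("short disordered tracts trigger the scorer-window warning", {
  expect_warning(
    gen_fusion_proteins(synthetic_config(seed = 17, n_fusions = 2,
                                         disorder_tract_length = c(10, 15))),
    "scorer window")
})

test_that("infeasible gene lengths are rejected", {
  expect_error(gen_partner_genes(synthetic_config(gene_length = 15,
                                                  breakpoints_per_gene = 2)),
               "too short")
})
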