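test_that("the bundled PTM predictor applies its motif rules", {
  s1 <- bundled_ptm_predict("ASPG", "p")
  expect_equal(s1$position, 2L)
  expect_equal(s1$residue, "S")
  expect_equal(s1$modification, "phosphorylation")

  s2 <- bundled_ptm_predict("ARGA", "p")
  expect_equal(s2$position, 2L)
  expect_equal(s2$modification, "methylation")

  expect_equal(nrow(bundled_ptm_predict("AAAA", "p")), 0L)

  # basophilic context (K within 3 upstream), acidic Y context, KK context
  s3 <- bundled_ptm_predict("KAATADYAKK", "p")
  expect_true(all(c(4L, 7L, 9L, 10L) %in% s3$position))
  # every emitted site satisfies the PTM invariants
  expect_silent(fusionscan:::validate_ptm_sites(
    s3, Biostrings::AAStringSet(c(p = "KAATADYAKK"))))
})

ptm_fixture <- function() {
  # 100 residues: S at fixed positions, disordered half [1, 50]
  res <- rep("A", 100)
  s_pos <- c(5, 15, 25, 35, 60, 70)
  res[s_pos] <- "S"
  protein <- paste(res, collapse = "")
  regions <- call_regions(c(rep(1, 50), rep(0, 50)), sequence_id = "p")
  sites <- data.frame(sequence_id = "p",
                      position = c(5, 15, 25, 35, 60),
                      residue = "S", modification = "phosphorylation",
                      score = NA_real_, stringsAsFactors = FALSE)
  list(protein = protein, regions = regions, sites = sites)
}

test_that("occurrence ratios divide sites by region residues", {
  fx <- ptm_fixture()
  tbl <- enrichment_table(fx$sites, fx$regions, fx$protein)
  s_row <- tbl[tbl$residue_class == "S" & tbl$scope == "protein", ]
  expect_equal(s_row$n_sites_disorder, 4L)
  expect_equal(s_row$n_sites_structural, 1L)
  expect_equal(s_row$ratio_disorder, 4 / 50)
  expect_equal(s_row$ratio_structural, 1 / 50)
  # disordered S sites are denser, echoing the serine pattern on real data
  expect_gt(s_row$ratio_disorder, s_row$ratio_structural)

  # per-class denominator counts only residues of that class
  tbl_cls <- enrichment_table(fx$sites, fx$regions, fx$protein,
                              denominator = "class")
  s_cls <- tbl_cls[tbl_cls$residue_class == "S" & tbl_cls$scope == "protein", ]
  expect_equal(s_cls$ratio_disorder, 4 / 4)
  expect_equal(s_cls$ratio_structural, 1 / 2)
})

test_that("breakpoint-window rows clip at sequence bounds", {
  fx <- ptm_fixture()
  tbl <- enrichment_table(fx$sites, fx$regions, fx$protein, junction = 10)
  w_s <- tbl[tbl$residue_class == "S" & tbl$scope == "breakpoint_window", ]
  # window [1, 60]: disordered residues 1..50, structural 51..60
  expect_equal(w_s$n_residues_disorder, 50L)
  expect_equal(w_s$n_residues_structural, 10L)
  expect_equal(w_s$n_sites_disorder, 4L)
  expect_equal(w_s$n_sites_structural, 1L)
})

test_that("zero-denominator ratios are flagged undefined", {
  fx <- ptm_fixture()
  none <- call_regions(rep(0, 100), sequence_id = "p")
  tbl <- enrichment_table(fx$sites, none, fx$protein)
  expect_true(all(is.na(tbl$ratio_disorder)))
  expect_true(all(is.finite(tbl$ratio_structural)))
})

test_that("sites are validated against protein and regions", {
  fx <- ptm_fixture()
  bad <- fx$sites
  bad$position[1] <- 6 # an A, not S
  expect_error(enrichment_table(bad, fx$regions, fx$protein), "mismatch")
  bad$position[1] <- 200
  expect_error(enrichment_table(bad, fx$regions, fx$protein), "outside")
})

test_that("pooling sums counts, never averages ratios", {
  fx <- ptm_fixture()
  t1 <- enrichment_table(fx$sites, fx$regions, fx$protein)
  # second protein: no sites, all structural
  t2 <- enrichment_table(fx$sites[0, ], call_regions(rep(0, 40)),
                         strrep("A", 40))
  pooled <- pool_enrichment(list(t1, t2))
  s_row <- pooled[pooled$residue_class == "S" & pooled$scope == "protein", ]
  expect_equal(s_row$n_residues_structural, 90L)
  expect_equal(s_row$ratio_structural, 1 / 90)
  # the pooled ratio differs from the mean of per-protein ratios
  expect_false(isTRUE(all.equal(s_row$ratio_structural,
                                mean(c(1 / 50, 0)))))

  t3 <- enrichment_table(fx$sites, fx$regions, fx$protein,
                         denominator = "class")
  expect_error(pool_enrichment(list(t1, t3)), "denominator")
})

test_that("residue conservation holds for every protein", {
  set.seed(31)
  cfg <- synthetic_config(seed = 31, n_fusions = 20)
  fus <- gen_fusion_proteins(cfg)
  sites <- gen_ptm_sites(fus$proteins, fus$truth, cfg)
  for (id in names(fus$proteins)[1:20]) {
    rs <- truth_region_set(fus$truth, id)
    tbl <- enrichment_table(sites[sites$sequence_id == id, ], rs,
                            fus$proteins[[id]])
    n <- Biostrings::width(fus$proteins)[names(fus$proteins) == id]
    expect_true(all(tbl$n_residues_disorder + tbl$n_residues_structural == n))
  }
})

test_that("Fisher comparison matches the hypergeometric oracle", {
  tbl <- data.frame(scope = "protein", residue_class = "S",
                    modification = "phosphorylation",
                    n_sites_disorder = 40L, n_sites_structural = 15L,
                    n_residues_disorder = 500L, n_residues_structural = 500L,
                    ratio_disorder = 40 / 500, ratio_structural = 15 / 500)
  attr(tbl, "denominator") <- "region"
  class(tbl) <- c("ptm_enrichment_table", "data.frame")
  res <- compare_classes(tbl)
  expect_lt(res$p_value, 0.01)

  # independent two-sided hypergeometric computation
  m <- 55; n_tot <- 1000; k_draw <- 500
  probs <- dhyper(0:m, m, n_tot - m, k_draw)
  p_manual <- sum(probs[probs <= dhyper(40, m, n_tot - m, k_draw) * (1 + 1e-7)])
  expect_equal(res$p_value, p_manual, tolerance = 1e-6)
})

test_that("equal ratios give a null Fisher result and empty rows are flagged", {
  tbl <- data.frame(scope = "protein",
                    residue_class = c("S", "K"),
                    modification = c("phosphorylation", "methylation"),
                    n_sites_disorder = c(20L, 0L),
                    n_sites_structural = c(20L, 0L),
                    n_residues_disorder = c(400L, 0L),
                    n_residues_structural = c(400L, 100L),
                    ratio_disorder = c(0.05, NA),
                    ratio_structural = c(0.05, 0))
  attr(tbl, "denominator") <- "region"
  class(tbl) <- c("ptm_enrichment_table", "data.frame")
  res <- compare_classes(tbl)
  expect_gt(res$p_value[1], 0.9)
  expect_false(res$tested[2])
  expect_true(is.na(res$p_value[2]))
})
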