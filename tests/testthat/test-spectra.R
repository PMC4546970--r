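one_window <- function(up, down) {
  w <- data.frame(sequence_id = "w", offset = nchar(up), role = "partner",
                  upstream = up, downstream = down, stringsAsFactors = FALSE)
  attr(w, "k") <- nchar(up)
  w
}

test_that("positional frequencies are exact count ratios", {
  w <- one_window("ACGTA", "CGTAC")
  pf <- positional_frequencies(w)
  expect_equal(pf$n_windows, 1L)
  expect_equal(pf$freq["P-5", "A"], 1)
  expect_equal(pf$freq["P-1", "A"], 1)
  expect_equal(pf$freq["P+1", "C"], 1)
  expect_equal(sum(pf$freq["P-5", ]), 1)
  expect_equal(unname(pf$freq["P-5", c("C", "G", "T")]), c(0, 0, 0))

  w2 <- rbind(one_window("AAAAG", "CCCCC"), one_window("TTTTG", "AAAAA"))
  attr(w2, "k") <- 5L
  pf2 <- positional_frequencies(w2)
  expect_equal(pf2$freq["P-1", "G"], 1)

  expect_error(positional_frequencies(w[0, ]), "no windows")
})

test_that("windows containing N are excluded from spectra", {
  w <- rbind(one_window("ACGTN", "CGTAC"), one_window("ACGTA", "CGTAC"))
  attr(w, "k") <- 5L
  pf <- positional_frequencies(w)
  expect_equal(pf$n_windows, 1L)
  sp <- junction_spectrum(w, k = 2)
  expect_equal(sp$n, 1L)
})

test_that("uniform random windows give near-uniform positional frequencies", {
  set.seed(101)
  n <- 10000
  nts <- c("A", "C", "G", "T")
  mk <- function() apply(matrix(sample(nts, n * 5, TRUE), n, 5), 1,
                         paste, collapse = "")
  w <- data.frame(sequence_id = sprintf("w%d", 1:n), offset = 5,
                  role = "partner", upstream = mk(), downstream = mk(),
                  stringsAsFactors = FALSE)
  attr(w, "k") <- 5L
  pf <- positional_frequencies(w)
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(pf$freq - 0.25) < 5 * se))
})

test_that("junction spectra are direct counts over stated positions", {
  ups <- c("AAAAG", "AAAAG", "AAAAG", "AAAAT")
  downs <- c("GAAAA", "GAAAA", "AAAAA", "CAAAA")
  w <- do.call(rbind, Map(one_window, ups, downs))
  attr(w, "k") <- 5L
  sp <- junction_spectrum(w, k = 2)
  expect_equal(sp$freq[["GG"]], 0.5)
  expect_equal(sp$freq[["GA"]], 0.25)
  expect_equal(sp$freq[["TC"]], 0.25)
  expect_equal(sp$n, 4L)
  expect_error(junction_spectrum(w, k = 4), "k must be")

  # all-identical windows are a point mass
  w_id <- do.call(rbind, replicate(3, one_window("GGGGG", "GGGGG"),
                                   simplify = FALSE))
  attr(w_id, "k") <- 5L
  sp3 <- junction_spectrum(w_id, k = 3)
  expect_equal(sp3$freq[["GGG"]], 1)
  expect_equal(sum(sp3$freq), 1)
})

test_that("background spectrum counts all overlapping k-mers", {
  sp <- background_spectrum(c(s = "AAAA"), k = 2)
  expect_equal(sp$counts[["AA"]], 3)
  expect_equal(sp$freq[["AA"]], 1)

  sp2 <- background_spectrum(c(s = "ACGT"), k = 2)
  expect_equal(unname(sp2$freq[c("AC", "CG", "GT")]), rep(1 / 3, 3))

  expect_error(background_spectrum(Biostrings::DNAStringSet(), 2),
               "no background")
})

test_that("large uniform background approaches the uniform spectrum", {
  set.seed(202)
  n <- 1e6
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  sp <- background_spectrum(c(chr = s), k = 2)
  se <- sqrt((1 / 16) * (15 / 16) / (n - 1))
  expect_true(all(abs(sp$freq - 1 / 16) < 5 * se))
})

test_that("positional P-1 marginal matches the dinucleotide first-character marginal", {
  set.seed(303)
  w <- random_windows(400)
  pf <- positional_frequencies(w)
  sp <- junction_spectrum(w, k = 2)
  first_char <- substr(names(sp$freq), 1, 1)
  marg <- tapply(sp$freq, first_char, sum)
  expect_equal(as.numeric(pf$freq["P-1", names(marg)]), as.numeric(marg))
})

test_that("spectra match the brute-force dictionary count on random windows", {
  set.seed(404)
  w <- random_windows(100)
  pf <- positional_frequencies(w)
  expect_identical(unname(pf$counts), unname(oracle_positional_counts(w)))

  sp2 <- junction_spectrum(w, k = 2)
  expect_identical(as.integer(sp2$counts),
                   unname(oracle_kmer_counts(junction_dinucleotide(w), 2)))

  sp3 <- junction_spectrum(w, k = 3)
  expect_identical(as.integer(sp3$counts),
                   unname(oracle_kmer_counts(pre_break_trinucleotide(w), 3)))

  seqs <- c(a = "ACGTNACGGT", b = "GGGCCCTTAA")
  bg <- background_spectrum(seqs, k = 2)
  expect_identical(as.integer(bg$counts),
                   unname(oracle_background_counts(seqs, 2)))
})

test_that("enrichment under the null gives ratios 1 and large p-values", {
  obs <- kmer_spectrum(setNames(rep(10L, 16), fusionscan:::all_kmers(2)))
  bg <- kmer_spectrum(setNames(rep(1000L, 16), fusionscan:::all_kmers(2)))
  res <- enrichment_test(obs, bg, pseudocount = 0)
  expect_equal(res$ratio, rep(1, 16))
  expect_true(all(res$p_value >= 0.99))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("a strongly planted k-mer tops the enrichment ranking", {
  counts <- setNames(rep(75L, 16), fusionscan:::all_kmers(2))
  counts[["GG"]] <- 875L
  obs <- kmer_spectrum(counts)
  expect_equal(obs$n, 2000L)
  bg <- kmer_spectrum(setNames(rep(10000L, 16), fusionscan:::all_kmers(2)))
  res <- enrichment_test(obs, bg)
  expect_equal(res$kmer[1], "GG")
  expect_lt(res$q_value[1], 1e-6)
})

test_that("a single observation has no power", {
  counts <- setNames(rep(0L, 16), fusionscan:::all_kmers(2))
  counts[["AA"]] <- 1L
  obs <- kmer_spectrum(counts)
  bg <- kmer_spectrum(setNames(rep(100L, 16), fusionscan:::all_kmers(2)))
  res <- enrichment_test(obs, bg)
  expect_true(all(res$q_value >= 0.05))
})

test_that("enrichment rejects mismatched or empty spectra", {
  obs2 <- kmer_spectrum(setNames(rep(1L, 16), fusionscan:::all_kmers(2)))
  bg3 <- kmer_spectrum(setNames(rep(1L, 64), fusionscan:::all_kmers(3)))
  expect_error(enrichment_test(obs2, bg3), "different k")
  empty <- kmer_spectrum(setNames(rep(0L, 16), fusionscan:::all_kmers(2)))
  expect_error(enrichment_test(empty, obs2), "empty")
})
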