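# position labels for a half-width k window: P-k..P-1, P+1..P+k
position_labels <- function(k) {
  c(paste0("P-", k:1), paste0("P+", 1:k))
}

all_kmers <- function(k) {
  stopifnot(k >= 1L)
  grid <- do.call(expand.grid,
                  rep(list(c("A", "C", "G", "T")), k))
  # first factor varies slowest so kmers come out in lexicographic order
  sort(apply(grid, 1L, paste, collapse = ""))
}

has_n <- function(x) grepl("N", x, fixed = TRUE)

#' Positional nucleotide frequencies around the junction
#'
#' Counts each of A/C/G/T at every window position P-k..P-1, P+1..P+k and
#' divides by the number of windows used. Windows containing `N` are excluded
#' so frequencies stay over the four-letter alphabet; each position's
#' frequencies then sum to exactly 1.
#'
#' @param windows Window data frame from [extract_windows()].
#' @return An object of class `positional_freq_table`: list with `freq` and
#'   `counts` (position x nucleotide matrices), `positions`, and `n_windows`.
#' @export
positional_frequencies <- function(windows) {
  if (nrow(windows) == 0L) {
    stop("no windows supplied")
  }
  keep <- !(has_n(windows$upstream) | has_n(windows$downstream))
  windows <- windows[keep, , drop = FALSE]
  if (nrow(windows) == 0L) {
    stop("all windows contain N; nothing to count")
  }
  k <- window_k(windows)
  full <- paste0(windows$upstream, windows$downstream)
  mat <- matrix(unlist(strsplit(full, "", fixed = TRUE)),
                nrow = nrow(windows), byrow = TRUE)
  labels <- position_labels(k)
  counts <- t(apply(mat, 2L, function(col) {
    table(factor(col, levels = c("A", "C", "G", "T")))
  }))
  rownames(counts) <- labels
  structure(
    list(freq = counts / nrow(windows),
         counts = counts,
         positions = labels,
         n_windows = nrow(windows)),
    class = "positional_freq_table"
  )
}

#' @export
print.positional_freq_table <- function(x, ...) {
  cat("Positional nucleotide frequencies over", x$n_windows, "windows\n")
  print(round(x$freq, 4))
  invisible(x)
}

#' Convert a positional frequency table to a data frame
#'
#' @param x A `positional_freq_table`.
#' @param ... Unused.
#' @export
as.data.frame.positional_freq_table <- function(x, ...) {
  data.frame(position = x$positions,
             A = x$freq[, "A"], C = x$freq[, "C"],
             G = x$freq[, "G"], T = x$freq[, "T"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a k-mer spectrum from counts
#'
#' @param counts Named integer vector of k-mer counts; missing k-mers are
#'   filled with 0 so the spectrum always covers all 4^k k-mers.
#' @param k k-mer width (2 or 3).
#' @return A `kmer_spectrum`.
#' @export
kmer_spectrum <- function(counts, k = unique(nchar(names(counts)))) {
  stopifnot(length(k) == 1L, k >= 1L)
  bad <- setdiff(names(counts), all_kmers(k))
  if (length(bad) > 0L) {
    stop("invalid ", k, "-mer name(s): ", paste(bad, collapse = ", "))
  }
  full <- setNames(numeric(4^k), all_kmers(k))
  full[names(counts)] <- counts
  new_kmer_spectrum(full, k)
}

new_kmer_spectrum <- function(counts, k) {
  n <- sum(counts)
  structure(
    list(k = as.integer(k),
         counts = counts,
         freq = if (n > 0L) counts / n else counts,
         n = n),
    class = "kmer_spectrum"
  )
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum (k =", x$k, ") over", x$n, "observations\n")
  print(round(sort(x$freq, decreasing = TRUE), 4))
  invisible(x)
}

#' Junction k-mer spectrum
#'
#' For `k = 2` counts the junction dinucleotide (P-1, P+1); for `k = 3` the
#' pre-break trinucleotide (P-3, P-2, P-1). k-mers containing `N` are
#' excluded. Counts are exact; frequencies are counts over the number of
#' usable windows.
#'
#' @param windows Window data frame from [extract_windows()].
#' @param k 2 or 3.
#' @return A `kmer_spectrum`: list with `k`, named `counts` and `freq` over
#'   all 4^k k-mers, and `n`.
#' @export
junction_spectrum <- function(windows, k = 2L) {
  if (!k %in% c(2L, 3L)) {
    stop("k must be 2 (junction dinucleotide) or 3 (pre-break trinucleotide)")
  }
  if (nrow(windows) == 0L) {
    stop("no windows supplied")
  }
  kmers <- if (k == 2L) junction_dinucleotide(windows)
           else pre_break_trinucleotide(windows)
  kmers <- kmers[!has_n(kmers)]
  if (length(kmers) == 0L) {
    stop("all junction k-mers contain N; nothing to count")
  }
  counts <- table(factor(kmers, levels = all_kmers(k)))
  new_kmer_spectrum(c(unclass(counts)), k)
}

#' Background k-mer spectrum from a sequence set
#'
#' Counts all overlapping k-mers (step 1) in every supplied sequence; k-mers
#' containing `N` are not counted. This is the background the junction
#' spectrum is tested against — typically a large corpus standing in for
#' "all genes".
#'
#' @param seqs Nucleotide sequences (`DNAStringSet` or named character).
#' @param k 2 or 3.
#' @return A `kmer_spectrum`.
#' @export
background_spectrum <- function(seqs, k = 2L) {
  if (!k %in% c(2L, 3L)) {
    stop("k must be 2 or 3")
  }
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (length(seqs) == 0L) {
    stop("no background sequences supplied")
  }
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k,
                                                         step = 1L))
  counts <- counts[all_kmers(k)]
  if (sum(counts) == 0L) {
    stop("background contains no usable k-mers")
  }
  new_kmer_spectrum(counts, k)
}

#' Exact binomial enrichment of junction k-mers against a background
#'
#' For each of the 4^k k-mers, tests the observed junction count (out of `n`
#' windows) against the background frequency with a two-sided exact binomial
#' test, then applies Benjamini-Hochberg correction across the 4^k tests.
#' A pseudocount (default 1) is added to every background k-mer count so
#' background frequencies are strictly positive and ratios are defined.
#'
#' @param observed Junction `kmer_spectrum`.
#' @param background Background `kmer_spectrum` of the same `k`.
#' @param pseudocount Count added to each background k-mer.
#' @return Data frame with columns `kmer`, `observed_count`, `observed_freq`,
#'   `background_freq`, `ratio`, `p_value`, `q_value`, sorted by descending
#'   ratio.
#' @export
enrichment_test <- function(observed, background, pseudocount = 1L) {
  stopifnot(inherits(observed, "kmer_spectrum"),
            inherits(background, "kmer_spectrum"))
  if (observed$k != background$k) {
    stop("observed and background spectra have different k")
  }
  if (observed$n == 0L) {
    stop("observed spectrum is empty")
  }
  bg_counts <- background$counts + pseudocount
  bg_freq <- bg_counts / sum(bg_counts)
  kmers <- names(observed$counts)
  p <- vapply(kmers, function(km) {
    stats::binom.test(observed$counts[[km]], observed$n,
                      p = bg_freq[[km]],
                      alternative = "two.sided")$p.value
  }, numeric(1))
  res <- data.frame(
    kmer = kmers,
    observed_count = as.integer(observed$counts),
    observed_freq = as.numeric(observed$freq),
    background_freq = as.numeric(bg_freq),
    ratio = as.numeric(observed$freq) / as.numeric(bg_freq),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(-res$ratio, res$kmer), , drop = FALSE]
}
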