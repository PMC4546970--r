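# Independent brute-force oracles: plain dictionary counting, no shared code
# with the implementation under test.

oracle_positional_counts <- function(windows) {
  k <- nchar(windows$upstream[1])
  labels <- c(paste0("P-", k:1), paste0("P+", 1:k))
  counts <- matrix(0L, nrow = 2 * k, ncol = 4,
                   dimnames = list(labels, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(windows))) {
    full <- paste0(windows$upstream[i], windows$downstream[i])
    for (p in seq_len(2 * k)) {
      ch <- substr(full, p, p)
      counts[p, ch] <- counts[p, ch] + 1L
    }
  }
  counts
}

oracle_kmer_counts <- function(kmers, k) {
  dict <- new.env()
  for (km in kmers) {
    cur <- mget(km, envir = dict, ifnotfound = 0L)[[1]]
    assign(km, cur + 1L, envir = dict)
  }
  nts <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(nts), k), stringsAsFactors = FALSE)
  all_k <- sort(apply(grid, 1, paste, collapse = ""))
  vapply(all_k, function(km) mget(km, envir = dict, ifnotfound = 0L)[[1]],
         integer(1))
}

oracle_background_counts <- function(seqs, k) {
  kmers <- character(0)
  for (s in as.character(seqs)) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (!grepl("N", km, fixed = TRUE)) kmers <- c(kmers, km)
    }
  }
  oracle_kmer_counts(kmers, k)
}

oracle_at_least_k <- function(calls, k) {
  sum(apply(calls, 1, function(row) sum(row) >= k))
}

# uniform random windows (half-width k) for counting-oracle tests
random_windows <- function(n, k = 5) {
  nts <- c("A", "C", "G", "T")
  w <- data.frame(
    sequence_id = sprintf("w%d", seq_len(n)),
    offset = k,
    role = "partner",
    upstream = vapply(seq_len(n), function(i)
      paste(sample(nts, k, replace = TRUE), collapse = ""), character(1)),
    downstream = vapply(seq_len(n), function(i)
      paste(sample(nts, k, replace = TRUE), collapse = ""), character(1)),
    stringsAsFactors = FALSE
  )
  attr(w, "k") <- as.integer(k)
  w
}

jaccard_regions <- function(called, truth) {
  a <- region_indicator(called)
  b <- region_indicator(truth)
  sum(a & b) / sum(a | b)
}
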