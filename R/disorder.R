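# Kyte-Doolittle hydropathy; X (unknown) treated as neutral 0
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

RESIDUE_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

# truncated sliding-window mean: at the ends the mean is over the residues
# actually available, so profile length always equals sequence length
window_mean <- function(x, window) {
  hw <- (window - 1L) %/% 2L
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(1L, idx - hw)
  hi <- pmin(n, idx + hw)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Construct a disorder profile
#'
#' @param sequence_id Sequence id the scores belong to.
#' @param scores Numeric per-residue scores in `[0, 1]`.
#' @param predictor Name of the predictor that produced the scores.
#' @param threshold Disorder decision threshold (residues with score strictly
#'   greater are disordered).
#' @return An object of class `disorder_profile`.
#' @export
disorder_profile <- function(sequence_id, scores, predictor = "external",
                             threshold = 0.5) {
  stopifnot(is.numeric(scores), length(scores) >= 1L,
            all(is.finite(scores)))
  if (any(scores < 0 | scores > 1)) {
    stop("disorder scores must lie in [0, 1]")
  }
  structure(
    list(sequence_id = sequence_id, predictor = predictor,
         scores = as.numeric(scores), threshold = threshold),
    class = "disorder_profile"
  )
}

#' Bundled hydropathy/charge disorder scorer
#'
#' A deterministic per-residue disorder score built on the classical
#' unfoldability index: over a sliding window,
#' `u = 2.785 * <H> - |<q>| - 1.151`, where `<H>` is the mean Kyte-Doolittle
#' hydropathy rescaled to `[0, 1]` via `(h + 4.5) / 9` and `<q>` the mean net
#' charge (K, R = +1; D, E = -1; others 0). The disorder score is
#' `clip(0.5 - u / 2, 0, 1)`, so the folded/unfolded boundary `u = 0` maps
#' onto the conventional 0.5 disorder threshold. Windows are truncated at the
#' sequence ends (mean over the available residues). This scorer stands in
#' for external disorder predictors when their score tracks are not
#' available; real analyses should ingest real predictor tracks via
#' [read_score_track()].
#'
#' @param protein Protein sequence (character scalar or `AAString`), or a
#'   named length-1 character vector whose name becomes the sequence id.
#' @param window Odd sliding-window width in residues (default 21).
#' @param sequence_id Sequence id recorded on the profile.
#' @return A `disorder_profile` with one score per residue.
#' @export
bundled_disorder_score <- function(protein, window = 21L,
                                   sequence_id = NULL) {
  if (inherits(protein, "DNAString") || inherits(protein, "DNAStringSet") ||
      inherits(protein, "RNAString")) {
    stop("bundled_disorder_score expects a protein sequence")
  }
  if (is.null(sequence_id)) {
    sequence_id <- if (!is.null(names(protein))) names(protein)[1] else "protein"
  }
  s <- as.character(protein)[1]
  stopifnot(nchar(s) >= 1L)
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be a positive odd integer")
  }
  res <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  unknown <- setdiff(unique(res), names(KYTE_DOOLITTLE))
  if (length(unknown) > 0L) {
    stop("non-protein character(s): ", paste(unknown, collapse = ", "))
  }
  h <- (KYTE_DOOLITTLE[res] + 4.5) / 9
  q <- RESIDUE_CHARGE[res]
  q[is.na(q)] <- 0
  u <- 2.785 * window_mean(h, window) - abs(window_mean(q, window)) - 1.151
  score <- pmin(pmax(0.5 - u / 2, 0), 1)
  disorder_profile(sequence_id, unname(score),
                   predictor = paste0("hydropathy_charge_w", window))
}

#' Call disordered regions from a profile
#'
#' Disordered regions are maximal runs of consecutive residues whose score is
#' strictly greater than the threshold (a residue scoring exactly at the
#' threshold is ordered); runs shorter than `min_length` are dropped.
#'
#' @param profile A `disorder_profile`, or a plain numeric score vector.
#' @param min_length Minimum region length retained.
#' @param threshold Override the profile's threshold.
#' @param sequence_id Id used when `profile` is a bare numeric vector.
#' @return An object of class `region_set`: list with `sequence_id`,
#'   `n_residues`, and `disordered`, a data frame of 1-based inclusive
#'   `[start, end]` intervals (sorted, disjoint, maximal).
#' @export
call_regions <- function(profile, min_length = 1L, threshold = NULL,
                         sequence_id = "protein") {
  if (inherits(profile, "disorder_profile")) {
    scores <- profile$scores
    if (is.null(threshold)) threshold <- profile$threshold
    sequence_id <- profile$sequence_id
  } else {
    scores <- as.numeric(profile)
    if (is.null(threshold)) threshold <- 0.5
  }
  r <- rle(scores > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  structure(
    list(sequence_id = sequence_id,
         n_residues = length(scores),
         disordered = data.frame(start = starts[keep], end = ends[keep],
                                 row.names = NULL)),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set for", x$sequence_id, "(", x$n_residues, "residues ):",
      nrow(x$disordered), "disordered region(s)\n")
  if (nrow(x$disordered) > 0L) print(x$disordered)
  invisible(x)
}

#' Per-residue disordered indicator from a region set
#'
#' @param regions A `region_set`.
#' @param n_residues Protein length; defaults to the region set's.
#' @return Logical vector, `TRUE` where the residue is disordered.
#' @export
region_indicator <- function(regions, n_residues = regions$n_residues) {
  ind <- logical(n_residues)
  d <- regions$disordered
  for (i in seq_len(nrow(d))) {
    ind[d$start[i]:d$end[i]] <- TRUE
  }
  ind
}

#' Is a breakpoint residue inside a disordered region?
#'
#' @param regions A `region_set`.
#' @param junction_residue 1-based residue index of the breakpoint.
#' @return `TRUE` iff the residue lies in a disordered interval.
#' @export
breakpoint_in_disorder <- function(regions, junction_residue) {
  stopifnot(inherits(regions, "region_set"))
  if (junction_residue < 1L || junction_residue > regions$n_residues) {
    stop("junction residue ", junction_residue, " outside 1..",
         regions$n_residues)
  }
  d <- regions$disordered
  any(d$start <= junction_residue & junction_residue <= d$end)
}

#' Multi-predictor consensus over breakpoint disorder calls
#'
#' Partitions breakpoints over the 2^k subsets of predictors that called
#' them disordered (Venn counts) and derives the at-least-k series. Every
#' predictor must cover every breakpoint (no ragged coverage).
#'
#' @param calls Logical matrix, rows = breakpoints, columns = predictors
#'   (column names used as predictor names).
#' @return An object of class `consensus_summary`: `n_breakpoints`,
#'   `per_predictor_disordered`, `venn_counts` (named by `&`-joined predictor
#'   subsets, `"none"` for the empty subset), and `at_least_k`.
#' @export
consensus <- function(calls) {
  calls <- as.matrix(calls)
  if (anyNA(calls)) {
    stop("ragged coverage: every predictor must call every breakpoint")
  }
  storage.mode(calls) <- "logical"
  preds <- colnames(calls)
  if (is.null(preds)) {
    preds <- paste0("predictor", seq_len(ncol(calls)))
    colnames(calls) <- preds
  }
  n <- nrow(calls)
  K <- ncol(calls)
  subset_key <- apply(calls, 1L, function(row) {
    if (!any(row)) "none" else paste(preds[row], collapse = "&")
  })
  # enumerate all 2^K subsets so absent cells report an explicit 0
  all_keys <- c("none", unlist(lapply(seq_len(K), function(m) {
    apply(utils::combn(preds, m), 2L, paste, collapse = "&")
  })))
  venn <- setNames(integer(length(all_keys)), all_keys)
  tab <- table(subset_key)
  venn[names(tab)] <- as.integer(tab)
  stopifnot(sum(venn) == n)
  n_calls <- rowSums(calls)
  at_least_k <- vapply(seq_len(K), function(k) sum(n_calls >= k), integer(1))
  names(at_least_k) <- paste0("at_least_", seq_len(K))
  stopifnot(all(diff(at_least_k) <= 0L))
  structure(
    list(n_breakpoints = n,
         per_predictor_disordered = colSums(calls),
         venn_counts = venn,
         at_least_k = at_least_k),
    class = "consensus_summary"
  )
}

#' @export
print.consensus_summary <- function(x, ...) {
  cat("Consensus over", x$n_breakpoints, "breakpoints\n")
  cat("Per predictor:\n")
  print(x$per_predictor_disordered)
  cat("Venn counts:\n")
  print(x$venn_counts)
  cat("At least k predictors:\n")
  print(x$at_least_k)
  invisible(x)
}

#' Fraction of breakpoints called disordered
#'
#' @param calls Logical vector of single-predictor breakpoint calls.
#' @return Disordered count over n.
#' @export
disorder_fraction <- function(calls) {
  calls <- as.logical(calls)
  stopifnot(length(calls) >= 1L, !anyNA(calls))
  mean(calls)
}

#' Flag proteins by minimum length
#'
#' Disorder prediction is customarily restricted to proteins longer than a
#' minimum (100 aa here by default); this helper flags rather than drops, so
#' the caller decides.
#'
#' @param proteins `AAStringSet` or named character vector.
#' @param min_aa Minimum length (exclusive: keep when length > `min_aa`).
#' @return Named logical vector, `TRUE` for proteins passing the filter.
#' @export
flag_long_proteins <- function(proteins, min_aa = 100L) {
  lens <- sequence_lengths(proteins)
  lens > min_aa
}
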