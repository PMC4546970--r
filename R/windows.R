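#' Extract the junction window around one breakpoint
#'
#' The window covers the `2k` positions P-k..P-1, P+1..P+k around the
#' junction (there is no position 0): `upstream = seq[offset-k+1 .. offset]`,
#' `downstream = seq[offset+1 .. offset+k]`. Windows that would overlap a
#' sequence end are not constructed (returns `NULL`); they are skipped, never
#' padded, so positional frequencies stay undistorted.
#'
#' @param seq A single sequence (character scalar or `XString`).
#' @param offset Breakpoint offset (residues retained before the junction).
#' @param k Half-window width (default 5, the ten-position window).
#' @return A list with `upstream` and `downstream` k-character strings, or
#'   `NULL` if the window does not fit.
#' @export
extract_window <- function(seq, offset, k = 5L) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L, k >= 1L)
  n <- nchar(seq)
  if (offset < k || offset + k > n) {
    return(NULL)
  }
  list(upstream = substr(seq, offset - k + 1L, offset),
       downstream = substr(seq, offset + 1L, offset + k))
}

#' Extract junction windows for a breakpoint table
#'
#' Vectorized form of [extract_window()]: one row per breakpoint whose window
#' fits inside its sequence; breakpoints too close to an end are dropped with
#' a message.
#'
#' @param seqs Named sequence set (`XStringSet` or character vector).
#' @param breakpoints Breakpoint data frame (see [read_breakpoints()]).
#' @param k Half-window width.
#' @return A data frame with columns `sequence_id`, `offset`, `role`,
#'   `upstream`, `downstream`; attribute `k` records the half-width.
#' @export
extract_windows <- function(seqs, breakpoints, k = 5L) {
  stopifnot(k >= 1L)
  chars <- setNames(as.character(seqs), names(seqs))
  unknown <- setdiff(breakpoints$sequence_id, names(chars))
  if (length(unknown) > 0L) {
    stop("breakpoints reference unknown sequence(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  s <- chars[breakpoints$sequence_id]
  n <- nchar(s)
  off <- breakpoints$offset
  ok <- off >= k & off + k <= n
  if (sum(!ok) > 0L) {
    message(sum(!ok), " breakpoint(s) skipped: window overlaps a sequence end")
  }
  out <- data.frame(
    sequence_id = breakpoints$sequence_id[ok],
    offset = off[ok],
    role = if ("role" %in% names(breakpoints)) breakpoints$role[ok]
           else NA_character_,
    upstream = substr(s[ok], off[ok] - k + 1L, off[ok]),
    downstream = substr(s[ok], off[ok] + 1L, off[ok] + k),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "k") <- as.integer(k)
  out
}

window_k <- function(windows) {
  k <- attr(windows, "k")
  if (is.null(k)) k <- unique(nchar(windows$upstream))
  stopifnot(length(k) == 1L)
  as.integer(k)
}

#' Junction dinucleotide of a window
#'
#' The 2-mer formed by positions (P-1, P+1): the last upstream character and
#' the first downstream character.
#'
#' @param windows Window data frame from [extract_windows()].
#' @return Character vector of 2-mers, one per window.
#' @export
junction_dinucleotide <- function(windows) {
  k <- window_k(windows)
  paste0(substr(windows$upstream, k, k), substr(windows$downstream, 1L, 1L))
}

#' Pre-break trinucleotide of a window
#'
#' The 3-mer at positions (P-3, P-2, P-1): the last three upstream characters.
#'
#' @param windows Window data frame from [extract_windows()].
#' @return Character vector of 3-mers, one per window.
#' @export
pre_break_trinucleotide <- function(windows) {
  k <- window_k(windows)
  stopifnot(k >= 3L)
  substr(windows$upstream, k - 2L, k)
}
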