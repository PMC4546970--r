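#' Build a fusion nucleotide sequence from two partner segments
#'
#' The fused sequence is the exact concatenation of the 5' partner's prefix
#' `a[1..bp_a]` and the 3' partner's suffix `b[bp_b+1..end]`. In fused
#' coordinates the junction offset equals `bp_a`.
#'
#' @param a,b Partner nucleotide sequences (character scalar or `DNAString`).
#' @param bp_a Offset on `a`: residues retained before the junction
#'   (`1 <= bp_a < length(a)`).
#' @param bp_b Offset on `b`: residues discarded before the retained suffix
#'   (`0 <= bp_b < length(b)`; 0 keeps all of `b`).
#' @param a_id,b_id Partner ids recorded on the construct.
#' @return A `fusion_construct`: list with the partner ids and offsets,
#'   `fused_nt`, and empty translation slots (`frame_offset`, `protein`,
#'   `junction_residue`, `junction_in_codon`) filled by [translate_fusion()]
#'   and [map_breakpoint_to_residue()].
#' @export
build_fusion <- function(a, bp_a, b, bp_b, a_id = "partner_a",
                         b_id = "partner_b") {
  a <- as.character(a)
  b <- as.character(b)
  la <- nchar(a)
  lb <- nchar(b)
  if (bp_a < 1L || bp_a >= la) {
    stop("bp_a must satisfy 1 <= bp_a < length(a) (got ", bp_a, " on length ",
         la, ")")
  }
  if (bp_b < 0L || bp_b >= lb) {
    stop("bp_b must satisfy 0 <= bp_b < length(b) (got ", bp_b, " on length ",
         lb, ")")
  }
  structure(
    list(partner_a_id = a_id, partner_b_id = b_id,
         bp_a = as.integer(bp_a), bp_b = as.integer(bp_b),
         fused_nt = paste0(substr(a, 1L, bp_a), substr(b, bp_b + 1L, lb)),
         frame_offset = NA_integer_, protein = NA_character_,
         junction_residue = NA_integer_, junction_in_codon = NA_character_),
    class = "fusion_construct"
  )
}

#' @export
print.fusion_construct <- function(x, ...) {
  cat("Fusion construct ", x$partner_a_id, "[1..", x$bp_a, "] + ",
      x$partner_b_id, "[", x$bp_b + 1L, "..] (", nchar(x$fused_nt),
      " nt)\n", sep = "")
  if (!is.na(x$protein)) {
    cat("  protein: ", nchar(x$protein), " aa; junction residue ",
        x$junction_residue, " (", x$junction_in_codon, ")\n", sep = "")
  }
  invisible(x)
}

#' Translate a fusion construct
#'
#' Standard genetic code, reading from `frame_offset` (0, 1 or 2); a partial
#' trailing codon is dropped. Under `truncate_at_first_stop` (the default,
#' mirroring the translated product of an out-of-frame fusion) the protein
#' ends before the first stop codon; `keep_through` keeps `*` characters for
#' QC of premature stops.
#'
#' @param fc A `fusion_construct`.
#' @param frame_offset Position of the first codon base in `fused_nt`
#'   (0 assumes CDS-trimmed input).
#' @param stop_policy `"truncate_at_first_stop"` or `"keep_through"`.
#' @return The construct with `protein`, `frame_offset`, `junction_residue`
#'   and `junction_in_codon` filled.
#' @export
translate_fusion <- function(fc, frame_offset = 0L,
                             stop_policy = c("truncate_at_first_stop",
                                             "keep_through")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(inherits(fc, "fusion_construct"))
  if (!frame_offset %in% 0:2) {
    stop("frame_offset must be 0, 1 or 2")
  }
  coding <- substr(fc$fused_nt, frame_offset + 1L, nchar(fc$fused_nt))
  n_codons <- nchar(coding) %/% 3L
  if (n_codons < 1L) {
    stop("fused sequence shorter than one codon after frame offset")
  }
  coding <- substr(coding, 1L, 3L * n_codons)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(coding),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  if (stop_policy == "truncate_at_first_stop") {
    aa <- sub("\\*.*$", "", aa)
  }
  fc$frame_offset <- as.integer(frame_offset)
  fc$protein <- aa
  m <- map_breakpoint_to_residue(fc)
  fc$junction_residue <- m$junction_residue
  fc$junction_in_codon <- m$junction_in_codon
  fc
}

#' Map the nucleotide junction to a protein residue
#'
#' With `d = bp_a - frame_offset` coding nucleotides from partner A: if `d`
#' is a multiple of 3 the junction falls between codons (`aligned`) and the
#' last residue wholly from partner A is `d / 3`; otherwise the junction
#' splits a codon (`split`) and the chimeric codon's residue `ceil(d / 3)` is
#' reported. In both cases `3r - 2 <= d <= 3r` holds for the reported
#' residue `r`.
#'
#' @param fc A `fusion_construct` (uses its `bp_a` and `frame_offset`), or a
#'   numeric `bp_a` when `frame_offset` is given explicitly.
#' @param frame_offset Frame offset; defaults to the construct's (or 0).
#' @return List with `junction_residue` (integer) and `junction_in_codon`
#'   (`"aligned"` or `"split"`).
#' @export
map_breakpoint_to_residue <- function(fc, frame_offset = NULL) {
  if (inherits(fc, "fusion_construct")) {
    bp_a <- fc$bp_a
    if (is.null(frame_offset)) {
      frame_offset <- if (is.na(fc$frame_offset)) 0L else fc$frame_offset
    }
  } else {
    bp_a <- as.integer(fc)
    if (is.null(frame_offset)) frame_offset <- 0L
  }
  d <- bp_a - frame_offset
  if (d <= 0L) {
    stop("junction lies upstream of the coding start (bp_a - frame_offset = ",
         d, ")")
  }
  if (d %% 3L == 0L) {
    list(junction_residue = d %/% 3L, junction_in_codon = "aligned")
  } else {
    list(junction_residue = as.integer(ceiling(d / 3)),
         junction_in_codon = "split")
  }
}
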