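#' Read a FASTA file with alphabet validation
#'
#' Reads nucleotide or protein FASTA into a Biostrings string set. Residues
#' are uppercased; every character must belong to the declared alphabet
#' (`ACGTN` for nucleotide, the 20 amino acids plus `X` for protein) and
#' record ids (first whitespace-delimited token of the header) must be unique.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet], named
#'   by record id.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    stop("no FASTA records in ", path)
  }
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids
  validate_alphabet(seqs, alphabet)
  if (alphabet == "nucleotide") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
}

validate_alphabet <- function(seqs, alphabet) {
  allowed <- if (alphabet == "nucleotide") NT_CHARS else AA_CHARS
  pattern <- paste0("[^", paste(allowed, collapse = ""), "]")
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (nchar(s) == 0L) {
      stop("empty sequence for id '", id, "'")
    }
    m <- regexpr(pattern, s)
    if (m > 0L) {
      stop("illegal ", alphabet, " character '", substr(s, m, m),
           "' in sequence '", id, "' at position ", as.integer(m))
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::XStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a breakpoint table
#'
#' TSV with columns `sequence_id`, `offset`, `role`, `molecule` (tab-separated,
#' `#` comments, header mandatory). `offset` is the 1-based count of residues
#' retained 5'/N-terminal of the junction, so the junction lies between
#' `offset` and `offset + 1` and the junction dinucleotide is
#' `(seq[offset], seq[offset + 1])`.
#'
#' @param path Path to the TSV.
#' @param sequences Optional named sequence set; when supplied, every record's
#'   id must be present and `1 <= offset < length(sequence)` is enforced.
#' @return A data frame of validated breakpoint records.
#' @export
read_breakpoints <- function(path, sequences = NULL) {
  df <- read_tsv_checked(path, c("sequence_id", "offset", "role", "molecule"))
  df$sequence_id <- as.character(df$sequence_id)
  df$offset <- as.integer(df$offset)
  validate_breakpoints(df, sequences)
  df
}

validate_breakpoints <- function(df, sequences = NULL) {
  if (any(is.na(df$offset)) || any(df$offset < 1L)) {
    stop("breakpoint offsets must be integers >= 1")
  }
  bad_role <- setdiff(unique(df$role), c("partner", "fusion"))
  if (length(bad_role) > 0L) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  bad_mol <- setdiff(unique(df$molecule), c("nucleotide", "protein"))
  if (length(bad_mol) > 0L) {
    stop("unknown molecule(s): ", paste(bad_mol, collapse = ", "))
  }
  if (!is.null(sequences)) {
    lens <- sequence_lengths(sequences)
    unknown <- setdiff(df$sequence_id, names(lens))
    if (length(unknown) > 0L) {
      stop("breakpoint references unknown sequence(s): ",
           paste(unknown, collapse = ", "))
    }
    out <- df$offset >= lens[df$sequence_id]
    if (any(out)) {
      stop("breakpoint offset out of range (needs a P+1 residue) for: ",
           paste(df$sequence_id[out], collapse = ", "))
    }
  }
  invisible(TRUE)
}

sequence_lengths <- function(sequences) {
  if (is.character(sequences)) {
    setNames(nchar(sequences), names(sequences))
  } else {
    setNames(Biostrings::width(sequences), names(sequences))
  }
}

#' Read per-residue score tracks
#'
#' TSV with columns `sequence_id`, `predictor`, `position`, `score`: one row
#' per residue, positions contiguous from 1. This is the ingestion seam for
#' external disorder predictors (IUPred-, PONDR-, PreDisorder-style output
#' reshaped to one score per residue).
#'
#' @param path Path to the TSV.
#' @param sequences Optional sequence set; track lengths are checked against
#'   sequence lengths when supplied.
#' @return A data frame of score-track rows.
#' @export
read_score_track <- function(path, sequences = NULL) {
  df <- read_tsv_checked(path, c("sequence_id", "predictor", "position", "score"))
  df$sequence_id <- as.character(df$sequence_id)
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score))) {
    stop("non-finite score(s) in ", path)
  }
  lens <- if (is.null(sequences)) NULL else sequence_lengths(sequences)
  for (key in unique(paste(df$sequence_id, df$predictor, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sel <- df$sequence_id == parts[1] & df$predictor == parts[2]
    pos <- sort(df$position[sel])
    if (!identical(pos, seq_along(pos))) {
      stop("score track for '", parts[1], "' (", parts[2],
           ") does not cover positions 1..n contiguously")
    }
    if (!is.null(lens)) {
      if (!parts[1] %in% names(lens)) {
        stop("score track references unknown sequence '", parts[1], "'")
      }
      if (length(pos) != lens[[parts[1]]]) {
        stop("score track length ", length(pos), " does not match sequence '",
             parts[1], "' length ", lens[[parts[1]]])
      }
    }
  }
  df
}

#' Extract one track from a score-track table as a numeric vector
#'
#' @param tracks Data frame from [read_score_track()].
#' @param sequence_id,predictor Track key.
#' @return Numeric vector of scores ordered by position.
#' @export
track_scores <- function(tracks, sequence_id, predictor) {
  sel <- tracks$sequence_id == sequence_id & tracks$predictor == predictor
  if (!any(sel)) {
    stop("no track for sequence '", sequence_id, "', predictor '",
         predictor, "'")
  }
  sub <- tracks[sel, ]
  sub$score[order(sub$position)]
}

#' Read a PTM-site table
#'
#' TSV with columns `sequence_id`, `position`, `residue`, `modification` and
#' optionally `score`. Phosphorylation sites must sit on S/T/Y and
#' methylation sites on R/K; when `sequences` is supplied the residue letter
#' is checked against the sequence.
#'
#' @param path Path to the TSV.
#' @param sequences Optional protein sequence set for residue validation.
#' @return A data frame of PTM sites.
#' @export
read_ptm_sites <- function(path, sequences = NULL) {
  df <- read_tsv_checked(path, c("sequence_id", "position", "residue",
                                 "modification"))
  df$sequence_id <- as.character(df$sequence_id)
  df$position <- as.integer(df$position)
  if (!"score" %in% names(df)) {
    df$score <- NA_real_
  }
  validate_ptm_sites(df, sequences)
  df
}

validate_ptm_sites <- function(df, sequences = NULL) {
  bad_res <- setdiff(unique(df$residue), PTM_RESIDUES)
  if (length(bad_res) > 0L) {
    stop("PTM residue(s) outside {S,T,Y,R,K}: ", paste(bad_res, collapse = ", "))
  }
  ok <- df$modification == MOD_FOR_RESIDUE[df$residue]
  if (any(!ok | is.na(ok))) {
    stop("modification/residue mismatch (phosphorylation on S/T/Y, ",
         "methylation on R/K) at row(s): ",
         paste(utils::head(which(!ok), 5L), collapse = ", "))
  }
  if (!is.null(sequences)) {
    seqs <- as.character(sequences)
    for (i in seq_len(nrow(df))) {
      s <- seqs[[df$sequence_id[i]]]
      if (is.null(s) || is.na(s)) {
        stop("PTM site references unknown sequence '", df$sequence_id[i], "'")
      }
      actual <- substr(s, df$position[i], df$position[i])
      if (actual != df$residue[i]) {
        stop("PTM site residue mismatch on '", df$sequence_id[i],
             "' position ", df$position[i], ": table says ", df$residue[i],
             ", sequence has ", actual)
      }
    }
  }
  invisible(TRUE)
}

#' Keep PTM sites at or above a score threshold
#'
#' Sites with missing scores are kept (external tables need not carry scores).
#' The default 0.5 matches the customary NetPhos-style cutoff.
#'
#' @param sites PTM-site data frame.
#' @param min_score Minimum score retained.
#' @export
filter_ptm_sites <- function(sites, min_score = 0.5) {
  sites[is.na(sites$score) | sites$score >= min_score, , drop = FALSE]
}

#' Write a result table as TSV
#'
#' Tab-separated, no quoting, no row names; the matching reader is
#' [read_result_table()]. Round-trips are loss-free on valid data.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Path to the TSV.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
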