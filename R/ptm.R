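#' Bundled naive PTM motif predictor
#'
#' A deterministic rule-based stand-in for neural-network/SVM PTM predictors,
#' bundled so the pipeline is testable offline; real analyses should ingest
#' predictor output via [read_ptm_sites()]. Rules:
#' * phospho-S/T: S or T followed by P, or preceded within 3 residues by R
#'   or K (basophilic kinase context);
#' * phospho-Y: Y preceded within 2 residues by D or E (acidic context);
#' * methyl-R: R adjacent to G (RG or GR context);
#' * methyl-K: K adjacent to K (KK context).
#'
#' @param protein Protein sequence (character scalar or `AAString`).
#' @param sequence_id Id recorded on the sites.
#' @return Data frame of PTM sites (`sequence_id`, `position`, `residue`,
#'   `modification`, `score = NA`), satisfying all PTM-site invariants.
#' @export
bundled_ptm_predict <- function(protein, sequence_id = "protein") {
  s <- toupper(as.character(protein)[1])
  res <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(res)
  nxt <- c(res[-1], "")
  prev_window <- function(i, w) res[seq(max(1L, i - w), max(0L, i - 1L))]
  pos <- integer(0)
  mod <- character(0)
  for (i in seq_len(n)) {
    r <- res[i]
    if (r %in% c("S", "T")) {
      if (nxt[i] == "P" || any(prev_window(i, 3L) %in% c("R", "K"))) {
        pos <- c(pos, i); mod <- c(mod, "phosphorylation")
      }
    } else if (r == "Y") {
      if (any(prev_window(i, 2L) %in% c("D", "E"))) {
        pos <- c(pos, i); mod <- c(mod, "phosphorylation")
      }
    } else if (r == "R") {
      if ((i > 1L && res[i - 1L] == "G") || (i < n && res[i + 1L] == "G")) {
        pos <- c(pos, i); mod <- c(mod, "methylation")
      }
    } else if (r == "K") {
      if ((i > 1L && res[i - 1L] == "K") || (i < n && res[i + 1L] == "K")) {
        pos <- c(pos, i); mod <- c(mod, "methylation")
      }
    }
  }
  data.frame(sequence_id = rep(sequence_id, length(pos)), position = pos,
             residue = res[pos], modification = mod,
             score = rep(NA_real_, length(pos)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' PTM occurrence ratios in disordered vs structured regions
#'
#' For each residue class (phospho S, T, Y; methyl R, K) counts predicted
#' sites falling in disordered versus structured residues of one protein and
#' forms occurrence ratios. Two denominator conventions:
#' * `"region"` (default): sites per residue of the region (e.g. the fraction
#'   of disordered residues that are predicted phospho-serines);
#' * `"class"`: sites per residue *of that amino-acid class* in the region
#'   (e.g. the fraction of disordered serines that are predicted sites).
#'
#' When `junction` is given, a second block of rows (`scope =
#' "breakpoint_window"`) restricts the same computation to residues within
#' `[junction - flank, junction + flank]`, clipped at the sequence ends.
#' Ratios with a zero denominator are reported as `NA` (flagged undefined).
#'
#' @param sites PTM-site data frame for this protein.
#' @param regions A `region_set` for this protein.
#' @param protein Protein sequence.
#' @param junction Optional 1-based breakpoint residue.
#' @param denominator `"region"` or `"class"`.
#' @param flank Half-width of the breakpoint window (default 50 residues).
#' @return A data frame of class `ptm_enrichment_table`: one row per residue
#'   class and scope with site and residue counts and the two ratios.
#' @export
enrichment_table <- function(sites, regions, protein, junction = NULL,
                             denominator = c("region", "class"),
                             flank = 50L) {
  denominator <- match.arg(denominator)
  s <- toupper(as.character(protein)[1])
  res <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(res)
  stopifnot(inherits(regions, "region_set"), regions$n_residues == n)
  if (nrow(sites) > 0L) {
    if (any(sites$position < 1L | sites$position > n)) {
      stop("PTM site position outside the protein")
    }
    mismatch <- res[sites$position] != sites$residue
    if (any(mismatch)) {
      stop("PTM site residue mismatch at position(s): ",
           paste(sites$position[mismatch], collapse = ", "))
    }
  }
  dis <- region_indicator(regions, n)
  # conservation: every residue is exactly one of disordered / structural
  stopifnot(sum(dis) + sum(!dis) == n)
  scopes <- list(protein = rep(TRUE, n))
  if (!is.null(junction)) {
    stopifnot(junction >= 1L, junction <= n)
    lo <- max(1L, junction - flank)
    hi <- min(n, junction + flank)
    scopes$breakpoint_window <- seq_len(n) >= lo & seq_len(n) <= hi
  }
  out <- list()
  for (scope_name in names(scopes)) {
    in_scope <- scopes[[scope_name]]
    for (cls in PTM_RESIDUES) {
      want_mod <- MOD_FOR_RESIDUE[[cls]]
      is_site <- logical(n)
      if (nrow(sites) > 0L) {
        sel <- sites$residue == cls & sites$modification == want_mod
        is_site[sites$position[sel]] <- TRUE
      }
      n_site_dis <- sum(is_site & dis & in_scope)
      n_site_str <- sum(is_site & !dis & in_scope)
      if (denominator == "region") {
        den_dis <- sum(dis & in_scope)
        den_str <- sum(!dis & in_scope)
      } else {
        den_dis <- sum(res == cls & dis & in_scope)
        den_str <- sum(res == cls & !dis & in_scope)
      }
      out[[length(out) + 1L]] <- data.frame(
        scope = scope_name, residue_class = cls, modification = want_mod,
        n_sites_disorder = n_site_dis, n_sites_structural = n_site_str,
        n_residues_disorder = den_dis, n_residues_structural = den_str,
        stringsAsFactors = FALSE
      )
    }
  }
  tbl <- do.call(rbind, out)
  tbl$ratio_disorder <- ifelse(tbl$n_residues_disorder > 0L,
                               tbl$n_sites_disorder / tbl$n_residues_disorder,
                               NA_real_)
  tbl$ratio_structural <- ifelse(tbl$n_residues_structural > 0L,
                                 tbl$n_sites_structural /
                                   tbl$n_residues_structural,
                                 NA_real_)
  attr(tbl, "denominator") <- denominator
  class(tbl) <- c("ptm_enrichment_table", "data.frame")
  tbl
}

#' Pool PTM enrichment tables across proteins
#'
#' Pooling sums numerators and denominators over proteins (never averages
#' per-protein ratios), then recomputes the ratios.
#'
#' @param tables List of `ptm_enrichment_table` objects built with the same
#'   denominator convention.
#' @return A pooled `ptm_enrichment_table`.
#' @export
pool_enrichment <- function(tables) {
  stopifnot(length(tables) >= 1L)
  denoms <- unique(vapply(tables, function(t) attr(t, "denominator"),
                          character(1)))
  if (length(denoms) != 1L) {
    stop("cannot pool tables with different denominator conventions")
  }
  all_rows <- do.call(rbind, lapply(tables, as.data.frame))
  agg <- stats::aggregate(
    all_rows[c("n_sites_disorder", "n_sites_structural",
               "n_residues_disorder", "n_residues_structural")],
    by = all_rows[c("scope", "residue_class", "modification")],
    FUN = sum
  )
  agg$ratio_disorder <- ifelse(agg$n_residues_disorder > 0L,
                               agg$n_sites_disorder / agg$n_residues_disorder,
                               NA_real_)
  agg$ratio_structural <- ifelse(agg$n_residues_structural > 0L,
                                 agg$n_sites_structural /
                                   agg$n_residues_structural,
                                 NA_real_)
  ord <- order(agg$scope, match(agg$residue_class, PTM_RESIDUES))
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "denominator") <- denoms
  class(agg) <- c("ptm_enrichment_table", "data.frame")
  agg
}

#' Test disordered vs structural PTM ratios per residue class
#'
#' Two-sided Fisher exact test on the 2x2 table of sites / non-sites by
#' disordered / structural for each row, BH-corrected over the rows tested.
#' Rows with a zero denominator on either side are flagged (`tested = FALSE`)
#' and excluded from testing and correction.
#'
#' @param table A (typically pooled) `ptm_enrichment_table`.
#' @return The table with `tested`, `odds_ratio`, `p_value`, `q_value`
#'   columns appended.
#' @export
compare_classes <- function(table) {
  tbl <- as.data.frame(table)
  tbl$tested <- tbl$n_residues_disorder > 0L & tbl$n_residues_structural > 0L
  tbl$odds_ratio <- NA_real_
  tbl$p_value <- NA_real_
  for (i in which(tbl$tested)) {
    m <- matrix(c(tbl$n_sites_disorder[i],
                  tbl$n_residues_disorder[i] - tbl$n_sites_disorder[i],
                  tbl$n_sites_structural[i],
                  tbl$n_residues_structural[i] - tbl$n_sites_structural[i]),
                nrow = 2L)
    ft <- stats::fisher.test(m, alternative = "two.sided")
    tbl$odds_ratio[i] <- unname(ft$estimate)
    tbl$p_value[i] <- ft$p.value
  }
  tbl$q_value <- NA_real_
  tbl$q_value[tbl$tested] <- stats::p.adjust(tbl$p_value[tbl$tested],
                                             method = "BH")
  attr(tbl, "denominator") <- attr(table, "denominator")
  class(tbl) <- c("ptm_enrichment_table", "data.frame")
  tbl
}
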