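stage_file <- function(dir, name) file.path(dir, name)

require_stage_output <- function(dir, name, stage) {
  path <- stage_file(dir, name)
  if (!file.exists(path)) {
    stop("missing '", name, "' in ", dir, "; run stage '", stage, "' first")
  }
  path
}

#' Simulate a synthetic fusion corpus into a directory
#'
#' Writes partner genes and their breakpoints, fusion proteins with their
#' breakpoints and ground-truth disordered tracts, and planted PTM sites, in
#' the same FASTA/TSV formats the readers ingest.
#'
#' @param cfg A `synthetic_config`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the list of generated objects.
#' @export
stage_simulate <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- gen_partner_genes(cfg)
  fus <- gen_fusion_proteins(cfg)
  sites <- gen_ptm_sites(fus$proteins, fus$truth, cfg)
  write_fasta(genes$sequences, stage_file(dir, "partner_genes.fasta"))
  write_table(genes$breakpoints, stage_file(dir, "partner_breakpoints.tsv"))
  write_fasta(fus$proteins, stage_file(dir, "fusion_proteins.fasta"))
  write_table(fus$breakpoints, stage_file(dir, "protein_breakpoints.tsv"))
  write_table(fus$truth, stage_file(dir, "truth_regions.tsv"))
  write_table(sites, stage_file(dir, "ptm_sites.tsv"))
  invisible(list(genes = genes, fusions = fus, sites = sites))
}

#' Junction spectra and enrichment for a simulated (or ingested) corpus
#'
#' Reads partner genes and breakpoints from `dir`, extracts the ten-position
#' junction windows, and writes the positional frequency table, the junction
#' dinucleotide enrichment against the partner-gene background, and the
#' pre-break trinucleotide spectrum.
#'
#' @param dir Directory holding `partner_genes.fasta` and
#'   `partner_breakpoints.tsv`.
#' @param background Optional sequence set for the background spectrum;
#'   defaults to the partner genes themselves.
#' @param k Half-window width.
#' @return Invisibly, a list of the computed tables.
#' @export
stage_spectra <- function(dir, background = NULL, k = 5L) {
  seqs <- read_fasta(require_stage_output(dir, "partner_genes.fasta",
                                          "simulate"), "nucleotide")
  bps <- read_breakpoints(require_stage_output(dir, "partner_breakpoints.tsv",
                                               "simulate"), seqs)
  if (is.null(background)) background <- seqs
  windows <- extract_windows(seqs, bps, k = k)
  pos <- positional_frequencies(windows)
  di <- junction_spectrum(windows, k = 2L)
  tri <- junction_spectrum(windows, k = 3L)
  bg2 <- background_spectrum(background, k = 2L)
  bg3 <- background_spectrum(background, k = 3L)
  enr2 <- enrichment_test(di, bg2)
  enr3 <- enrichment_test(tri, bg3)
  write_table(as.data.frame(pos), stage_file(dir, "positional_frequencies.tsv"))
  write_table(enr2, stage_file(dir, "dinucleotide_enrichment.tsv"))
  write_table(enr3, stage_file(dir, "trinucleotide_enrichment.tsv"))
  invisible(list(positional = pos, dinucleotide = enr2, trinucleotide = enr3))
}

#' Build and translate demonstration fusions from consecutive partner pairs
#'
#' Pairs partner genes (1,2), (3,4), ... using each partner's first
#' breakpoint as `bp_a` / `bp_b`, builds the fused nucleotide sequence,
#' translates in frame 0, and maps each junction to its protein residue.
#'
#' @param dir Directory holding the simulate-stage outputs.
#' @return Invisibly, the fusion constructs table.
#' @export
stage_fusions <- function(dir) {
  seqs <- read_fasta(require_stage_output(dir, "partner_genes.fasta",
                                          "simulate"), "nucleotide")
  bps <- read_breakpoints(require_stage_output(dir, "partner_breakpoints.tsv",
                                               "simulate"), seqs)
  first_bp <- bps[!duplicated(bps$sequence_id), ]
  ids <- names(seqs)
  n_pairs <- length(ids) %/% 2L
  rows <- vector("list", n_pairs)
  fused <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    a_id <- ids[2L * i - 1L]
    b_id <- ids[2L * i]
    fc <- build_fusion(seqs[[a_id]],
                       first_bp$offset[first_bp$sequence_id == a_id],
                       seqs[[b_id]],
                       first_bp$offset[first_bp$sequence_id == b_id],
                       a_id = a_id, b_id = b_id)
    fc <- translate_fusion(fc)
    fused[i] <- fc$fused_nt
    rows[[i]] <- data.frame(
      fusion_id = sprintf("fused%05d", i),
      partner_a_id = a_id, partner_b_id = b_id,
      bp_a = fc$bp_a, bp_b = fc$bp_b,
      fused_length = nchar(fc$fused_nt),
      protein_length = nchar(fc$protein),
      junction_residue = fc$junction_residue,
      junction_in_codon = fc$junction_in_codon,
      stringsAsFactors = FALSE
    )
  }
  tbl <- do.call(rbind, rows)
  write_table(tbl, stage_file(dir, "fusion_constructs.tsv"))
  write_fasta(setNames(fused, tbl$fusion_id),
              stage_file(dir, "fused_genes.fasta"))
  invisible(tbl)
}

#' Disorder calling and multi-predictor consensus
#'
#' Scores every fusion protein with the bundled hydropathy/charge scorer at
#' each window size in `scorer_windows` (three window variants act as
#' distinct predictors for the consensus demonstration), plus any external
#' score tracks supplied, calls regions at the 0.5 threshold, classifies each
#' breakpoint residue, and writes per-predictor calls, called regions, the
#' Venn/at-least-k consensus and per-predictor disorder fractions.
#'
#' @param dir Directory holding the simulate-stage outputs.
#' @param scorer_windows Window sizes of the bundled-scorer predictor
#'   variants.
#' @param tracks Optional external score-track data frame
#'   (see [read_score_track()]).
#' @param min_region_length Minimum disordered-region length.
#' @param min_aa Proteins of length `<= min_aa` are flagged and excluded
#'   from the consensus (set to 0 to keep all).
#' @return Invisibly, a list with the calls matrix and consensus summary.
#' @export
stage_disorder <- function(dir, scorer_windows = c(15L, 21L, 27L),
                           tracks = NULL, min_region_length = 1L,
                           min_aa = 100L) {
  prot <- read_fasta(require_stage_output(dir, "fusion_proteins.fasta",
                                          "simulate"), "protein")
  bps <- read_breakpoints(require_stage_output(dir, "protein_breakpoints.tsv",
                                               "simulate"), prot)
  keep <- flag_long_proteins(prot, min_aa)
  bps <- bps[keep[bps$sequence_id], , drop = FALSE]
  profiles <- list()
  for (w in scorer_windows) {
    for (id in names(prot)) {
      if (!keep[[id]]) next
      profiles[[length(profiles) + 1L]] <-
        bundled_disorder_score(prot[[id]], window = w, sequence_id = id)
    }
  }
  if (!is.null(tracks)) {
    for (key in unique(paste(tracks$sequence_id, tracks$predictor,
                             sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      profiles[[length(profiles) + 1L]] <-
        disorder_profile(parts[1],
                         track_scores(tracks, parts[1], parts[2]),
                         predictor = parts[2])
    }
  }
  region_rows <- list()
  call_rows <- list()
  for (p in profiles) {
    rs <- call_regions(p, min_length = min_region_length)
    if (nrow(rs$disordered) > 0L) {
      region_rows[[length(region_rows) + 1L]] <-
        data.frame(sequence_id = p$sequence_id, predictor = p$predictor,
                   rs$disordered, stringsAsFactors = FALSE)
    }
    sel <- bps$sequence_id == p$sequence_id
    if (any(sel)) {
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        sequence_id = p$sequence_id, predictor = p$predictor,
        offset = bps$offset[sel],
        in_disorder = vapply(bps$offset[sel],
                             function(j) breakpoint_in_disorder(rs, j),
                             logical(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  regions_tbl <- do.call(rbind, region_rows)
  calls_tbl <- do.call(rbind, call_rows)
  preds <- unique(calls_tbl$predictor)
  key <- paste(calls_tbl$sequence_id, calls_tbl$offset)
  bpkeys <- unique(key)
  calls <- matrix(NA, nrow = length(bpkeys), ncol = length(preds),
                  dimnames = list(bpkeys, preds))
  calls[cbind(match(key, bpkeys), match(calls_tbl$predictor, preds))] <-
    calls_tbl$in_disorder
  cons <- consensus(calls)
  fractions <- data.frame(
    predictor = preds,
    n = nrow(calls),
    disorder_fraction = vapply(preds, function(p)
      disorder_fraction(calls[, p]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  write_table(regions_tbl, stage_file(dir, "disorder_regions.tsv"))
  write_table(calls_tbl, stage_file(dir, "disorder_calls.tsv"))
  write_table(data.frame(subset = names(cons$venn_counts),
                         count = as.integer(cons$venn_counts)),
              stage_file(dir, "consensus_venn.tsv"))
  write_table(data.frame(k = seq_along(cons$at_least_k),
                         count = as.integer(cons$at_least_k)),
              stage_file(dir, "consensus_at_least_k.tsv"))
  write_table(fractions, stage_file(dir, "disorder_fractions.tsv"))
  invisible(list(calls = calls, consensus = cons, fractions = fractions,
                 regions = regions_tbl))
}

#' PTM enrichment over called disorder regions
#'
#' Classifies every protein residue as disordered or structured using the
#' bundled scorer at `window` (or an external predictor's track from the
#' disorder stage), then pools sites-per-residue counts across proteins into
#' the occurrence-ratio table — overall and in the breakpoint window — and
#' Fisher-tests disordered vs structured per residue class.
#'
#' @param dir Directory holding simulate-stage outputs.
#' @param window Bundled-scorer window used for region calling.
#' @param denominator Ratio denominator convention (see [enrichment_table()]).
#' @param flank Breakpoint-window half-width (residues).
#' @return Invisibly, the tested pooled table.
#' @export
stage_ptm <- function(dir, window = 21L, denominator = "region",
                      flank = 50L) {
  prot <- read_fasta(require_stage_output(dir, "fusion_proteins.fasta",
                                          "simulate"), "protein")
  bps <- read_breakpoints(require_stage_output(dir, "protein_breakpoints.tsv",
                                               "simulate"), prot)
  sites <- read_ptm_sites(require_stage_output(dir, "ptm_sites.tsv",
                                               "simulate"), prot)
  tables <- list()
  for (id in names(prot)) {
    profile <- bundled_disorder_score(prot[[id]], window = window,
                                      sequence_id = id)
    regions <- call_regions(profile)
    junction <- bps$offset[bps$sequence_id == id][1]
    tables[[id]] <- enrichment_table(
      sites[sites$sequence_id == id, , drop = FALSE],
      regions, prot[[id]], junction = junction,
      denominator = denominator, flank = flank
    )
  }
  pooled <- compare_classes(pool_enrichment(tables))
  write_table(pooled, stage_file(dir, "ptm_enrichment.tsv"))
  invisible(pooled)
}

#' Collate stage outputs into one summary table
#'
#' Gathers the dinucleotide/trinucleotide enrichment, consensus counts,
#' disorder fractions and PTM ratios written by the upstream stages into a
#' single long-format `summary.tsv` (section, key, value), and writes a
#' `manifest.tsv` recording the parameters of the run.
#'
#' @param dir Directory holding the upstream stage outputs.
#' @param cfg The `synthetic_config` used (recorded in the manifest).
#' @return Invisibly, the summary data frame.
#' @export
stage_report <- function(dir, cfg = NULL) {
  di <- read_result_table(require_stage_output(dir,
                                               "dinucleotide_enrichment.tsv",
                                               "spectra"))
  venn <- read_result_table(require_stage_output(dir, "consensus_venn.tsv",
                                                 "disorder"))
  alk <- read_result_table(require_stage_output(dir,
                                                "consensus_at_least_k.tsv",
                                                "disorder"))
  fr <- read_result_table(require_stage_output(dir, "disorder_fractions.tsv",
                                               "disorder"))
  ptm <- read_result_table(require_stage_output(dir, "ptm_enrichment.tsv",
                                                "ptm"))
  num <- function(x) formatC(x, digits = 10, format = "g")
  rows <- rbind(
    data.frame(section = "dinucleotide", key = di$kmer,
               value = num(di$observed_freq)),
    data.frame(section = "dinucleotide_q", key = di$kmer,
               value = num(di$q_value)),
    data.frame(section = "consensus_venn", key = venn$subset,
               value = as.character(venn$count)),
    data.frame(section = "consensus_at_least_k", key = as.character(alk$k),
               value = as.character(alk$count)),
    data.frame(section = "disorder_fraction", key = fr$predictor,
               value = num(fr$disorder_fraction)),
    data.frame(section = "ptm_ratio_disorder",
               key = paste(ptm$scope, ptm$residue_class, sep = ":"),
               value = num(ptm$ratio_disorder)),
    data.frame(section = "ptm_ratio_structural",
               key = paste(ptm$scope, ptm$residue_class, sep = ":"),
               value = num(ptm$ratio_structural))
  )
  write_table(rows, stage_file(dir, "summary.tsv"))
  if (!is.null(cfg)) {
    flat <- unlist(cfg)
    write_table(data.frame(parameter = c(names(flat), "fusionscan_version"),
                           value = c(as.character(flat),
                                     as.character(utils::packageVersion(
                                       "fusionscan")))),
                stage_file(dir, "manifest.tsv"))
  }
  invisible(rows)
}

#' Run the whole pipeline on a synthetic corpus
#'
#' Chains simulate, spectra, fusions, disorder, ptm and report. All stages
#' communicate only through files in `dir`, so externally produced predictor
#' tracks or PTM tables can replace the bundled stand-ins at the same seams.
#' Identical config and inputs produce byte-identical outputs.
#'
#' @param cfg A `synthetic_config`.
#' @param dir Output directory.
#' @param scorer_windows Bundled-scorer window variants for the consensus.
#' @return Invisibly, the summary table from [stage_report()].
#' @export
run_pipeline <- function(cfg = synthetic_config(), dir,
                         scorer_windows = c(15L, 21L, 27L)) {
  stage_simulate(cfg, dir)
  stage_spectra(dir)
  stage_fusions(dir)
  stage_disorder(dir, scorer_windows = scorer_windows)
  stage_ptm(dir)
  stage_report(dir, cfg)
}

#' Read a flat key=value generator config file
#'
#' Lines of the form `key=value`; `#` comments and blank lines ignored.
#' Vector-valued parameters use comma-separated `name:value` pairs, e.g.
#' `junction_dinucleotide_bias=GG:0.3,GA:0.1`, and plain comma-separated
#' numbers for ranges, e.g. `disorder_tract_length=40,80`.
#'
#' @param path Path to the config file.
#' @return A `synthetic_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      stop("malformed config line: ", ln)
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (grepl(":", val, fixed = TRUE)) {
      pairs <- strsplit(strsplit(val, ",", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      args[[key]] <- setNames(vapply(pairs, function(p) as.numeric(p[2]),
                                     numeric(1)),
                              vapply(pairs, `[`, character(1), 1L))
    } else if (grepl(",", val, fixed = TRUE)) {
      args[[key]] <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    } else {
      args[[key]] <- as.numeric(val)
    }
  }
  do.call(synthetic_config, args)
}
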