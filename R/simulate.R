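# residue sampling weights for synthetic protein tracts. Ordered tracts are
# dominated by hydrophobics so the hydropathy/charge scorer reads them as
# folded; a small polar/charged admixture keeps every PTM-eligible residue
# class (S/T/Y/R/K) present in structured regions. Disordered tracts are
# polar/charged with a trace of T and Y for the same reason.
ORDERED_RESIDUE_PROBS <- c(
  I = 0.13, L = 0.13, V = 0.13, F = 0.12, A = 0.12, M = 0.11, W = 0.10,
  S = 0.05, T = 0.04, Y = 0.03, R = 0.02, K = 0.02
)
DISORDERED_RESIDUE_PROBS <- c(
  E = 0.14, K = 0.13, S = 0.13, R = 0.12, P = 0.12, Q = 0.11, G = 0.11,
  D = 0.10, T = 0.02, Y = 0.02
)

#' Configuration for the synthetic fusion-event generator
#'
#' The generator plants known signal at every pipeline stage: junction
#' dinucleotide bias at (P-1, P+1) and pre-break trinucleotide bias at
#' (P-3, P-2, P-1) in partner genes; sandwich ordered-disordered-ordered
#' fusion proteins whose breakpoint residue falls inside the disordered tract
#' with probability `p_breakpoint_in_disorder`; and PTM sites planted on
#' eligible residues at class- and region-specific densities. The seed fully
#' determines every output.
#'
#' Bias maps give, per k-mer, the probability that that k-mer is planted
#' (overwriting the i.i.d. background) at its junction positions; the maps
#' must sum to at most 1 and the remainder is left to the base composition.
#' When both a trinucleotide and a dinucleotide plant fire on the same
#' breakpoint the trinucleotide is written first, so the dinucleotide wins
#' at P-1.
#'
#' @param seed Integer seed.
#' @param n_partners Number of partner genes.
#' @param breakpoints_per_gene Breakpoints per partner gene.
#' @param gene_length Partner gene length (nt).
#' @param base_composition Named probabilities for A, C, G, T.
#' @param junction_dinucleotide_bias Named plant probabilities for 2-mers at
#'   (P-1, P+1).
#' @param pre_break_trinucleotide_bias Named plant probabilities for 3-mers
#'   at (P-3, P-2, P-1).
#' @param n_fusions Number of synthetic fusion proteins.
#' @param ordered_tract_length Length range (min, max) of each ordered tract.
#' @param disorder_tract_length Length range of the disordered tract.
#' @param p_breakpoint_in_disorder Probability the junction residue is placed
#'   inside the disordered tract.
#' @param ptm_density_disorder,ptm_density_structural Named per-class
#'   (S, T, Y, R, K) probabilities that an eligible residue is a site, in
#'   disordered / structured regions.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_partners = 200L,
    breakpoints_per_gene = 2L,
    gene_length = 500L,
    base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    junction_dinucleotide_bias = c(GG = 0.3),
    pre_break_trinucleotide_bias = c(AAG = 0.1, CAG = 0.05,
                                     GAG = 0.1, TAG = 0.05),
    n_fusions = 200L,
    ordered_tract_length = c(60L, 120L),
    disorder_tract_length = c(40L, 80L),
    p_breakpoint_in_disorder = 0.68,
    ptm_density_disorder = c(S = 0.08, T = 0.024, Y = 0.011,
                             R = 0.009, K = 0.007),
    ptm_density_structural = c(S = 0.03, T = 0.011, Y = 0.012,
                               R = 0.003, K = 0.004)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  stopifnot(n_partners >= 1L, breakpoints_per_gene >= 1L, gene_length >= 1L,
            n_fusions >= 1L)
  stopifnot(setequal(names(base_composition), c("A", "C", "G", "T")),
            abs(sum(base_composition) - 1) < 1e-9,
            all(base_composition >= 0))
  check_bias <- function(bias, k, label) {
    if (length(bias) == 0L) return(invisible(TRUE))
    stopifnot(all(bias >= 0), sum(bias) <= 1 + 1e-12)
    bad <- names(bias)[!names(bias) %in% all_kmers(k)]
    if (length(bad) > 0L) {
      stop(label, " bias has invalid ", k, "-mer(s): ",
           paste(bad, collapse = ", "))
    }
    invisible(TRUE)
  }
  check_bias(junction_dinucleotide_bias, 2L, "dinucleotide")
  check_bias(pre_break_trinucleotide_bias, 3L, "trinucleotide")
  check_range <- function(r) {
    stopifnot(length(r) == 2L, r[1] >= 1L, r[1] <= r[2])
  }
  check_range(ordered_tract_length)
  check_range(disorder_tract_length)
  stopifnot(p_breakpoint_in_disorder >= 0, p_breakpoint_in_disorder <= 1)
  check_density <- function(d) {
    stopifnot(all(names(d) %in% PTM_RESIDUES), all(d >= 0), all(d <= 1))
  }
  check_density(ptm_density_disorder)
  check_density(ptm_density_structural)
  structure(
    list(seed = as.integer(seed), n_partners = as.integer(n_partners),
         breakpoints_per_gene = as.integer(breakpoints_per_gene),
         gene_length = as.integer(gene_length),
         base_composition = base_composition[c("A", "C", "G", "T")],
         junction_dinucleotide_bias = junction_dinucleotide_bias,
         pre_break_trinucleotide_bias = pre_break_trinucleotide_bias,
         n_fusions = as.integer(n_fusions),
         ordered_tract_length = as.integer(ordered_tract_length),
         disorder_tract_length = as.integer(disorder_tract_length),
         p_breakpoint_in_disorder = p_breakpoint_in_disorder,
         ptm_density_disorder = ptm_density_disorder,
         ptm_density_structural = ptm_density_structural),
    class = "synthetic_config"
  )
}

#' Generate partner genes with planted junction motifs
#'
#' Sequences are i.i.d. draws from the base composition. Breakpoint offsets
#' are placed one per equal-length block of the gene, uniformly within the
#' block at least `k = 5` positions from its edges, which keeps every window
#' extractable and consecutive plants non-overlapping. For each breakpoint,
#' with the configured probabilities a trinucleotide is planted at
#' (P-3, P-2, P-1) and then a dinucleotide at (P-1, P+1).
#'
#' @param cfg A `synthetic_config`.
#' @return List with `sequences` (a `DNAStringSet`) and `breakpoints`
#'   (a breakpoint data frame).
#' @export
gen_partner_genes <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  k <- 5L
  n <- cfg$n_partners
  L <- cfg$gene_length
  m <- cfg$breakpoints_per_gene
  block <- L %/% m
  if (block < 2L * k) {
    stop("gene_length too short for ", m, " breakpoints with k = ", k,
         " flanks (need length >= ", m * 2L * k, ")")
  }
  nts <- c("A", "C", "G", "T")
  mat <- matrix(sample(nts, n * L, replace = TRUE,
                       prob = cfg$base_composition),
                nrow = n, ncol = L)
  offmat <- matrix(0L, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    lo <- (j - 1L) * block + k
    hi <- j * block - k
    offmat[, j] <- sample(lo:hi, n, replace = TRUE)
  }
  rows <- rep(seq_len(n), times = m)
  offs <- as.integer(offmat)
  nb <- length(offs)
  tri_bias <- cfg$pre_break_trinucleotide_bias
  if (length(tri_bias) > 0L && sum(tri_bias) > 0) {
    fire <- runif(nb) < sum(tri_bias)
    if (any(fire)) {
      kmer <- sample(names(tri_bias), sum(fire), replace = TRUE,
                     prob = tri_bias / sum(tri_bias))
      for (d in 0:2) {
        mat[cbind(rows[fire], offs[fire] - 2L + d)] <-
          substr(kmer, d + 1L, d + 1L)
      }
    }
  }
  di_bias <- cfg$junction_dinucleotide_bias
  if (length(di_bias) > 0L && sum(di_bias) > 0) {
    fire <- runif(nb) < sum(di_bias)
    if (any(fire)) {
      kmer <- sample(names(di_bias), sum(fire), replace = TRUE,
                     prob = di_bias / sum(di_bias))
      mat[cbind(rows[fire], offs[fire])] <- substr(kmer, 1L, 1L)
      mat[cbind(rows[fire], offs[fire] + 1L)] <- substr(kmer, 2L, 2L)
    }
  }
  ids <- sprintf("gene%05d", seq_len(n))
  seqs <- Biostrings::DNAStringSet(
    setNames(apply(mat, 1L, paste, collapse = ""), ids)
  )
  bps <- data.frame(
    sequence_id = ids[rows], offset = offs, role = "partner",
    molecule = "nucleotide", stringsAsFactors = FALSE
  )
  bps <- bps[order(bps$sequence_id, bps$offset), , drop = FALSE]
  rownames(bps) <- NULL
  list(sequences = seqs, breakpoints = bps)
}

sample_tract <- function(total, probs) {
  sample(names(probs), total, replace = TRUE, prob = probs)
}

#' Generate sandwich fusion proteins with known disordered tracts
#'
#' Each protein is ordered-disordered-ordered: ordered tracts drawn from a
#' hydrophobic-dominated residue distribution, the disordered tract from a
#' polar/charged one (see the package constants), with tract lengths uniform
#' in the configured ranges. With probability `p_breakpoint_in_disorder` the
#' junction residue is placed uniformly inside the disordered tract,
#' otherwise uniformly in the ordered tracts (proportionally to their
#' lengths). Ground-truth disordered boundaries are emitted alongside.
#'
#' @param cfg A `synthetic_config`.
#' @return List with `proteins` (`AAStringSet`), `breakpoints` (breakpoint
#'   data frame with a ground-truth `in_disorder` column), and `truth`
#'   (data frame `sequence_id`, `start`, `end`, `n_residues` of the planted
#'   disordered tract).
#' @export
gen_fusion_proteins <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  if (cfg$disorder_tract_length[1] < 21L) {
    warning("disordered tracts shorter than the bundled scorer window (21); ",
            "region calls will be unreliable")
  }
  n <- cfg$n_fusions
  runi <- function(r) sample(r[1]:r[2], n, replace = TRUE)
  o1 <- runi(cfg$ordered_tract_length)
  d <- runi(cfg$disorder_tract_length)
  o2 <- runi(cfg$ordered_tract_length)
  L <- o1 + d + o2
  ids <- sprintf("fusion%05d", seq_len(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- paste(c(sample_tract(o1[i], ORDERED_RESIDUE_PROBS),
                       sample_tract(d[i], DISORDERED_RESIDUE_PROBS),
                       sample_tract(o2[i], ORDERED_RESIDUE_PROBS)),
                     collapse = "")
  }
  in_dis <- runif(n) < cfg$p_breakpoint_in_disorder
  junction <- integer(n)
  for (i in seq_len(n)) {
    if (in_dis[i]) {
      junction[i] <- o1[i] + sample.int(d[i], 1L)
    } else {
      # ordered placement, proportional to tract lengths; keep offset < L
      n_ord <- o1[i] + o2[i] - 1L
      u <- sample.int(n_ord, 1L)
      junction[i] <- if (u <= o1[i]) u else o1[i] + d[i] + (u - o1[i])
    }
  }
  list(
    proteins = Biostrings::AAStringSet(setNames(seqs, ids)),
    breakpoints = data.frame(sequence_id = ids, offset = junction,
                             role = "fusion", molecule = "protein",
                             in_disorder = in_dis,
                             stringsAsFactors = FALSE),
    truth = data.frame(sequence_id = ids, start = o1 + 1L, end = o1 + d,
                       n_residues = L, stringsAsFactors = FALSE)
  )
}

#' Ground-truth region set for one synthetic protein
#'
#' @param truth Truth data frame from [gen_fusion_proteins()].
#' @param sequence_id Protein id.
#' @return A `region_set` holding the planted disordered tract.
#' @export
truth_region_set <- function(truth, sequence_id) {
  row <- truth[truth$sequence_id == sequence_id, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  structure(
    list(sequence_id = sequence_id, n_residues = row$n_residues,
         disordered = data.frame(start = row$start, end = row$end)),
    class = "region_set"
  )
}

#' Plant PTM sites at region-specific densities
#'
#' Every eligible residue (S/T/Y for phosphorylation, R/K for methylation)
#' independently becomes a site with the class- and region-specific density
#' from the config, using the ground-truth disordered tracts for the region
#' assignment.
#'
#' @param proteins `AAStringSet` from [gen_fusion_proteins()].
#' @param truth Matching truth data frame.
#' @param cfg A `synthetic_config`.
#' @return A PTM-site data frame.
#' @export
gen_ptm_sites <- function(proteins, truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 2L)
  dens_dis <- setNames(rep(0, length(PTM_RESIDUES)), PTM_RESIDUES)
  dens_str <- dens_dis
  dens_dis[names(cfg$ptm_density_disorder)] <- cfg$ptm_density_disorder
  dens_str[names(cfg$ptm_density_structural)] <- cfg$ptm_density_structural
  out <- list()
  chars <- as.character(proteins)
  for (id in names(chars)) {
    res <- strsplit(chars[[id]], "", fixed = TRUE)[[1]]
    n <- length(res)
    regions <- truth_region_set(truth, id)
    dis <- region_indicator(regions, n)
    eligible <- res %in% PTM_RESIDUES
    p <- numeric(n)
    p[eligible] <- ifelse(dis[eligible],
                          dens_dis[res[eligible]],
                          dens_str[res[eligible]])
    hit <- runif(n) < p
    if (any(hit)) {
      out[[id]] <- data.frame(
        sequence_id = id, position = which(hit), residue = res[hit],
        modification = unname(MOD_FOR_RESIDUE[res[hit]]), score = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sequence_id = character(0), position = integer(0),
                      residue = character(0), modification = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
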