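---
title: "Methods: breakpoint sequence, disorder and PTM analysis in fusionscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breakpoint sequence, disorder and PTM analysis in fusionscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionscan)
```

## The problem

A fusion gene joins a 5′ prefix of partner gene A (the first `bp_a`
nucleotides) to a 3′ suffix of partner gene B (everything after `bp_b`).
Three questions about such events are addressed here: whether breakpoints
fall in biased sequence contexts; whether the breakpoint residue of the
translated fusion protein tends to lie in intrinsically disordered regions;
and whether phosphorylation and methylation sites concentrate in those
disordered regions. This vignette records the models, parameter choices and
numerical conventions the package uses, and what its synthetic-data tests
do and do not demonstrate.

## Coordinates and junction windows

All file formats are 1-based and inclusive. A breakpoint `offset` counts the
residues retained before the junction, so the junction lies between `offset`
and `offset + 1` and there is no "position 0": the flanking positions are
labelled P−5…P−1, P+1…P+5. The junction dinucleotide is
(`seq[offset]`, `seq[offset + 1]`), i.e. (P−1, P+1), and the pre-break
trinucleotide occupies (P−3, P−2, P−1).

Windows that would overlap a sequence end are skipped, never padded: padding
would contaminate positional frequencies with an arbitrary fill symbol.
Windows containing `N` are likewise excluded from all spectra, which keeps
every distribution over the 4-letter alphabet and makes each positional
column and each spectrum sum to exactly 1 (asserted to 1e−9 in the tests).
Sequences are assumed to be supplied in coding/transcript orientation; the
package never reverse-complements silently, because doing so on
database-derived mixed input is a classic source of sign errors.

## Junction spectra and enrichment

Positional frequencies are exact count ratios. The junction dinucleotide and
pre-break trinucleotide spectra are exact counts over the 4^k k-mers divided
by the number of usable windows. The background is whatever sequence set the
caller supplies — in practice a large corpus standing in for "all genes";
the statistic is background-relative by design and the package ships no
reference genome. Background counting uses all overlapping k-mers at step 1.

No specific test is canonical for junction k-mer enrichment, so the package
supplies one with conservative, reproducible behavior: per k-mer, a
two-sided exact binomial test of the junction count (out of n windows)
against the background frequency, with Benjamini–Hochberg correction across
the 4^k tests. A pseudocount of 1 is added to every background k-mer count
so background frequencies are strictly positive and observed/background
ratios are always defined. Exactness matters because junction counts are
small (hundreds, not millions); BH is used rather than Bonferroni because
the 16 (or 64) tests are positively dependent through the shared n.
Under the null the procedure is calibrated: sampling junction counts from
the post-pseudocount background distribution, fewer than 7% of k-mers are
called at q < 0.05 over 500 replicates (measured ≈ 0.2–0.3%).

## Fusion construction and codon mapping

`build_fusion` concatenates exactly; no bases are lost or invented, so
`length(fused) = bp_a + length(b) − bp_b` always. Translation uses the
standard genetic code from a caller-chosen frame offset (default 0, i.e.
CDS-trimmed input; frame detection is out of scope), drops a partial
trailing codon, and by default truncates at the first stop codon — the
biologically produced product of an out-of-frame fusion — with a
`keep_through` policy retained for QC of premature stops.

With `d = bp_a − frame_offset` coding nucleotides from partner A, the
junction residue is `d/3` when `d` is a multiple of 3 (`aligned`), else
`ceil(d/3)` (`split`): the chimeric codon's residue is the one reported,
because it is the biologically ambiguous one, and the flag preserves the
distinction instead of silently rounding. The invariant `3r − 2 ≤ d ≤ 3r` is
verified exhaustively for d = 1…300. A 1059-residue construct with its
junction after codon 496 — the geometry of the EML4-ALK variant 1 fusion —
is reproduced in the test suite on synthetic sequences.

## Disorder scoring, regions and consensus

External per-residue disorder predictors are **ingested, never executed**:
any predictor that can emit one score per residue in [0, 1] drops in as a
TSV score track. For offline, deterministic operation the package bundles a
hydropathy/charge scorer built on the classical mean-hydrophobicity /
mean-net-charge unfoldability index: over a sliding window (default 21
residues, odd so the window centers; truncated to the available residues at
the ends),

u = 2.785·⟨H⟩ − |⟨q⟩| − 1.151,

with ⟨H⟩ the mean Kyte–Doolittle hydropathy rescaled to [0, 1] by
(h + 4.5)/9 and ⟨q⟩ the mean net charge (K, R = +1; D, E = −1; else 0;
X is treated as neutral with hydropathy 0). The disorder score is
`clip(0.5 − u/2, 0, 1)`, a linear map chosen so that the folded/unfolded
boundary u = 0 lands exactly on the conventional 0.5 disorder threshold —
the same threshold semantics external predictors use, so ingested tracks
and the bundled scorer are interchangeable downstream. Closed-form anchor
points: poly-glutamate scores exactly 1, poly-isoleucine exactly 0 (both
asserted to 1e−9).

Disordered regions are maximal runs of residues with score **strictly
greater than** 0.5; a residue at exactly 0.5 is ordered. This tie-break
follows the convention that a disordered residue must exceed the threshold;
with continuous scores the choice is immaterial, but binarized tracks
(0/1 indicators) make it observable, and strict inequality keeps 0/1 tracks
meaning what they say. `min_length` defaults to 1 (no published minimum
exists); it is configurable for users who want to suppress single-residue
blips.

Multi-predictor consensus partitions breakpoints over the 2^k subsets of
predictors calling them disordered; at-least-k counts are derived from the
partition and checked monotone on every run. The pipeline's demonstration
consensus uses three window-size variants (15/21/27) of the bundled scorer
as pseudo-predictors; real analyses should substitute three genuinely
different external predictors through the score-track seam. Proteins of
100 residues or fewer are flagged and excluded from the consensus by
default (short chains make disorder prediction unreliable), but never
silently dropped from the data.

## PTM enrichment

The occurrence ratio of a residue class (phospho-S/T/Y, methyl-R/K) in a
region class is sites per residue of the region (`denominator = "region"`,
the default, which makes disordered and structured rows directly
comparable) or per residue of that amino-acid class in the region
(`denominator = "class"`, the convention under which planted per-residue
densities are recovered exactly). Both are implemented because the
field's tables rarely state which denominator they use; the package makes
the choice explicit. Ratios with zero denominators are reported `NA`,
flagged, and excluded from testing rather than coerced to 0.

Pooling across proteins sums numerators and denominators — never averages
per-protein ratios, which would weight a 50-residue peptide equally with a
1000-residue kinase. Per residue class, disordered vs structured is tested
with a two-sided Fisher exact test on the sites / non-sites × region 2×2
table, BH-corrected over the rows tested. The breakpoint-window analysis
restricts the same computation to residues within ±50 of the junction,
clipped at the sequence ends (clipping retains data; an edge rule that
discards clipped windows would bias against short proteins).

A naive motif predictor (proline-directed and basophilic S/T, acidic-context
Y, RG/GR methyl-R, KK methyl-K) is bundled only so the pipeline can run
offline end to end; its rules are deliberately simple and deterministic and
are not a substitute for real site predictors.

## The synthetic generator

The generator emulates the statistical structure the analyses target, with
full determinism under a seed (each sub-generator derives its stream from
`seed`, `seed + 1`, `seed + 2`):

* **Partner genes**: i.i.d. nucleotides (default uniform), default length
  500 nt with 2 breakpoints per gene placed uniformly within equal blocks,
  at least 5 positions from block edges so every ±5 window exists and
  consecutive plants cannot collide. With probability 0.3 a trinucleotide
  ending in AG is planted at (P−3, P−2, P−1), and with probability 0.3 `GG`
  is planted at (P−1, P+1) — defaults that echo, in direction, the AG/GG
  junction preferences reported for real fusion breakpoints. The
  trinucleotide is written first, so on the rare double plant the
  dinucleotide wins at P−1. With only the GG channel active the expected
  junction GG frequency has the closed form 0.3 + 0.7/16, which the
  parameter-recovery tests use; with both channels active the interaction
  raises it (≈ 0.38) and no closed form is asserted.
* **Fusion proteins**: ordered–disordered–ordered sandwiches. Ordered
  tracts (default 60–120 residues) sample a hydrophobic-dominated
  distribution, disordered tracts (default 40–80) a polar/charged one.
  Each distribution carries a small admixture of the other character's
  residues — in particular S/T/Y/R/K at ~16% total in ordered tracts —
  so that every PTM-eligible class occurs in both region types and
  region-specific densities are measurable on both sides; the admixture is
  small enough that the scorer's expected index u stays above +0.7 in
  ordered and below −0.6 in disordered tracts, a separation of several
  window-level standard deviations. The breakpoint residue is placed inside
  the disordered tract with probability 0.68 (the planted
  breakpoint-in-disorder rate), else uniformly in the ordered tracts.
* **PTM sites**: every eligible residue becomes a site independently with a
  class- and region-specific density; serine defaults 0.08 (disordered) vs
  0.03 (structured), the other classes follow the same disordered-enriched
  direction at lower densities.

What passing these tests shows: counting, mapping, region calling,
classification, pooling and testing are correct, calibrated, and recover
planted parameters through the full pipeline. What they do not show: real
genomes are not i.i.d. (repeats, GC structure, exon boundaries), real
disorder is not a single clean tract with a composition switch, and real
PTM deposition is motif- and context-dependent — so quantitative results on
real data depend on the ingested predictors and backgrounds, not on these
defaults.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 2000 breakpoints for motif
recovery; 500 null replicates of 500 junctions for test calibration; 100
proteins for region-recovery (mean Jaccard ≈ 0.93 against planted tracts,
asserted ≥ 0.8 — the gap to 1 is boundary smoothing of the 21-residue
window, ~2 residues per tract edge); 500 proteins for
breakpoint-in-disorder recovery (the scorer's boundary erosion biases the
recovered fraction slightly below the planted 0.68, within the asserted 3
standard errors); and 200 proteins (plus 200 equal-density null replicates)
for PTM recovery and Fisher calibration. These sizes give each recovery
check a 3-standard-error margin while keeping a full run in tens of
seconds. Two pipeline runs with the same config are byte-identical; the
report stage writes no timestamps for that reason.

## Known limitations

* The bundled scorer is a composition index: it cannot see context beyond
  its window, and proteins mixing charge and hydrophobicity finely (e.g.
  coiled coils) can score near 0.5 either way. Use real predictor tracks
  for biological conclusions.
* Breakpoint offsets are sequence-relative; genomic-to-transcript liftover,
  strand handling, introns and splice isoforms are the caller's
  responsibility upstream.
* The enrichment test treats windows as independent draws; overlapping
  breakpoints on one gene mildly violate this, which is one more reason the
  package reports q-values rather than claiming calibrated family-wise
  error on real data.
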