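# fusionscan

Sequence, structure and post-translational-modification (PTM)
characterization of tumor fusion-gene breakpoints, as an R package.

Chromosomal translocations fuse two partner genes into a chimeric gene whose
protein product is a recurrent driver of blood and solid tumors (the
EML4-ALK fusion of non-small-cell lung cancer is the textbook case).
`fusionscan` is for researchers who have breakpoint-annotated sequences —
from fusion databases, RNA-seq fusion callers, or simulation — and want to
quantify three layers of signal around the junction:

1. **Sequence preference at the breakpoint.** For a breakpoint after
   position *P*, the ten flanking positions *P−5 … P−1, P+1 … P+5* (no
   position 0) are extracted. The package computes per-position nucleotide
   frequencies, the junction dinucleotide spectrum at (*P−1*, *P+1*) and the
   pre-break trinucleotide spectrum at (*P−3*, *P−2*, *P−1*), and tests each
   k-mer's junction frequency against a background sequence set with a
   two-sided exact binomial test, Benjamini–Hochberg corrected over the 4ᵏ
   k-mers.
2. **Intrinsic disorder at the breakpoint residue.** The nucleotide junction
   is mapped codon-aware onto the fusion protein (junction residue
   `ceil(d/3)` for `d` coding nucleotides retained from the 5′ partner,
   flagged `split` when the junction interrupts a codon). Per-residue
   disorder scores — from ingested external predictor tracks, or the bundled
   hydropathy/charge scorer `u = 2.785⟨H⟩ − |⟨q⟩| − 1.151`,
   `score = clip(0.5 − u/2, 0, 1)` — are thresholded at score > 0.5 into
   maximal disordered regions; breakpoints are classified
   disordered/structured per predictor and summarized as Venn and
   at-least-*k* consensus counts.
3. **PTM enrichment in disorder.** Phosphorylation (S/T/Y) and methylation
   (R/K) site densities are compared between disordered and structured
   regions — overall and within ±50 residues of the breakpoint — as
   occurrence ratios (sites per residue of the region, or per residue of the
   amino-acid class), pooled across proteins by summing counts, with
   per-class Fisher exact tests.

A seeded synthetic generator (`synthetic_config()`, `gen_partner_genes()`,
`gen_fusion_proteins()`, `gen_ptm_sites()`) plants known junction motif
biases, disordered tracts and differential PTM densities, so every stage of
the pipeline has a parameter-recovery test that runs offline.

## Worked example

```r
library(fusionscan)

cfg <- synthetic_config(seed = 42)       # GG junction bias 0.3, AG-suffix
gen <- gen_partner_genes(cfg)            # trinucleotide bias 0.3 planted

w   <- extract_windows(gen$sequences, gen$breakpoints)   # P-5..P+5 windows
sp  <- junction_spectrum(w, k = 2)                       # (P-1, P+1) 2-mers
bg  <- background_spectrum(gen$sequences, k = 2)
head(enrichment_test(sp, bg), 3)
#>    kmer observed_count observed_freq background_freq ratio  p_value  q_value
#> 11   GG            171        0.4275          0.0642  6.66 5.17e-94 8.27e-93
#> 9    GA             32        0.0800          0.0623  1.28 1.47e-01 1.67e-01
#> 12   GT             31        0.0775          0.0621  1.25 2.13e-01 2.27e-01
```

The planted GG bias is recovered: GG occurs at 43% of junctions against a
6.4% background (ratio 6.7, q ≈ 8e-93); the unplanted dinucleotides stay
near ratio 1. Disorder calling on a synthetic fusion protein:

```r
fus  <- gen_fusion_proteins(cfg)
id   <- names(fus$proteins)[1]
prof <- bundled_disorder_score(fus$proteins[[id]], sequence_id = id)
(rs  <- call_regions(prof))
#> Region set for fusion00001 ( 229 residues ): 1 disordered region(s)
#>   start end
#> 1   106 150
breakpoint_in_disorder(rs, fus$breakpoints$offset[1])
#> [1] FALSE
```

The scorer recovers the single planted disordered tract of protein 1; its
breakpoint (residue 224) lies in the C-terminal ordered tract, so it is
classified structured. Building and translating a fusion:

```r
translate_fusion(build_fusion("ATGGCTAGCAAGGAA", 9, "TTTGGCTAA", 3))
#> Fusion construct partner_a[1..9] + partner_b[4..] (15 nt)
#>   protein: 4 aa; junction residue 3 (aligned)
```

The whole pipeline (simulate → spectra → fusions → disorder → ptm → report)
runs with `run_pipeline(cfg, "outdir")`, or stage by stage from a shell via
`Rscript inst/cli/fusionscan.R <stage> --outdir outdir --seed 42`; stages
communicate only through FASTA/TSV files, so externally produced disorder
tracks (`--tracks`) or PTM tables drop in at the same seams the bundled
stand-ins use.

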