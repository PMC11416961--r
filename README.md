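# epimark

Multi-omic integration of DNA methylation, chromatin marks and gene
expression for studies of T-cell reprogramming.

When a T-cell population converts into a new functional state — for
example liver-resident invariant NKT (iNKT) cells reprogramming into a
regulatory, TR1-like subset under repeated ligand exposure — the
question is which epigenetic layer carries the change: DNA
methylation, chromatin accessibility, or the deposition of active
histone marks (H3K27ac, H3K4me3). `epimark` implements the analysis
chain used to answer that question from tabular genomics inputs:

* **DMR calling** from per-CpG bisulfite counts. Candidate regions are
  runs of CpGs covered in both groups (inter-CpG gap ≤ 300 bp,
  ≥ 5 CpGs). Methylated/unmethylated read counts are pooled over the
  region into one 2×2 table and tested with a two-sided Fisher exact
  test; a region is differentially methylated when the mean
  methylation level changes ≥ 2-fold (either direction) and
  P ≤ 0.05, with Benjamini–Hochberg q-values over all tested
  candidates (significant set at q ≤ 0.05). Adjacent same-direction
  DMRs merge when everything between them was also differentially
  methylated.
* **Active-enhancer prediction**: an open chromatin region (OCR) that
  overlaps an H3K27ac peak and does not overlap a promoter (2 kb
  upstream of the TSS) is an active enhancer, partitioned into
  gene-body versus intergenic compartments.
* **Window-based feature-to-gene annotation**: gene body > promoter >
  intergenic precedence, with intergenic features annotated to genes
  within a ±100 kb TSS window and enhancers linked to genes within
  ±50 kb.
* **Mark–expression association**: for each epigenetic mark, the 2×2
  table `[[up ∧ mark, up ∧ ¬mark], [down ∧ mark, down ∧ ¬mark]]` over
  genes classified as upregulated (FC ≥ 4, FDR ≤ 0.01) or
  downregulated (log2 FC < 0, FDR ≤ 0.01) is tested with a Pearson
  chi-square (df = 1, no continuity correction); the one-sided P is
  half the two-sided P in the observed direction. Fisher's exact test
  is available as a robustness alternative.
* **Epigenetic grouping**: hypo-methylated genes partition into
  Group 1 (+OCR +H3K27ac), Group 2 (+H3K27ac only), Group 3 (+OCR
  only) and Group 4 (hypo-methylation alone); per-mark tallies (radar)
  and 0–4 modification-type burdens per gene.
* **TCR clonotype analysis**: paired-chain clonotypes keyed on
  (TRAV, TRAJ, CDR3α, TRBV, TRBJ, CDR3β), clonal-group size spectra,
  V/J usage, and clonotype sharing across transcriptional
  sub-clusters.
* **Synthetic data with ground truth**: seeded generators for every
  input — toy genome, bisulfite methylomes with a tunable odds ratio θ
  between gene-body hypo-methylation and upregulation, peak sets with
  planted rule violations, DE tables that the classifier recovers
  exactly, and TCR repertoires with an exact clonal composition — so
  every caller is scored against a manifest.

Everything is tidyverse-native: data frames in, tibbles out, ggplot2
`plot_*()` builders, and broom-style `tidy()`/`glance()` for test
objects.

## Worked example

```r
library(epimark)

cfg    <- study_config(seed = 42, n_genes = 200, n_up = 50, n_down = 25)
study  <- simulate_study(cfg)
result <- run_pipeline(study)
result
#> <epi_pipeline>
#>   genes: 200 | DMRs: 87 (78 hypo / 9 hyper)
#>   enhancers pre/post: 214 / 221 (hypo-methylated: 17, linked genes: 46)
#>   DE: down=25, unchanged=125, up=50
#>   clonotypes: 331 over 343 cells (singleton fraction 94.75%)
```

87 DMRs are called on the synthetic methylome (78 hypo-, 9
hyper-methylated in the treated group), 214/221 active enhancers are
predicted pre/post treatment of which 17 post-treatment enhancers
colocalise with hypo-methylated DMRs (linked to 46 genes within
±50 kb of a TSS), the DE classifier recovers the intended 50 up / 25
down genes, and the generated repertoire resolves into 331 clonotypes
over 343 productive-paired cells.

A single contingency test — here, promoter hypo-methylation in 10 of
162 upregulated versus 0 of 76 downregulated genes:

```r
tidy(chi_square_2x2(matrix(c(10, 152, 0, 76), 2, byrow = TRUE)))
#> # A tibble: 1 × 7
#>   method     statistic p_one_sided p_two_sided odds_ratio odds_ratio_haldane
#>   <chr>          <dbl>       <dbl>       <dbl>      <dbl>              <dbl>
#> 1 chi-square      4.90      0.0135      0.0269        Inf               10.5
```

The one-sided P of 0.0135 says promoter de-methylation is
significantly enriched among upregulated genes; the infinite odds
ratio reflects the empty marked-and-downregulated cell (the
Haldane–Anscombe estimate, 10.5, is reported alongside).

Figures: `plot_mark_radar(result$tally)`,
`plot_burden(result$burden)`, `plot_mark_heatmap(result$mark_matrix)`,
`plot_clonal_spectrum(result$clonal)`.

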