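---
title: "Methods: models, parameters and design choices in epimark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in epimark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimark)
```

`epimark` integrates four epigenetic layers — DNA methylation,
chromatin accessibility, H3K27ac and H3K4me3 deposition — with
differential gene expression, and summarises TCR clonotype structure.
This vignette explains each model, its assumptions, the parameters
that matter, and the design decisions taken where the procedure was
genuinely open.

## Coordinates and annotation geometry

All intervals are 0-based half-open (BED convention) internally; the
per-CpG count parser converts from the 1-based report dialect at the
boundary. A single convention avoids off-by-one drift across the many
overlap rules. Two intervals overlap when they share a chromosome and
at least one base (`max(starts) < min(ends)`); there is no
minimum-overlap-fraction rule anywhere.

The TSS is the first transcribed base: `start` on the plus strand,
`end − 1` on the minus strand. Three windows drive annotation, all
set in `annotation_params()`:

* `promoter_upstream_bp` (default 2000) and `promoter_downstream_bp`
  (default 0): the promoter is the 2 kb strictly upstream of the TSS.
  A symmetric ±2 kb promoter is one parameter away
  (`promoter_downstream_bp = 2000`); the upstream-only reading was
  chosen because it is the operational definition used in
  enhancer-exclusion practice, and the two readings are otherwise
  interchangeable here.
* `gene_window_bp` (default 100000): intergenic features are
  annotated to every gene whose TSS lies within this half-width. The
  window is read as ±100 kb around the TSS (total span 200 kb) rather
  than a 100 kb total span, consistent with the ±50 kb enhancer rule
  being stated explicitly as "upstream or downstream".
* `enhancer_link_bp` (default 50000): enhancers are linked to genes
  within ±50 kb of the TSS. "Within N kb" is inclusive at exactly
  N kb.

`classify_location()` applies the precedence gene body > promoter >
intergenic, so every feature receives exactly one label; intergenic
features may link to zero genes when no TSS window reaches them.

## DMR calling

The caller tests *regions*, not single cytosines. Because no public
segmentation rule accompanies the criteria it implements, candidate
regions are defined deterministically: maximal runs of CpGs covered
in both groups whose consecutive positions are at most `max_gap_bp`
(default 300 bp) apart, keeping runs of at least `min_cpg` (default
5) sites. This is order-independent and matches the defaults of
common region-based callers. Replicates are pooled by summing counts
per site before analysis; per-replicate dispersion modelling is out
of scope.

Per candidate region:

1. methylated and unmethylated read counts are pooled per group into
   one 2×2 table and tested with a two-sided Fisher exact test. The
   criteria name Fisher's test per region without specifying its
   table; pooling raw counts is the simplest faithful construction
   and is exact at any coverage.
2. the methylation level per group is the mean of per-site levels
   (methylated / total reads per cytosine); zero-coverage sites never
   enter (candidates require coverage in both groups). The fold
   change is the larger mean over the smaller. If exactly one level
   is zero the fold is infinite and passes the threshold; if both are
   zero the region is not callable.
3. regions with fold ≥ `min_fold` (default 2) *and* P ≤ `alpha`
   (default 0.05) are reported. Direction is `hypo` when the treated
   level is below control.
4. Benjamini–Hochberg q-values are computed across **all tested
   candidates** genome-wide, and the significant set uses
   `q_threshold` (default 0.05).

Merging: consecutive same-direction DMRs on a chromosome join into
one region when no tested candidate between them failed the criteria
— the operational reading of "adjacent DMRs are joined if everything
in between is differentially methylated". Merged statistics are
recomputed from the pooled counts of the merged span, q-values are
recomputed over the resulting region set, and the operation is
idempotent. Note that a merge therefore re-anchors the BH adjustment
to the merged region list; when nothing merges the original
q-values are kept.

Only CpG context is analysed; the parser accepts a context column and
filters to CpG by default.

## Active enhancers and their genes

An active enhancer is each OCR that overlaps ≥ 1 H3K27ac peak and
overlaps no promoter interval. The reported interval is the whole OCR
— the phrasing is "open chromatin regions *containing* H3K27ac marks"
— with an intersection mode available. Enhancers are called per
condition; pre- and post-treatment peak sets are never unioned.
Compartment is gene body if the OCR overlaps any gene span, else
intergenic. One linking codepath serves both analyses, with the
half-width as its parameter: ±100 kb for annotation, ±50 kb for the
hypo-methylated-enhancer analysis. Differential peak calling itself
(DiffBind-class model fits) is deliberately an input, not a
computation: the differential-feature table carries assay, gain/loss
direction, FDR and gene.

## Differential expression classes

Upregulated: linear FC ≥ `up_min_fc` (default 4) and FDR ≤ `fdr_max`
(default 0.01). Downregulated: log2 FC < `down_max_log2fc` (default
0, i.e. any significant decrease). The asymmetry is intentional — the
source analyses use a 4-fold gate for upregulation but count any
significant decrease as downregulation ("FC ≤ 0" only parses on the
log scale, and a stated "FC ≤ 4" for downregulation is an apparent
typo). A symmetric option (`symmetric_down = TRUE`, FC ≤ 1/4) is
provided. Classification is a pure function of (FC, FDR), so `up` and
`down` are mutually exclusive by construction.

## Association statistics

For each mark, the table compares marked versus unmarked genes within
the upregulated and within the downregulated sets. The test is a
Pearson chi-square with df = 1 and **no Yates continuity
correction**; the one-sided P is `p/2` when the observed first-cell
count exceeds its independence expectation and `1 − p/2` otherwise.
This convention — halved, uncorrected — is the one that reproduces
the published P values for these tables (0.0135, 0.0327, 0.0976,
0.0008, 0.0034, 0.0002) where two-sided or Yates-corrected values do
not; both sidednesses are always reported, and the correction is
available as a flag. Two published values from the H3K4me3 donut
analysis (0.0004 and 0.0187) could not be reproduced under any
standard 2×2 construction of the printed counts and are treated as
unresolved.

The one-sided chi-square is an asymptotic approximation. Against a
fixed-margin permutation null it corresponds to the *mid-p* tail
(ties counted half), and the agreement is good only when expected
cell counts are large; for sparse tables — a zero cell, small margins
— it deviates systematically, which is one reason `fisher_2x2()` is
offered alongside. The test suite checks the permutation
correspondence on a well-conditioned table and checks Fisher against
exhaustive hypergeometric enumeration.

Odds ratios are reported raw (∞ allowed on a zero cell) together with
the Haldane–Anscombe estimate (0.5 added to each cell). Tests degrade
to `NA` (not an error) inside `association_report()` when a margin is
zero, since scanning many marks routinely hits all-false columns.

## Groups, tallies and burden

Epigenetic groups partition genes by co-occurrence: hypo-methylation
(any compartment) is required for Groups 1–4; differential-OCR gain
and H3K27ac gain split them 2×2 (Group 1 has both, Group 4 neither);
genes without hypo-methylation are ungrouped. The mark tally counts,
per mark, the up- and downregulated genes carrying it (the radar
numbers). The burden collapses marks to 4 types — any methylation
change, any accessibility change, any H3K27ac change, any H3K4me3
change — and histograms the 0–4 count per DE class.

## TCR clonotypes

Cells with exactly one productive α and one productive β chain are
kept. The clonotype key is (TRAV, TRAJ, CDR3α, TRBV, TRBJ, CDR3β)
with CDR3 identity at the nucleotide level — the strictest identity;
an amino-acid mode exists because "identical CDR3" does not specify
the level. Sharing ("twins") is reported within treatment arms by
default and across arms with a flag, since the published comparison
is not explicit on this point. Singletons are never shared.

## The synthetic-data generators

The generators define the study conditions; they are not tuning
dials. Defaults mirror the modelled system: 162 upregulated and 76
downregulated genes; a repertoire of 343 productive-paired cells (of
528 sequenced) composed of 325 singleton clonotypes, two 5-cell and
four 2-cell clonal groups with the published cluster placement, and
333 cells using TRAV11/TRAJ18; bisulfite coverage Poisson with mean
100; a 4-fold methylation effect in true regions.

* **Genome**: genes of 3–8 kb laid down with 20–50 kb gaps on 4
  chromosomes, strands random — spans cannot overlap by construction.
  The generous gaps guarantee that planted promoter and intergenic
  features cannot collide with neighbouring genes.
* **Methylome**: CpGs are laid down as islands (by default 10 CpGs at
  100 bp spacing, islands 400 bp apart edge-to-edge) because the
  run-based segmenter needs inter-region gaps larger than
  `max_gap_bp` to see region boundaries; this mimics CpG-island
  clustering rather than a uniform CpG lawn. Island baseline levels
  are Beta(8, 2) (mean 0.8, typical for gene-body CpGs); counts are
  Binomial(Poisson coverage, level). A true hypo region divides the
  treated level by `effect_fold`; true hyper regions start from a low
  Beta(2, 8) baseline so a ≥ 2-fold *increase* is attainable. The
  association parameter θ acts on gene-body hypo-methylation only:
  down/null genes receive a hypo region with probability
  `p_down_hypo` (default 0.2) and up genes with the probability whose
  odds are θ times larger. Promoter/intergenic hypo regions and hyper
  regions are class-independent (odds ratio 1), matching the design
  in which only the gene-body association is the estimand.
* **Peaks**: enhancer-candidate OCR/H3K27ac pairs sit in fixed
  non-overlapping slots inside gene bodies so that planted rule
  violations (promoter-overlapping OCRs, OCRs without H3K27ac)
  cannot accidentally borrow another candidate's H3K27ac peak — the
  truth labels are exact by construction, letting the enhancer test
  assert exact recovery rather than approximate agreement.
* **DE table**: fold changes and FDRs are drawn inside the acceptance
  regions of the thresholds (up: FC 4–64 at FDR ≤ 10⁻³; null: FC
  within (2⁻¹·⁹, 2¹·⁹) at FDR ≥ 0.05), so classification recovers the
  classes exactly and DE recovery failures can only indicate
  classifier defects.
* **Repertoire**: clonal groups are realised exactly per the
  composition table; the TRAV11/TRAJ18 quota is assigned per
  clonotype (never splitting one clonotype across V genes). Exact
  rather than sampled composition keeps the clonal-spectrum
  arithmetic checkable to the last digit. One consequence: the
  singleton fractions are deterministic, so those checks are exact
  identities rather than statistical statements.

What the generators do *not* emulate: read-level error, bisulfite
conversion failure, spatially correlated chromatin state,
overdispersed (non-binomial) methylation counts, replicate-level
variance, and biased coverage. Passing tests therefore demonstrate
correctness of the rules and statistics under the declared generative
family, not robustness to real-data artefacts.

## Problem sizes and numerical choices

The test suite runs the full pipeline on studies of 40–200 genes at
25–100× coverage, the DMR-sensitivity check on 200 genes at 100×
coverage with 4-fold effects, the null-calibration check on 2,000
simulated candidate regions, the permutation comparison with 200,000
fixed-margin draws, Fisher-versus-enumeration on tables up to N = 60,
and parameter recovery over 100 (θ = 6) and 1,000 (θ = 1)
replicates at the default 162/76 class sizes. These sizes were chosen
so each statistical check has the power it needs while the whole
suite stays comfortably interactive.

Ties and degenerate inputs: equal levels give fold 1 (never a DMR);
both-zero levels give no call; zero-coverage sites are excluded
before candidates form; chi-square errors on a zero margin when
called directly but reports `NA` inside the association scan;
`merge_adjacent_dmrs()` with ≤ 1 DMR is the identity. The BH
recomputation after merging is the one place where a downstream step
re-anchors an upstream statistic; it is documented above and
deliberate (the merged region list is the unit of inference).

## Known limitations

* The DMR caller's pooled-count Fisher test treats reads as
  independent Bernoulli draws; biological replicate variance is not
  modelled (no beta-binomial), so at very high coverage the test is
  anti-conservative against replicate noise. The q-threshold and the
  fold gate mitigate but do not remove this.
* Segmentation is coverage-driven, not signal-driven: a true region
  sharing an island with unchanged CpGs is diluted. The island
  defaults make regions coincide with islands; real data need a
  segmentation choice (`max_gap_bp`) informed by CpG density.
* The one-sided chi-square convention is tied to the published
  values; for sparse tables prefer `fisher_2x2()`.
* Gene models are whole spans; exon structure, alternative TSSs and
  CpG-island annotation are not modelled.
* Differential peak calling and DE model fitting are inputs by
  design.
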