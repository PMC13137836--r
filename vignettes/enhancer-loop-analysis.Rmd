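---
title: "Classifying and integrating enhancer-promoter chromatin interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and integrating enhancer-promoter chromatin interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiloops)
library(dplyr)
```

`epiloops` takes the tabular products of an enhancer-regulation study —
promoter-capture Hi-C (PCHi-C) significant interactions, H3K27ac HiChIP
loops, H3K27ac peak calls, expression and DEG tables, viability plates —
and carries them through classification, cross-sample signatures,
differential-region calling and gene-level integration. This vignette
explains the model behind each step, the thresholds that matter, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the problem left genuine choices.

## Coordinates and promoter windows

Everything is BED-style: 0-based starts, half-open `[start, end)`
intervals, overlap meaning at least one shared base pair, strand ignored for
overlap. A single internal convention avoids fencepost drift; readers for
1-based dialects convert at the boundary. Chromosome names match by exact
string equality — `normalize_chroms()` bridges "chr1"/"1" only when asked,
because silent aliasing corrupts overlap counts.

Promoter windows are symmetric ±1 kb flanks around each transcript TSS
(`flank = 1000`, configurable), clipped at the chromosome origin; on the
minus strand the TSS is the last transcribed base (`txEnd − 1`). The ±1 kb
choice follows the `slop -b 1000` convention: a "2 kb flanking region" in
the loose sense of 2 kb total width. Windows are built per transcript by
default — a gene with several TSSs gets several windows, all carrying its
`gene_id` — because fragment-level capture data cannot resolve which TSS a
bait serves; identical duplicate windows collapse.

The interval algebra itself (overlap, gap-bridged merging, bp-level
multi-sample consensus, presence/absence differences) is delegated to
GenomicRanges/IRanges behind tibble-in/tibble-out wrappers; the test suite
verifies each operation against independent per-base brute-force oracles
rather than trusting either implementation.

## Interaction classification

**PCHi-C mode** is asymmetric: each interaction has a bait (captured
promoter fragment) and an other end (OE). Four activity classes cross bait
and OE H3K27ac status (`AP_AO`, `AP_IO`, `IP_AO`, `IP_IO`). The regulatory
classes are:

* **EPI** — H3K27ac⁺ promoter bait contacting an H3K27ac⁺ OE that overlaps
  no promoter window (an active enhancer proxy);
* **PPI** — the OE is an H3K27ac⁺ promoter.

An OE that overlaps both a promoter window and a peak is classified PPI:
promoter identity takes precedence, since a three-way outcome needs a
precedence rule and promoter annotation is the more specific claim.
`ambiguous_oe = "both"` additionally marks such contacts
(`oe_also_enhancer`) for analyses that want to count them toward EPIs too.

**HiChIP mode** is symmetric and the assay guarantees H3K27ac on at least
one anchor, so only promoter-window overlap is consulted: PPI if both ends
are promoters, EEI (enhancer–enhancer) if neither, EPI otherwise. No
activity class is emitted, and classification is invariant under swapping
the two ends (tested). PCHi-C mode never emits EEI; the capture design
makes a promoterless bait a contradiction rather than a class.

**Active genes and promoter classes.** A gene is active when its mean
normalized count across the reference-condition samples is ≥ 10 *and* its
promoter window overlaps a peak. The mean-of-reference-samples reading was
chosen because the activity filter precedes any treatment comparison;
per-sample filtering would make the active universe condition-dependent.
Each active gene then aggregates the classes of the interactions whose bait
maps to its promoter — baits touching several windows contribute to every
overlapped gene — into exactly one of `EPI_ONLY`, `PPI_ONLY`,
`EPI_AND_PPI`, `NO_ACTIVE_OE`. The four labels partition the active set and
the partition is asserted on every run. Genes whose contacts all end at
peak-free OEs and genes with no significant contacts both fall in
`NO_ACTIVE_OE`; `has_any_interaction` keeps the two distinguishable, since
the biological readings differ (inactive wiring vs no wiring detected).

HiChIP raw counts become interaction scores by per-10-million
normalization, `score = count × 10⁷ / library_size`, and duplicate records
(one loop reported once per expected-contact cluster) collapse to one per
(sample, canonical id), keeping the largest raw count. Canonical ids order
the two ends lexicographically, so end order never splits an interaction.

## Cross-sample signatures

Core interactions are the canonical ids that qualify (default: EPI or PPI)
in *every* sample — the class filter is evaluated per sample, so a contact
that loses its active OE in one sample drops out. Identity across samples
is exact coordinate equality of both ends, which presumes one shared
fragment map; a tolerance-window matcher is deliberately out of scope.

The interactions × samples score matrix fills undetected cells with 0 by
default: at a fixed significance threshold, non-detection is evidence of
absence, and the alternative (`missing_policy = "drop"`) is available for
sensitivity analysis. Sample profiles feed

* **UPGMA**: Euclidean distances, average-linkage `hclust` — merge heights
  are mean inter-cluster distances and cannot invert (tested); and
* **PCA**: samples as observations, column-centred, unscaled (the `prcomp`
  defaults). SVD component signs are arbitrary, so each component is
  canonicalized to make its largest-magnitude loading positive — tests and
  re-runs then see identical coordinates.

No variance filtering is applied before clustering or PCA; with score
matrices this small the full core set is used as-is.

## Differential H3K27ac regions

Two engines are implemented. The presence/absence engine is the
`intersect -u/-v` convention: `lost` = reference peaks with no treatment
overlap, `gained` = the converse; per-sample results are merged within
1 kb (`-d 1000`) and intersected across samples at bp resolution. The
count-based engine follows the fold + Poisson core of the Homer
`getDifferentialPeaks` test: on per-10M normalized tag counts over a shared
region set, a region is flagged iff fold ≥ 2 and the one-sided Poisson tail
`P(X ≥ observed)` with mean equal to the comparison sample's count (floored
at one pseudo-tag, so empty comparisons cannot produce infinite folds or
zero-mean tails) is below 0.05. Non-integer normalized observations are
rounded up — the conservative direction. This is a deliberately simplified
surrogate with parameter-compatible knobs (`fold_min`, `p_max`,
`recenter_regions(size = 500)` for fixed-width windows around region
midpoints); background rescaling and Homer's exact pseudo-count conventions
are not reproduced. Dispersion-model engines (DiffBind/edgeR-style) are
consumed as external tables through the DEG reader path, not re-implemented.

Heatmap exports z-score each region row; zero-variance rows map to 0, not
NaN, so exports are deterministic.

DEG thresholding is the printed rule — `padj < 0.05` and `|log2FC| > 1`,
both strict — and the four-way gene grouping crosses a disease contrast
with a drug contrast into `PH_UP_ONLY`, `PH_UP_TKI_DOWN`, `TKI_DOWN_ONLY`,
`OTHER`, again an asserted partition of the supplied universe.

## Gene-level integration

* **Enrichment** (`set_enrichment()`): 2×2 Fisher exact p (two-sided) with
  the cross-product odds ratio, Haldane-corrected when a cell is zero.
  Fisher is the primary statistic for comparing fractions of a dichotomy;
  `expression_contrast()` (Welch, or paired for matched before/after
  values) is provided alongside for mean comparisons, reporting `p = 1`
  with a flag on degenerate zero-variance input rather than erroring.
* **EPI scores per gene**: mean of the gene's EPI interaction scores, with
  sum and count carried so either aggregation can be read off; condition
  deltas are computed on the genes present in both conditions.
* **HiChIP loop changes**: per-gene loop counts (a loop belongs to a gene
  when either end overlaps its promoter window) averaged within sample
  groups, compared as `log2((mean_a + 0.5)/(mean_b + 0.5))`; the
  pseudocount keeps genes observed in one group finite.
* **Concordance** of loop changes with expression changes is Spearman rank
  correlation. A smoother (GAM trend line) is a visualization, not a test;
  a rank correlation is the quantitative statement the figure implies.
* **Bliss synergy**: inhibition `y = 1 − viability`; expected combination
  inhibition `yA + yB − yA·yB` from the zero-dose margins; per-cell excess
  ×100; the summary score is the unweighted mean over combination cells
  only (margins excluded — they define the expectation and would dilute
  it), with the ±10 call thresholds. The full grid is always exported so a
  per-dose-window reading remains possible. Plates normalize to reference
  wells per experiment (`dmso`: both doses zero; `tki_only`: drug A alone),
  which makes the normalization scale-invariant per plate.

## The synthetic study generator

`synthetic_config()` + `generate_synthetic_study()` produce a complete toy
study with planted ground truth; it is first-class, tested code, and the
pipeline's default input. The geometry is a grid of 20-kb gene slots (200
genes over 4 chromosomes by default; generation fails before writing
anything if a requested chromosome length cannot fit the slots). Each
active gene gets a promoter peak; EPI-class genes get an enhancer peak and
a contact to it; PPI-class genes a contact to another active promoter; half
of the `NO_ACTIVE_OE` genes a contact to a peak-free region. Enhancer
positions are placed so planted EPI other ends can never overlap promoter
windows, and planted interaction scores never drop below the significance
floor — class truth is unambiguous at zero peak jitter, which is what makes
"100% recovery" a meaningful contract rather than a statistical hope. With
jitter the contract deliberately degrades (regression-tested at three
jitter levels).

Default statistical structure, chosen once as realistic study conditions:
log2-normal expression (mean 6, gene sd 0.5, replicate sd 0.25 on the log2
scale, three replicates per condition) with a +1 log2 boost for EPI⁺ genes;
drug sensitivity planted at probability 0.7 for EPI⁺ vs 0.2 for other
active genes, with a −2 log2 treatment effect; 15% of genes inactive; two
interaction-sample groups of three with 40 group-specific interactions
shifted by +5 score units against noise sd 0.5 (a 10× shift-to-noise
ratio); HiChIP loop intensities coupled to the planted disease expression
effect so loop and expression fold changes are concordant; a viability
plate with +0.15 planted Bliss excess and 1% well noise. DEG tables are
*computed from the generated counts* (vectorized Welch t on log2 values,
BH-adjusted) rather than sampled independently, so the pipeline and the
truth cannot disagree by construction — consistent with treating
differential-expression inference itself as an upstream input everywhere
else in the package.

What the generator does **not** emulate: read-level noise, fragment-level
contact background and distance decay, copy-number structure, antibody
efficiency differences, batch effects, and realistic peak-shape variation.
Passing tests therefore demonstrate the correctness of the bookkeeping,
thresholds and statistics on data whose structure is known — not detection
power on real sequencing noise.

## Orchestration and determinism

`pipeline_config()` is the single source of truth for a run — every
threshold (CHiCAGO floor 5, activity floor 10, DEG 1/0.05, differential
2/0.05, merge gap 1000, flank 1000, region size 500, synergy bound 10) plus
the seed; unknown keys are rejected so a typo cannot silently disable a
filter. `run_pipeline()` executes simulate → classify → signature →
differential → integrate, writing plain-text tables per stage, logging row
counts and the config hash, and is byte-identical when re-run with the same
config: all randomness flows from the one seed. The package exposes no
shell entry point — it is an analysis library; the exported functions and
this vignette are the interface, and `scripts/acceptance.R` shows a
complete scripted run.

Test and acceptance problem sizes were picked to keep the full suite fast
while leaving the statistical claims testable: 100-seed recovery loops at
the default 200-gene study, oracle comparisons on ~1,000 random intervals
per operation, and Fisher enumeration on tables up to n = 200.

## Known limitations

* Cross-sample interaction identity is positional; data from different
  fragment maps must be harmonized upstream.
* The fold + Poisson differential engine is a surrogate for Homer's test,
  not a reimplementation; treat borderline calls accordingly.
* `epi_enrichment`/`classify_promoters` assume one expression universe;
  genes missing from the expression table are warned about and treated as
  count 0.
* No dose-response curve fitting, no ZIP/LOEWE/HSA synergy models, no
  GAM smoothing, no loop calling or contact-significance modelling — those
  belong to upstream tools whose outputs this package consumes.
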