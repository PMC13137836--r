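# epiloops

Integrative analysis of enhancer regulation from chromatin-interaction data.

In cancers driven by enhancer hijacking and deregulation — the motivating
case is Philadelphia-chromosome-positive (Ph+) B-cell acute lymphoblastic
leukemia — key oncogenes are wired to distal enhancers through long-range
chromatin loops. `epiloops` implements the downstream analysis that connects
three data layers at the gene level:

1. **chromatin interactions** — promoter-capture Hi-C significant contacts
   (CHiCAGO-score convention) and H3K27ac HiChIP loops (raw counts +
   library sizes),
2. **enhancer activity** — H3K27ac ChIP-seq peak calls, and
3. **transcription and drug response** — normalized expression tables, DEG
   tables, and dose-response viability plates.

It is aimed at epigenomics analysts who already have upstream calls (peaks,
loops, DEG tables) and need the classification, signature, differential and
integration steps as tested, reusable functions. Everything is
data-frame-first: functions take tibbles and return tibbles, so steps chain
with the pipe; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` plots.

## The core classifications and statistics

All coordinates are BED-style half-open `[start, end)`. Promoter windows are
`[TSS − 1000, TSS + 1000)` (`bedtools slop -b 1000` convention). With
promoter (P) and H3K27ac (K) status of the two ends of each contact:

* **PCHi-C mode** (bait → other end, OE): an interaction is an
  **EPI** (enhancer–promoter interaction) when an H3K27ac⁺ promoter bait
  contacts an H3K27ac⁺ *non-promoter* OE; a **PPI** when the OE is an
  H3K27ac⁺ promoter. Activity classes `AP_AO … IP_IO` cross bait/OE H3K27ac
  status. Each **active gene** (normalized count ≥ 10 and H3K27ac⁺
  promoter) is then labelled `EPI_ONLY`, `PPI_ONLY`, `EPI_AND_PPI` or
  `NO_ACTIVE_OE` — a strict partition.
* **HiChIP mode** (symmetric ends, H3K27ac guaranteed by the assay):
  **PPI** if both ends are promoters, **EEI** if neither, **EPI** otherwise.
  Loop scores are raw counts normalized per 10 million reads:
  `score = count × 10⁷ / library_size`.
* **Signatures**: core interactions (class-qualified in *every* sample) form
  an interactions × samples score matrix, analysed by Euclidean/average-
  linkage clustering (UPGMA) and centred PCA (samples as observations).
* **Differential H3K27ac regions**: presence/absence (`intersect -v`) and a
  fold + Poisson rule (flag iff fold ≥ 2 and `P(X ≥ obs | λ = comparison)`
  < 0.05, λ floored at 1 tag), with `-d 1000` merging and multi-sample
  bp-level consensus.
* **Bliss synergy**: with single-agent inhibitions `yA`, `yB`, the expected
  combination inhibition is `yA + yB − yA·yB`; the per-cell excess
  `(y_obs − e) × 100` averaged over combination cells is called
  synergistic above +10, antagonistic below −10.
* **Enrichment**: 2×2 Fisher exact test with cross-product odds ratio
  (Haldane-corrected), e.g. the fraction of drug-sensitive genes among
  EPI⁺ vs non-EPI genes.

## Worked example

A six-gene toy study (also shipped as plain-text fixtures under
`inst/extdata/worked_example/`) small enough to check by hand:

```r
library(epiloops)
library(dplyr)

wx <- worked_example()
ints <- wx$interactions |>
  filter(sample == "s1") |>
  annotate_ends(filter(wx$peaks, sample == "s1"), wx$promoters) |>
  classify_interactions(mode = "pchic")
classify_promoters(ints, wx$promoters, wx$expression,
                   filter(wx$peaks, sample == "s1"))
#> # A tibble: 5 × 6
#>   gene_id promoter_class n_epi n_ppi has_any_interaction mean_expression
#>   <chr>   <chr>          <int> <int> <lgl>                         <dbl>
#> 1 g1      EPI_AND_PPI        1     1 TRUE                             51
#> 2 g2      EPI_ONLY           1     0 TRUE                             62
#> 3 g3      PPI_ONLY           0     1 TRUE                             21
#> 4 g4      NO_ACTIVE_OE       0     0 TRUE                             29
#> 5 g5      NO_ACTIVE_OE       0     0 FALSE                            13
```

g1 has one EPI and one PPI; g4's only contact reaches a peak-free other
end and g5 has no contacts at all (`has_any_interaction` separates them);
g6 (count 2 < 10, no promoter peak) is not an active gene and is absent.
The HiChIP loops score `5, 3, 2` reads at library size 5 × 10⁶ into
`10, 6, 4` per 10 M, and the single combination well of the viability plate
(yA = 0.5, yB = 0.4, observed inhibition 0.9) gives

```r
bliss_synergy(viability_matrix(normalize_viability(wx$viability, "dmso")))
#> Bliss synergy: mean score 20.00 (synergistic)
```

For a full-size run, `generate_synthetic_study(synthetic_config(seed = 1))`
builds a 200-gene study (170 active) with 1,752 interaction records across
six samples plus HiChIP loops, expression, DEG tables and a viability plate,
all with planted ground truth, and `run_pipeline(pipeline_config(seed = 1),
out_dir)` executes simulate → classify → signature → differential →
integrate end to end, deterministically under the seed.

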