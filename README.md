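# pressrecover

Resistance, resilience and activity dynamics of microbiomes under a press
disturbance.

`pressrecover` is for microbial ecologists analysing paired 16S rRNA /
rRNA-gene (cDNA/DNA) amplicon time series from disturbance experiments —
replicated mesocosms tracked before, during and after a sustained stressor,
with or without an experimental dispersal event. DNA profiles alone conflate
active cells, dormant cells and relic DNA; pairing each DNA library with an
rRNA library from the same cell pool lets the pipeline split every sample
into a **Total** community and an **Active** community (taxa with
rRNA:rRNA-gene ratio > 1, quantified by their DNA reads) and quantify which
mechanism — local resuscitation from the dormant pool or immigration —
rebuilds the community after the stressor is released.

## What it computes

* **Activity designation** on rarefied paired counts, with explicit
  handling of *phantoms* (RNA without DNA; undefined ratio, excluded) and
  below-detection taxa.
* **Diversity**: richness, Pielou's evenness (`H / ln S`), Bray–Curtis
  dissimilarity, principal coordinates with negative-eigenvalue
  bookkeeping, and beta dispersion as distance to the group spatial median.
* **Stability indices** of community structure, from within-mesocosm
  Bray–Curtis similarity `y` to the pre-disturbance baseline:

  ```
  RS = 1 − 2|y_c − y_d| / (y_c + |y_c − y_d|)
  RL = 2|y_c,s − y_d,s| / (|y_c,s − y_d,s| + |y_c,e − y_d,e|) − 1
  ```

  both unitless in [−1, 1]; `RS = 1` means no displacement beyond the
  controls, `RL = 1` full recovery over a succession window (s, e).
* **Subset contributions to beta diversity**: the share of Bray–Curtis
  dissimilarity carried by any taxon subset,
  `Σ_S |x_i − y_i| / Σ |x_i − y_i|`, applied to *responsive* taxa
  (activity flips during succession) and *immigrant* taxa (a four-clause
  detection rule across treatments and weeks).
* **Response categories** for the most abundant Active taxa: resistant,
  sensitive, early/late transition, resilient, opportunist, immigrant.
* A **mechanistic simulator** of the 15-mesocosm thermal-press design
  (dormancy dynamics, Gaussian thermal niches, relic DNA, a dispersal
  event, multinomial paired read sampling) with planted ground-truth
  archetypes, used to validate the pipeline end to end.

## A worked example

Simulate the default design (292 taxa, 6 control + 5 disturbance + 4
disturbance+immigration mesocosms, sampled weeks 4–45, rarefied to 50 000
reads) and run the full analysis:

```r
library(pressrecover)
res <- run_press_analysis(press_config(seed = 101))
res
#> press_analysis
#>   128 paired samples x 292 OTUs at depth 50,000 (7 pair(s) omitted, 7 libraries discarded)
#>   phantom cells excluded: 9
#>   resistance (week 10): median 0.062 [0.061, 0.068]
#> stability summary by treatment
#>         kind window               treatment median    min    max
#> 1 resistance     10             disturbance 0.0616 0.0612 0.0622
#> 2 resilience  16-20             disturbance 0.0206 0.0200 0.0207
#> 3 resilience  16-45             disturbance 0.2206 0.2199 0.2207
#> 4 resilience  20-45             disturbance 0.2006 0.2002 0.2010
#> 5 resistance     10 disturbance_immigration 0.0630 0.0614 0.0683
#> 6 resilience  16-20 disturbance_immigration 0.2079 0.1746 0.2350
#> 7 resilience  16-45 disturbance_immigration 0.7593 0.7550 0.7748
#> 8 resilience  20-45 disturbance_immigration 0.6602 0.6322 0.6834
#>   responsive taxa: 55; immigrant taxa: 11
#> response categories (50 taxa):
#>        resistant        sensitive early_transition  late_transition
#>                8               20                4               11
#>        resilient      opportunist        immigrant     unclassified
#>                0                1                6                0
```

Reading this: 7 of 270 libraries fell below the rarefaction depth, so 7 of
135 sample pairs were omitted — the discard report is in
`res$manifest$discarded_samples`. Resistance at the height of the press is
near zero (the Active community is displaced almost completely from its
baseline), and the dispersal treatment is far more resilient over the full
secondary succession (median RL 0.76 vs 0.22 without immigration). Among
the 50 most abundant Active taxa the classifier finds the planted spectrum
of responses; `res$contributions` apportions the post-press beta diversity:

```r
res$contributions
#> contribution of taxon subsets to Total-community beta diversity
#>       subset min_pct median_pct max_pct
#> 1 responsive    6.53      25.10   47.02
#> 2  immigrant    0.00       3.42    6.33
```

`write_report(res, "out/")` writes one TSV per stage (activity calls,
divergence series, stability indices, heatmap-ready profile matrix,
categories, contributions, discards) plus a JSON manifest; the same
analysis is scriptable via `inst/scripts/pressrecover`. File-based runs
accept tab-separated OTU tables (OTUs as rows) or BIOM, plus a sample
metadata TSV — see `?read_otu_table` and `?press_config`.

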