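# apexloc

Ratiometric protein localization from APEX2 proximity-labeling TMT
proteomics, with signal-peptide feature analysis.

## What this is for

APEX2 proximity labeling biotinylates proteins within ~10–20 nm of a bait
protein; because the phenol radical does not cross membranes, labeling is
compartment-specific.  Quantifying the biotinylated pools of several baits
per compartment with multiplexed TMT mass spectrometry gives a
protein × sample intensity matrix from which each protein's subcellular
localization can be inferred.  `apexloc` is for proteomics groups applying
this design to cells with several membrane-bound compartments — the
motivating case is cyanobacteria, whose thylakoid lumen and
periplasm/outer membrane (P-OM) both receive proteins through N-terminal
signal peptides — and for anyone studying which signal-sequence
characteristics correlate with sorting between such compartments.

The pipeline:

1. **Normalization** — `ln(x + 1)` transform, cyclic loess (reference-average
   or full pairwise, both verified bit-for-bit against
   `limma::normalizeCyclicLoess`), back-transform `e^x`; QC by sample
   Pearson correlation and PCA.
2. **Enrichment** — per protein and sample pair,
   `e = log2((a + 1) / (b + 1))`.
3. **Classification** — per comparison, a ROC scan anchored on curated
   control proteins picks the enrichment cutoff maximizing TPR − FPR
   (TPR/FPR defined with the ≥ convention over detected controls); a
   protein above the cutoff in ≥ 35 of the 36 comparisons
   (2 baits × 3 replicates vs 2 baits × 3 replicates) is called for the
   compartment, a reverse pass calls cytoplasm, and the lumen/P-OM
   analyses merge by precedence into
   {lumen, pom, dual, cytoplasm, unknown}.
4. **Signal-peptide features** — per peptide and region (full, N, H, C):
   composition, GRAVY, molecular weight, pI, charge at pH 7/8/9, charged
   residue counts, mean z-scales, z-scale auto/cross-correlation
   `A_jj(d) = Σ z_j(i) z_j(i+d) / (N − d)` at lags 1–4, and
   secondary-structure/burial run statistics from JPred-style predictions.
5. **Group statistics** — pooled-variance Student's t per (region,
   feature) between lumen- and P-OM-localized peptides of one SignalP
   category (SP, LIPO, TAT, TATLIPO), raw P < 0.05 counting, optional
   cross-species transfer through best-reciprocal-hit homologs.

A first-class synthetic-data module (`sim_config()`,
`generate_compartment_proteome()`, `generate_tmt_intensities()`,
`generate_signal_peptides()`, `generate_ss_predictions()`) emulates the
whole input stack with known ground truth.  See
`vignettes/apexloc-methods.Rmd` for the model, parameter choices, and
design decisions.

## Worked example

```r
library(apexloc)

cfg   <- sim_config(seed = 1)          # 100 lumen, 100 P-OM, 20 dual, 800 cytoplasm
truth <- generate_compartment_proteome(cfg)
m     <- generate_tmt_intensities(truth, cfg)
m
#> intensity_matrix: 1020 proteins x 18 samples (intensity scale)
#> samples per bait compartment: cytoplasm=6, lumen=6, pom=6

norm <- back_transform(cyclic_loess_normalize(log_transform(m)))
res  <- classify_compartmentalome(norm, truth_control_sets(truth))
table(res$calls$final)
#>     lumen       pom      dual cytoplasm   unknown
#>       100        96        18       779        27
```

Of the 1,020 simulated proteins, the classifier recovers the lumen and
P-OM proteomes almost completely (the handful of `unknown`s are proteins
whose simulated labeling effect is intrinsically weak), finds the dually
localized proteins, and calls no cytoplasmic protein into a compartment.
Control bookkeeping matches: all 40 lumen control proteins are recovered
(`res$summary$lumen_controls$tp_recovery` is `1`).

```r
pc    <- sp_sim_config(seed = 1)
peps  <- generate_signal_peptides(pc)
preds <- generate_ss_predictions(peps, pc)
ft    <- feature_table(peps, preds)
cmp   <- compare_localizations(ft, category = "SP")
cmp$n_significant
#> [1] 58
head(cmp$results[order(cmp$results$p), c("region", "feature", "t", "p")], 5)
#>     region     feature         t            p
#> 271      h acf_z1_lag1  6.772847 2.124364e-09
#> 312      h  helix_conf  6.626334 4.012953e-09
#> 53    full acf_z1_lag1  6.554649 5.471370e-09
#> 268      h     mean_z1 -6.211582 2.382618e-08
#> 280      h acf_z1_lag2  5.545760 3.855003e-07
```

58 of 436 SP characteristics separate the groups; the strongest are
H-region hydrophobicity (z1) autocorrelation, helix confidence and mean
z1 — the synthetic world's lumen peptides carry more hydrophobic,
more helical H-regions, the pattern the analysis is designed to detect.

## Command-line pipeline

Every stage is also a subcommand driven by one JSON config (seed, paths,
and all stage parameters; outputs carry provenance headers):

```sh
Rscript -e 'apexloc::pipeline_main()' all --config config.json --seed 1
# or stage by stage: simulate | normalize | classify | features | compare | report
```

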