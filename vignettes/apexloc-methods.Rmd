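---
title: "apexloc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apexloc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexloc)
```

## The problem

APEX2 proximity labeling anchors an engineered peroxidase in one
membrane-bound compartment of a cell (here: the cyanobacterial cytoplasm,
thylakoid lumen, or periplasm/outer membrane, "P-OM").  With biotin-phenol
and H2O2, APEX2 biotinylates proteins within ~10-20 nm; because the phenol
radical does not cross membranes, the biotinylated pool is
compartment-specific.  Labeling several baits per compartment, purifying
the biotinylated proteins, and quantifying them with TMT multiplexed mass
spectrometry yields a protein x sample reporter-ion intensity matrix whose
between-compartment ratios encode localization.

`apexloc` implements the full downstream analysis: normalization,
enrichment ratios, a control-anchored ratiometric classifier,
signal-peptide feature computation for the classified proteomes, and
two-group significance scans of those features.  A synthetic-data module
generates ground-truthed inputs with the statistical structure the
analysis assumes, so every stage is testable without the original data.

## Normalization and enrichment

Intensities are transformed as $\ln(x + 1)$, normalized by cyclic loess,
and back-transformed as $e^x$ (deliberately *without* subtracting the 1:
the downstream enrichment formula re-adds it, and the published pipeline
used exactly this asymmetric pair of transforms).  The enrichment of
protein $p$ between samples $a$ and $b$ is

$$ e_p(a, b) \;=\; \log_2 \frac{x_{pa} + 1}{x_{pb} + 1}, $$

which is antisymmetric and always finite for nonnegative intensities.

Cyclic loess fits, for a sample pair, a local-linear smooth of
$M = x_i - x_j$ against $A = (x_i + x_j)/2$ and removes the fitted trend.
Two variants are provided and both are verified bit-for-bit against
`limma::normalizeCyclicLoess`:

* `method = "fast"` (default): each sample is smoothed against the mean of
  all samples, once per cycle.  This is also the default of the limma
  routine the original analysis called.
* `method = "pairs"`: every unordered pair is visited per cycle, with
  exactly zero-sum adjustments (half subtracted from one sample, half
  added to the other), so the grand mean is preserved to rounding error.

**Why "fast" is the default.**  Cyclic loess assumes most proteins are
unchanged between samples.  Proximity-labeling data violate this strongly:
between a P-OM-bait and a cytoplasm-bait sample, *most* proteins differ by
the labeling effect.  On synthetic data with known truth, the pairwise
variant interprets this biology as intensity-dependent bias and removes
enough of it to collapse the separation between true-positive and
false-positive control enrichments; the reference-average variant dilutes
each biological contrast across all 18 samples and distorts far less.
Both remain available, and the choice is configurable per run.

**Numerical behavior.**  A lowess smooth of noisy $M$-$A$ scatter has
wiggle of order $\mathrm{sd}(M)/\sqrt{\mathrm{span}\cdot n}$; cyclic loess
therefore keeps making small adjustments on noisy data and is idempotent
only up to that scale.  The package's idempotence test uses
trend-dominated pair structure (small constant offsets), where sequential
pairwise averaging contracts geometrically and the default 3 cycles reach
a fixed point to within $10^{-3}$.  Span 0.7 and 3 cycles follow the
limma defaults; both are configurable.

QC mirrors the original study: pairwise Pearson correlations between
samples on the normalized (back-transformed) values, and a centered PCA of
the ln-scale matrix with samples as observations.

## Ratiometric classification

For one analysis (say thylakoid lumen), each of the 6 lumen-bait samples
(2 baits x 3 replicates) is paired with each of the 6 cytoplasm-bait
samples: 36 comparisons.  Per comparison, every protein's enrichment is
computed and curated control proteins anchor a ROC scan: at each attained
enrichment $t$, TPR is the fraction of detected lumen controls with
$e \ge t$ and FPR the analogous fraction of cytoplasm controls; the cutoff
maximizes TPR $-$ FPR.  A protein positive ($e \ge$ cutoff) in at least 35
of 36 comparisons is called lumen.  A reverse pass (inverted ratios,
control roles swapped) calls cytoplasm; proteins passing neither, or
pathologically both, are unknown.  TPR/FPR denominators count only
controls detected in the dataset.

The lumen and P-OM analyses are merged with the original precedence
table: (target, target) is dual; a single target wins over reference or
unknown; (reference, reference) is cytoplasm; everything else is unknown.
The five final categories partition the proteome.

**Tie-breaking at the ROC optimum.**  With well-separated control
distributions, every attained threshold in the gap attains the maximal
TPR $-$ FPR, and the choice within that plateau matters.  Anchoring at the
*largest* maximizer (the weakest TP control's enrichment) makes a
non-control compartment protein — statistically exchangeable with the
controls — fall below the cutoff with probability $1/(n_{TP}+1)$ per
comparison, which caps the 35-of-36 vote's recall at roughly 77-93%
*regardless of effect size or noise*: a pure artifact of control-list
size.  `apexloc` therefore defaults to the *smallest* attained maximizer
(the sensitive end of the plateau); specificity is still controlled by the
FPR term and the near-unanimous vote.  The stringent rule remains
available as `tie_break = "largest"`.

## The synthetic world

The generator emulates the study's design: 6 baits (2 per compartment),
3 replicates, and a proteome with 100 lumen, 100 P-OM, 20 dual and 800
cytoplasmic proteins by default.  Protein $p$'s intensity in sample $s$ is

$$ x_{ps} = \exp\big(\beta_p + (\mu + \delta_p)\,\mathbb{1}[\text{match}]
  + \lambda (\mu + \delta_p)\,\mathbb{1}[\text{leak}] + s_s +
  \varepsilon_{ps}\big) $$

with baseline $\beta_p \sim N(8, 1.5^2)$ (ln scale), match effect
$\mu = 4\log 2$ (a 16-fold labeling gain when the bait shares the
protein's compartment; dual proteins match both lumen and P-OM baits),
per-protein effect heterogeneity $\delta_p \sim N(0, (\log 2)^2)$
(labeling efficiency varies with distance from the bait; the study's
control-enrichment distributions span several log2 units), Tat leak
$\lambda = 0.3$ applied to cytoplasmic proteins in P-OM-bait samples
(P-OM baits carry Tat signal sequences, fold in the cytoplasm, and label
cytoplasmic proteins before translocation — reproducing the elevated
cytoplasm-periplasm sample correlation of the real data), an optional
per-sample labeling-efficiency factor $s_s$ (default off: no published
value to match), and replicate noise
$\varepsilon_{ps} \sim N(0, 0.5^2)$ (ln scale).  Control lists are drawn
from the matching compartments with the study's detected control counts
(40 lumen TP, 65 P-OM TP, 381 cytoplasm FP); dual proteins are never
controls.

Signal peptides are generated per SignalP category.  N-regions start with
M and contain a positive residue (with a terminal RR for TAT/TATLIPO);
H-region residues are drawn from an exponentially tilted distribution over
uncharged residues whose mean z1 differs between the lumen and P-OM
groups by `h_hydrophobicity_shift` (default 0.8 z1 units, a moderate
effect that the group tests detect at the study's sample sizes);
LIPO/TATLIPO sequences end in a lipobox `[LVI][ASG][GA]C` with no
C-region; SP/TAT carry an A-X-A C-region.  JPred-style predictions emit
per-residue helix probabilities increasing with hydrophobicity, mixed
toward 1 inside the H-region by `h_helix_bias`, plus nested burial tracks
at three exposure cutoffs and confidence digits encoding the state
probability.

**What a green test does not establish.**  The generator has no missing
values, no peptide-level rollup, no shared-complex covariance between
proteins, no compartment-size-dependent background, and its effect model
is a single log-normal family.  Passing recovery tests demonstrates the
classifier's correctness under these assumptions, not performance on real
spectra.  Note also that recovery of the *P-OM* compartment is intrinsically
the hardest case (the Tat leak compresses the control separation), and at
the default parameters sits only a few percent above the 95% test
threshold, so it is the first number to degrade if the generator is made
harsher.

## Signal-peptide characteristics

For each peptide and region (full, N, H, C; LIPO/TATLIPO have no
C-region), the package computes: length; counts and proportions of the 20
amino acids; GRAVY (mean Kyte-Doolittle hydropathy); molecular weight
(average residue masses minus one water per bond); isoelectric point and
net charge at pH 7, 8, 9 (Henderson-Hasselbalch over termini and side
chains with a Bjellqvist-style pKa table; terminal groups are included at
all pH values); positive (K, R; histidine excluded at neutral pH, both
documented and configurable) and negative (D, E) residue counts; mean
z-scale descriptors; and z-scale auto/cross-correlations

$$ A_{jj}(d) = \frac{1}{N-d}\sum_{i=1}^{N-d} z_j(i)\, z_j(i+d), \qquad
   C_{jk}(d) = \frac{1}{N-d}\sum_{i=1}^{N-d} z_j(i)\, z_k(i+d) $$

at lags 1-4 with raw (uncentered) values, the convention of the cited ACC
equations; a centered variant sits behind a flag because the source is
ambiguous.  "Every 4th amino acid" is read as lag 4 (its plain reading);
lag 3, the helical-period alternative, is always computed alongside.
Lags at or beyond the region length are missing, not zero.  Structural
features from the per-residue predictions: longest helix, strand and
helix-or-strand runs; counts, proportions and mean confidences per state
(missing, not 0, when a state is absent — zero-filling would bias group
tests); and burial run/count/proportion per exposure cutoff.  Region
coordinates are 1-based inclusive throughout.

## Group comparisons

Each (region, feature) pair is compared between lumen- and P-OM-localized
peptides of one signal-peptide category with a pooled-variance Student's
t-test (two-sided, df $= n_1 + n_2 - 2$; Welch behind a flag), with dual
proteins excluded by default, and significance counted at raw
$P < 0.05$ — no multiple-testing correction, mirroring the original
analysis; a Benjamini-Hochberg column is emitted alongside as a marked
extension.  Zero-variance features with equal means score $p = 1$;
features untestable in a group (fewer than 2 finite values) are flagged
and excluded from the tested count.  Cross-species comparisons transfer
the reference species' localization calls through best-reciprocal-hit
homolog pairs and repeat the scan per species; species whose lumen and
periplasm are one physical compartment can be flagged so the expected
null is documented.

Because many characteristics are near-duplicates (counts vs proportions,
GRAVY vs mean z1), significance events are correlated across features;
the null-calibration test therefore checks the pooled significant
fraction over 20 seeds against the binomial envelope, and its variance
sits close to that envelope's edge by construction.

## Open questions resolved here

* Loess variant: both implemented, "fast" default (above).
* ROC tie-break: smallest maximizer default (above).
* "Every 4th amino acid": lag 4, with lag 3 computed too.
* Charges at pH 7/8/9 include terminal groups.
* Proteins at the cutoff: "above the cutoff" means $\ge$, consistent with
  the $\ge$ in the TPR definition.
* Missing feature values are dropped per group in the t-tests, not
  zero-filled.

## Limitations

Peptide-level quantification, missing-value mechanisms, and the
machine-learning localization variant of the original study are out of
scope.  The classifier assumes exactly two baits per compartment only
through the `vote_config` defaults (35/36); other designs work by
adjusting it.  Signal-peptide and secondary-structure prediction are
consumed, never performed.
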