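---
title: "Methods: detection, preprocessing and simulation for sorted-cell metabolomics"
author: "facsmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, preprocessing and simulation for sorted-cell metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facsmet)
```

# The problem

Targeted LC-MS metabolomics normally needs $10^5$–$10^7$ cells per sample.
Rare populations purified by fluorescence-activated cell sorting (FACS) —
hematopoietic stem cells, tissue-resident mast cells — yield a few thousand
cells at best. At that scale the dominant analytical questions shift from
quantification to *attribution*: which part of a peak area comes from the
cells, and which from the droplet of sheath fluid, the suspension buffer,
the extraction solvent, or the instrument itself?

`facsmet` implements the data-analysis half of a sorted-cell metabolomics
workflow:

1. a **droplet model** for the physical composition of a sorted sample;
2. **peak-table I/O** with explicit missingness;
3. a **preprocessing chain** (low-detection filter, best-matched
   internal-standard normalization, half-minimum imputation, z-score
   outlier removal);
4. **detection above background** against sorted-debris blanks over an
   event-count series, with a chained detection rule;
5. **differential analyses** (blank-gated volcano comparisons, buffer
   effect deltas, PCA profiles, cross-study log-ratio correlation);
6. a **synthetic-data generator** with ground truth, so every stage is
   testable without instrument data.

# The droplet model

Each sorted event is one charged droplet (nominally 1 nL, consistent with a
124 µm diameter) containing roughly a 1000:1 ratio of sheath fluid to
sample-stream core. A prototypic cell is a 10 µm sphere
($\pi d^3/6 \approx 5.2\times10^{-4}$ nL). The model composes, per droplet
and per well:

```{r droplet}
ct <- compose_sample(droplet_model(n_events = 5000))
ct
```

Two conventions coexist for the suspension-buffer volume: the droplet's
sample core minus the cell volume (default; reproduces the printed
composition table), or the spherical shell between a 12 µm suspension
sphere and the cell. Per-droplet volumes are reported raw and rounded to
`rounding_decimals` (default 4) decimal places; printed in-sample values
are rounded-per-droplet × events, which is how the bench-side table is
constructed (0.0005 × 5000 = 2.5 nL). Cells contribute
`r sprintf("%.4f%%", 100 * attr(ct, "cell_volume_fraction"))` of a
5000-event sample — below the 0.01% worry threshold.

The make-up scheme keeps the organic:aqueous ratio constant when fewer
events are sorted into the same 25 µL of extraction solution: the missing
droplet volume is replaced by pipetted sheath fluid.

```{r makeup}
makeup_volume(c(5000, 4000, 3000, 2000, 1000, 500, 100))
```

`total_uL` is the *pipetted* volume (extraction + make-up), matching the
pipetting scheme; `final_uL` additionally counts sorted droplets and is
constant by construction.

# Preprocessing

The chain mirrors standard practice for targeted peak tables:

* **Low-detection filter** — metabolites observed (non-missing) in fewer
  than 10 samples are removed, before any transformation.
* **Best-matched internal-standard normalization** — each metabolite $m$
  is assigned the internal standard $i^\*$ minimizing the coefficient of
  variation of the per-sample ratio $m/i$ over samples where both are
  present; the normalized value is $(m/i^\*)\cdot\mathrm{median}(i^\*)$,
  which removes the per-sample technical factor while keeping intensity
  units (so half-minimum imputation stays meaningful). The matching
  criterion is the standard CV-minimization reading of "best-matched";
  ties break deterministically by standard order. Standards missing in
  more than half the samples are excluded from candidacy.
* **Half-minimum imputation** — a missing value becomes half the smallest
  observed value of its metabolite. Left-censoring at the limit of
  detection is the dominant missingness mechanism in targeted MS, so a
  value below the observed minimum is the right order of magnitude.
* **z-score outlier removal** — each sorted sample is summarised by the
  median over metabolites of intensity/event-count ("event-number
  normalized" data), compared within its (cell type × role × event count)
  group, and removed when $|z| > 3$.

Two decisions here deserve their arithmetic:

**Leave-one-out z.** A plain within-group z-score with $n$ group members
is bounded by $(n-1)/\sqrt{n}$ — about 2.47 for the typical $n = 8$ — so a
threshold of 3 could never remove anything. The implementation therefore
compares each sample against the mean and standard deviation of the
*remaining* group members. The sd = 0 guard is kept: a sample identical to
its peers has $z = 0$ regardless.

**Outlier statistic before internal-standard normalization.** A
whole-sample technical outlier multiplies biological signals and internal
standards alike; ratio normalization cancels it exactly
($10m/10i = m/i$). The z statistic is therefore computed on
event-number-normalized *raw* intensities (after filtering), and the
flagged samples are removed from the normalized, imputed table. The
filter stages themselves remain pure functions and can be reordered by
callers who disagree.

# Detection above background

Sorted-debris samples — droplets with near-zero scatter, sorted in equal
number — carry every contamination a cell sample carries, except the cell.
A metabolite is *significant* at an event level when its cell intensities
exceed the debris intensities by a one-sided Wilcoxon rank-sum test, with
Benjamini–Hochberg control at FDR < 0.05 across the metabolites of that
level (internal standards are excluded from the tested family but reported
alongside). It is *detected* under the chained rule: detection at the
highest level is plain significance; at any lower level the metabolite
must also be detected at the next higher level. The chain is recursive, so
detected sets are nested upward and detection counts are non-decreasing in
the event count — a theorem about the rule, asserted on every run.

Numerical choices:

* exact permutation p-values (mid-ranks, exhaustive enumeration over group
  assignments) for combined $n \le 12$; a tie-corrected normal
  approximation with continuity correction above that;
* p-values are clamped to $(0, 1]$; a fully tied comparison yields $p = 1$;
* the BH family is the set of tested metabolites within one event level
  (the per-level comparison is the unit of inference); per-cell-type
  detection uses the same convention within each cell type;
* "signed rank" phrasing in figure-caption style descriptions of this
  procedure is read as the unpaired rank-sum (Mann–Whitney U) test — the
  cells-vs-debris design has no pairing.

# Differential analyses

The volcano comparison first gates on "above blank in both groups" (the
same one-sided rank-sum + BH machinery, applied per group against the
blank-role samples), then reports log2 fold change from the ratio of group
means and a two-sided Welch t-test p-value. A hit needs
$|\log_2 FC| > 1$ (a fold change beyond ±2) and $p < 0.05$; a BH-adjusted
column over the included metabolites is emitted as well, since it is not
stated whether such plots are multiplicity-corrected beyond the gate.
Fold change uses arithmetic means by default (median by option).

PCA log10-transforms and autoscales each metabolite before the
eigendecomposition; the buffer-effect module reports per-metabolite
retention-time shifts and log2 intensity ratios against a water reference;
cross-study agreement is a Pearson correlation of signed log ratios over
the metabolites common to both studies (externally published comparator
data is typically only available auto-scaled, which the module does not
attempt to undo).

# The synthetic world

The generator (`generate_sorting_series()`, `generate_treatment_pair()`,
`generate_celltype_panel()`) emulates the statistical structure the
analyses assume. The expected intensity of sample $s$, metabolite $m$ is

$$\mu_{sm} = \bigl(E_s\, c_m\, \mathbf{1}[s\text{ is cell}] + b_m\bigr)
            \cdot g_s \cdot \varepsilon_{sm}$$

with $E_s$ the sorted event count, $c_m$ the per-cell content, $b_m$ the
event-independent extracellular background, $g_s$ a log-normal per-sample
technical factor and $\varepsilon_{sm}$ log-normal measurement noise.
Metabolite classes: *intracellular* ($b_m = 0$; the 4-aminobutyric-acid
pattern), *extracellular* ($c_m = 0$; the spiked-standard pattern —
identical in cells and debris), *mixed* (both; the S-adenosyl-methionine
pattern), and *internal standards* (a constant spiked amount times
$g_s \varepsilon$, which is exactly what makes best-matched normalization
identifiable). Whole-sample outliers multiply every intensity of a sample
by `outlier_magnitude`, giving the z-filter known positives.

Noise is multiplicative log-normal because peak areas are positive and
heteroscedastic; additive Gaussian noise would permit negative areas.

**Defaults and what they mean.** Event levels 100–5000 and $n = 8$
replicates per group follow the reference sorting design. The remaining
defaults are free parameters chosen once as field-realistic values:
40 metabolites with 2 internal standards; class fractions 50/20/30%
(intracellular/extracellular/mixed); per-cell content 0.5–20 units/cell;
backgrounds 500–20,000 units; $\sigma_\text{measurement} = 0.25$,
$\sigma_\text{technical} = 0.15$ (25% and 15% CV, the upper range of
routine MRM variability at low analyte amounts); outlier rate 2% at 10×;
`lod_quantile` 0.15. No synthetic configuration is claimed to reproduce
any empirical detection count from real instrument data.

**Censoring model.** Purely intracellular metabolites traverse the limit
of detection along the dilution series, so their LOD is the
`lod_quantile` quantile of the noise-free cell-signal series (on a grid
that starts at 0, so `lod_quantile = 0` censors nothing). This censors
debris (expected signal 0) and low-event cell samples — which is what
creates detection curves that rise with the event count. Metabolites with
a flat signal component (extracellular, mixed, internal standards) are by
construction observable in blanks, so their LOD is the same *fraction of*
that flat level and effectively never censors; an early variant that
applied the series-quantile rule to standards censored half their values
and broke normalization, which is why the rule is class-aware. Censoring
is strict (`< lod`), so a noise-free flat signal exactly at its LOD is
retained. Censored values are recorded as missing, never zero, matching
the imputation stage's contract.

**What a green test does not establish.** The generator has no
chromatography: no retention-time drift, no co-elution, no
integration error, no between-batch drift, no correlation structure
between metabolites beyond the shared sample factors. Detection counts
and hit counts on synthetic data validate the *machinery* (test
calibration, chain logic, recovery of injected effects), not any claim
about real biological samples.

# Geometry of the cell-type panel PCA

In the panel design, half of all samples are matched debris, and every
metabolite "detected in all cell types" is coherently higher in cells than
in debris. After autoscaling, that common offset is a single strong
direction, so the first principal component is necessarily the
cells-vs-debris axis and the debris centroid cannot sit nearest the origin
in the PC1–PC2 plane of this model. On the *type-contrast* components
(PC2–PC3), debris — being low on everything — projects near zero while
cell types occupy the extremes: the familiar "background in the middle,
cell types separated" picture. The test suite asserts cell-type
silhouette > 0 on PC1–PC2 and debris centrality on PC2–PC3, and this held
across all seeds tried before one was frozen.

# Fold-change recovery and when normalization helps

Best-matched normalization removes the per-sample technical factor at the
cost of adding the matched standard's own measurement noise. With the
default synthetic world ($\sigma_\text{tech} = 0.15 <
\sigma_\text{meas} = 0.25$) that trade is unfavourable for *estimating*
fold changes: the log2 estimator sd grows from ≈ 0.21 (raw group means) to
≈ 0.26 (normalized), enough to push ±0.5 recovery below 95%. The recovery
check in the acceptance suite therefore runs the pipeline without
internal-standard normalization, which is also how the generator-level
recovery contract is defined. On real data, where slowly drifting
technical factors typically dominate measurement noise, the trade goes the
other way — that is the regime normalization exists for, and the test
suite separately verifies that normalization reduces within-group CV when
$\sigma_\text{tech}$ dominates.

# Degenerate inputs and edge behaviour

* Tables with zero samples or metabolites round-trip through I/O.
* A metabolite with no observed values cannot be imputed and errors by
  name (it should have been filtered).
* z-filter groups smaller than 3 are skipped with a warning; blank and
  medium samples (no event count) are never z-filtered.
* A cell larger than the droplet's sample core is an error, not a clipped
  value.
* The make-up scheme refuses event counts above the reference (it only
  tops up).
* `detect_above_background()` requires complete data and at least one
  event level with both roles; internal standards never enter a BH family.

# Known limitations

* The rank-sum normal approximation is used above combined $n = 12$; at
  $n = 16$ (the default 8 vs 8) its one-sided p differs from the exact
  tail by well under the decision threshold in our checks, but extremely
  tied data near $\alpha$ could in principle flip a call.
* The outlier filter assumes whole-sample multiplicative outliers;
  metabolite-specific corruption (a single mis-integrated peak) is not
  modelled and would pass.
* The droplet model is bookkeeping, not fluid dynamics: sort efficiency,
  doublets and satellite droplets are out of scope.
* Cross-study correlation takes externally computed ratio maps as given;
  auto-scaling in a comparator study changes ratio magnitudes, and no
  attempt is made to undo it.
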