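---
title: "Cross-tissue calibration of DNA methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue calibration of DNA methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcal)
```

## The problem

Large epidemiological studies of DNA methylation almost always measure an
easy-to-access surrogate tissue — peripheral blood leukocytes (PBL), or
EBV-transformed lymphoblastoid cell lines — while the tissue that matters
biologically (heart atrium, artery, brain) is out of reach at scale.
Methylation is largely conserved across tissues, so the surrogate is
informative; but a substantial minority of CpG sites carry *consistent*
cross-tissue differences: a site that is more methylated in atrium than in
blood in one person tends to be more methylated, by a similar amount, in
every person. A relationship that is stable across individuals can be
learned from a paired training study and then applied to surrogate-only
data.

methcal implements that recalibration. For each CpG probe $j$, with paired
training betas $x_{ij}$ (surrogate) and $y_{ij}$ (target) over samples
$i = 1, \dots, n$:

* **LM** — ordinary least squares
  $y_{ij} = a_j + b_j x_{ij} + e_{ij}$, predicting
  $\hat y_j = \hat a_j + \hat b_j x_j$ for a new sample. Closed form:
  $\hat b_j = \mathrm{cov}(x_j, y_j) / \mathrm{var}(x_j)$.
* **SVR** — $\varepsilon$-insensitive support-vector regression with a
  radial-basis-function kernel, at the reference defaults:
  $\varepsilon = 0.1$, cost $C = 1$, kernel width
  $\gamma = 1/\#\text{predictors}$, with predictor and response
  standardized before fitting and the transform inverted at prediction.

Accuracy is always reported as the squared Pearson correlation $R^2$ and
the mean absolute error (MAE), per sample (across probes) and per probe
(across samples), estimated by leave-one-sample-out or — when samples are
related — leave-one-family-out cross-validation, so training and testing
partitions are completely independent.

## Why both metrics, and why per sample *and* per probe

$R^2$ here is squared correlation, not $1 - \mathrm{SSE}/\mathrm{SST}$. A
prediction shifted by a constant keeps $R^2 = 1$; MAE reports the shift.
The two levels answer different questions. Per-sample $R^2$ across probes
is dominated by between-probe structure — exactly what per-probe offsets
corrupt and calibration repairs, so this is where recalibration shows its
large gains. Per-probe $R^2$ across samples is invariant to any affine
per-probe recalibration (correlation is affine-invariant), so a
single-probe linear model cannot raise it except through shared
*nonlinearity*; see "Boundary saturation" below. Per-probe MAE, by
contrast, improves directly, and for well-calibrated probes approaches the
Gaussian noise floor $\sigma\sqrt{2/\pi}$.

## The two engines

The linear engine extrapolates: with a steep fitted slope and a query near
the edge of the beta scale, predictions can leave $[0, 1]$. This is a real,
documented behavior — the package counts such predictions and leaves them
unclamped by default (`clamp = TRUE` truncates). The support-vector engine
is constrained to the range of its training targets
(`clamp_to_range = TRUE` by default), which enforces the range property
that distinguishes it from the linear engine; the RBF expansion itself
already flattens outside the training support, and the explicit constraint
makes the guarantee unconditional.

The $\varepsilon$-tube has a quiet cost: with standardized responses,
deviations up to $0.1\,\mathrm{sd}(y)$ from the conditional mean are not
penalized, so at the probe level the SVR engine gives away a few points of
$R^2$ relative to OLS on cleanly linear probes. At the sample level, where
between-probe structure dominates, the two engines are nearly
indistinguishable. This trade is inherent to the pinned "default
parameters" and is deliberately not tuned away.

## Boundary saturation and clamped calibration

Beta values saturate at the scale boundaries. In the generator this is
modeled by truncating to $[0.001,\, 0.999]$ (the beta formula
$M/(M+U+100)$ itself never reaches the bounds); in real data the same
compression appears near 0 and 1. Saturation is *shared* between the
measured target and a calibrated value constrained to $[0, 1]$, and that
shared nonlinearity is the one mechanism by which even probe-level $R^2$
can improve over the raw surrogate. For accuracy comparisons the package
therefore treats the clamped predictions as "calibrated methylation" — a
calibrated beta is, by definition, a beta. Unclamped linear output remains
the default of `predict_matrix()` so the out-of-range phenomenon stays
visible.

## Preprocessing chain

`normalize_27k()` quantile-normalizes all methylated and unmethylated
probe intensities together across samples, recomputes
$\beta = M/(M + U + 100)$, and masks cells with detection $p > 0.05$.
`normalize_450k()` is a simplified two-step equivalent of the usual 450k
pipeline: mask cells with detection $p > 0.01$ or fewer than 3 beads, drop
samples with more than 20% missing probes (all inequalities strict, as the
QC phrasing dictates), remove SNP-flagged probes (flags are taken from the
annotation; no variant lookup), quantile-normalize betas across samples,
then align Infinium II betas onto the Infinium I distribution within each
functional category by a monotone quantile map with mid-rank plotting
positions (so the type II median lands exactly on the type I median).
Background and color-bias correction are accepted as pre-applied or
skipped; the returned log records this. Quantile normalization delegates
to `limma::normalizeQuantiles`, which matches the rank-mean contract
exactly on complete data and interpolates per-rank means under
missingness.

The extreme-probe filter removes probes whose pooled minimum beta (across
all supplied subjects and tissues) exceeds 0.9 or whose pooled maximum is
below 0.1 — constitutively methylated/unmethylated sites that inflate
between-tissue correlations; (0.8, 0.2) is the stricter level, and its
retention set is always nested inside the looser one.

## Missing data policy

Fitting uses pairwise-complete observations per probe; probes with fewer
than 3 usable pairs (configurable) are flagged, not dropped. Metrics use
pairwise-complete entries with reason codes for undefined cells. Clustering
drops incomplete probes rather than imputing — the smallest-assumption
choice; imputation is out of scope.

## The synthetic generator

`generate_pair()` draws a paired study with the structure the method
assumes, and records the generating truth per probe. Its defaults *are*
the study conditions used throughout the tests:

* 40 individuals in 20 families of two (the scale of a family-based
  paired-tissue study); family membership enters as a shared random
  intercept carrying 30% of each probe's between-individual variance,
  giving leave-one-family-out cross-validation something real to protect
  against.
* 2000 probes: 20% constitutively methylated (means near 0.95), 20%
  constitutively unmethylated (near 0.05) — together roughly the share the
  (0.9, 0.1) filter targets — 15% offset probes with a consistent
  cross-tissue mean shift of at least 0.1 (real tissue pairs put the
  "differing CpG" share at 14–26%), the rest conserved.
* The target is a per-probe affine transform of the surrogate pivoting at
  the probe mean, $y = \mu_y + b(x - \mu_x) + e$: tissue differences are
  local mean shifts, and pivoting at zero would make every high-mean,
  high-slope probe fully saturated, which arrays do not show. Slopes are
  $N(1, 0.35)$ — cross-tissue scale relationships vary widely around
  proportionality — and 10% of non-constitutive probes are *uncoupled*
  (slope near 0): tissue-autonomous CpGs whose surrogate variation carries
  no target information, the regime in which a raw surrogate actively
  misleads.
* Technical noise SD 0.02 on the target (the scale of array replicate
  noise); per-probe between-individual SD uniform on (0.03, 0.15) for
  non-constitutive probes.
* A binary outcome (30% cases) shifts the target tissue only, at 5% of
  non-constitutive probes with effects $N(0, 0.08)$.

What the generator does **not** emulate: probe-level genomic positions and
spatial correlation, SNP genotypes under probes, batch and cell-composition
effects, and non-affine cross-tissue relationships beyond boundary
saturation. Passing tests therefore demonstrate correctness of the
machinery and the qualitative phenomena, not performance on any real
tissue pair.

## Validation experiment designs

Each experiment fixes its configuration for an identifiable reason:

* **Parameter recovery** uses a configuration without constitutive probes
  and assesses slope recovery only on probes whose cells were never
  truncated. A near-constant predictor makes the slope unidentifiable
  (its standard error is $\sigma/(\tau\sqrt n)$, exploding as the probe SD
  $\tau \to 0$), and a truncated probe's least-squares estimand is not the
  generating slope — neither failure says anything about the fitter.
* **Calibration versus raw** compares mean per-sample $R^2$ over probes
  with target SD > 0.1 — variable probes, where prediction is meaningful —
  between the raw surrogate and the cross-validated calibrated values of
  both engines, plus the probe-level comparison for the clamped linear
  engine (the boundary-saturation effect).
* **Noise-floor MAE** uses an interior configuration (probe means in
  (0.25, 0.75), no offsets) and the linear engine, because the
  $\varepsilon$-tube biases SVR away from the $\sigma\sqrt{2/\pi}$ limit
  by construction and truncation distorts absolute errors in both
  directions.
* **Sample size** trains on random subsets of 39 samples (sizes 3–39, 10
  replicates, each grid cell independently seeded by
  (seed, size, replicate)) and predicts 15 independent samples from the
  same population, 300 probes.
* **Downstream utility** emulates a distantly related tissue pair (30%
  uncoupled probes) with an outcome signature in the target only, trains
  the calibration on 40 independent samples and applies it to a 20-sample
  study set — the cross-study workflow. Fitting on the study samples
  themselves would inflate the clustering comparison by memorization.
  Because tree comparisons at 20 samples are stochastic, the dendrogram
  property (calibrated tree closer to the target tree than the raw
  surrogate tree, by cophenetic correlation) is asserted on means over a
  small seed grid.

Problem sizes throughout (2000 probes for the main study, 300–800 for the
stochastic experiments) are chosen so each experiment estimates its
quantity stably while the whole suite stays comfortably interactive.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere in QC, matching the conventional
  phrasing; a cell at exactly the detection threshold is retained.
* Bin convention for the density diagnostic: left-closed, right-open bins
  on $[0, 1)$, last bin closed at 1; a value on an edge belongs to the bin
  it opens.
* Constant predictors fall back to intercept-only models; constant SVR
  targets yield flagged constant predictors; both predict sensibly rather
  than erroring mid-pipeline.
* Multi-probe predictor selection: the same-id probe is always first,
  then the $K-1$ probes with largest $|r|$ against the target vector in
  training data, ties broken lexicographically. This selection rule is
  this package's own design choice (the extension itself is standard; a
  published selection rule is not). With $K = 1$ the coefficients equal
  the single-probe linear model exactly (the implementation delegates).
  Collinear predictors are dropped with a warning and the model refit.
* Clustering sorts samples lexicographically before `hclust`, making the
  merge order deterministic under tied distances; `ward` maps to Ward's D2.
* Model containers are JSON; support-vector predictors serialize their RBF
  kernel expansion (support vectors, dual coefficients, $\rho$, scaling)
  and evaluate identically after a round trip.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state (`withr::with_seed`).

## Known limitations

* The probe-level $R^2$ of the SVR engine under the pinned defaults sits
  a few points below OLS on cleanly linear probes (the
  $\varepsilon$-tube cost above); no probe-level $R^2$ gain over the raw
  surrogate should be expected from SVR, and the package's claims about
  SVR improvements are at the sample level.
* The 450k chain is a documented simplification: it does not reimplement
  background or color-bias correction, nor the full published pipeline it
  abbreviates.
* The association scan fits methylation on the outcome alone, with no
  covariates and no multiple-testing procedure, mirroring the simplest
  utility analysis; covariate support is a configuration extension, off
  by default.
* Dendrogram comparisons use Euclidean distance and average linkage by
  default; these choices are conventional, not canonical, and are
  configurable.
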