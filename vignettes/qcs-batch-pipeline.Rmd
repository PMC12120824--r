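---
title: "Evaluating and correcting batch effects in MSI feature tables with QCS"
author: "msibatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and correcting batch effects in MSI feature tables with QCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msibatch)
```

## The problem

Mass-spectrometry imaging (MSI) experiments that span several slides and
days accumulate technical variation at every level: matrix spraying varies
from spot to spot, slides differ in preparation and crystallization, the ion
source drifts along the acquisition sequence, and whole days differ in
instrument state. Because biological tissue offers no internal replicate of
known composition, a fabricated quality-control standard (QCS) — here a
gelatin-embedded drug standard (propranolol) with its isotope-labelled
internal standard (propranolol-d7) co-spotted around every tissue section —
turns these nuisance processes into measurable quantities.

`msibatch` operates on the region-level feature tables exported after
spectral preprocessing (observations = QCS spots or tissue sections,
columns = m/z features) and provides the two halves of a QCS-driven
workflow:

* **Part 1 (evaluation)**: intraday/interday coefficient of variation (CV%)
  of the QCS analyte, Kruskal–Wallis batch tests, robust outlier-slide
  flags, and acquisition-drift profiles.
* **Part 2 (correction + re-evaluation)**: TIC and internal-standard
  normalization, native empirical-Bayes location-scale correction
  (ComBat-type) and wavelet/ICA drift correction (WaveICA-type), evaluated
  before and after correction through CV%, PCA score-space proximity and
  PLS-DA VIP feature robustness.

## The working model

All corrections in the package assume *multiplicative* technical structure,
because the two normalizations that demonstrably work on QCS data — TIC and
internal-standard ratios — are ratio corrections, and ratios only cancel
multiplicative factors. On the log scale the package's generative picture of
an abundance $x_{of}$ for observation $o$ and feature $f$ is

$$\log x_{of} = \mu_{g(o),f} + b_{s(o)} + c_{d(o)} + v_o +
\beta_f \cdot \mathrm{order}(o) + u_{s(o)} + \varepsilon_{of},$$

with slide effects $b_s$, day effects $c_d$, per-observation spray/ion-
suppression factors $v_o$, feature-specific acquisition drift $\beta_f$,
designated outlier-slide attenuations $u_s$, and residual noise
$\varepsilon$. The analyte and its internal standard share every
observation-level term, so their ratio retains only residual noise — the
mechanism by which IS normalization collapses QCS variation to near the
residual floor.

## Quality metrics

`cvPercent` is $100\,\mathrm{sd}(x)/\mathrm{mean}(x)$ with the sample
standard deviation. Intraday CV pools all of a day's QCS spots; interday CV
pools the whole experiment (pooling, rather than averaging daily CVs,
matches how a single interday figure is conventionally reported). 15% is
the usual bioanalytical ceiling for analyte variability; IS-normalized QCS
data should sit below it.

`kruskalWallisBatchTest` wraps the rank-based test (`stats::kruskal.test`)
with one added policy: if every value is identical the tie correction is
0/0, and the package defines $H = 0$, $p = 1$ — total ties carry no
evidence of batch differences.

`detectOutlierSlides` scores each slide's median QCS analyte level (log
scale, since slide effects are multiplicative) with a modified z-score:
deviation over $1.4826 \cdot \mathrm{MAD}$, flagged above $k = 3.5$. Two
refinements matter at the cohort sizes of slide experiments (~18 slides):
slide medians are first centred on their day's median, so a between-day
shift cannot inflate the MAD and mask a within-day sprayer failure, and the
centre and MAD for each slide are computed from the *other* slides
(leave-one-out), so a strong outlier does not dilute its own score. With 18
slides the leave-one-out score distribution is heavy-tailed and at
$k = 3.5$ occasionally flags a clean slide; flags are therefore advisory
(Part 1 warns, it does not abort) and $k$ is configurable.

## Correction methods

Both correction methods are applied unsupervised — no tissue-group
covariates — to the combined QCS + tissue matrix, so that QC standards and
samples are processed identically. Both operate on $\log(x + \epsilon)$
with $\epsilon$ = half the smallest positive intensity in the table, and
back-transform afterwards; this follows the multiplicative working model
above.

**ComBat-type empirical Bayes.** Per feature, batch locations and scales
are estimated on standardized data, shrunk across features through a normal
prior on locations and an inverse-gamma prior on scales (method-of-moments
hyperparameters), iterated to convergence (max absolute change $<10^{-4}$,
cap 100 iterations), and removed. Zero-variance features cannot be
standardized and pass through unchanged with a log entry. A single-batch
table reduces to a standardize/restore round trip. The implementation is
cross-checked in the test suite against an independent reference
implementation (`sva::ComBat`) to $10^{-5}$ on the log scale.

**WaveICA-type wavelet/ICA.** Each feature's series along the global
measurement order is decomposed with a maximal-overlap discrete wavelet
transform (MODWT: shift-invariant, defined for any series length, exactly
invertible, energy-preserving; implemented in-package with Haar and D4
filters). Per wavelet level, deflation-mode FastICA (logcosh negentropy,
fixed seed) extracts $K = \min(20, n-1, p)$ components; each component's
score vector is scored by the $R^2$ of a regression on batch dummies (a
sign- and order-invariant statistic, deliberately robust to ICA's sign
indeterminacy), and components with $R^2 \ge 0.05$ are subtracted before
inverting the transform. With the threshold above 1 nothing is removed and
the reconstruction is exact to rounding, which the tests assert at
$10^{-8}$.

A pluggable registry (`registerCorrectionMethod`) lets externally corrected
tables (for example from a deep-learning corrector trained elsewhere) enter
the same evaluation machinery; only the two methods above ship natively.

## Multivariate evaluation

PCA is always fit with centering and unit-variance scaling on the combined
table; zero-variance features are dropped with a message, and component
signs follow a deterministic convention (largest-magnitude loading
positive). Proximity metrics use exactly PC1–PC2: the QCS proximity of a
method is the mean distance of QCS spots from their common centroid; tissue
structure is summarized by mean within-group centroid distance and mean
pairwise between-group centroid distance. For IS-normalized tables the
full-feature PCA proximity is reported as `NA` — IS normalization
transforms only the declared analyte, so a full-feature distance would not
measure the normalization.

PLS-DA uses NIPALS PLS2 on autoscaled features against a centred one-hot
group response, with the component count defaulting to (groups − 1), capped
at rank. VIP scores follow the standard weighted-explained-variance formula,
which guarantees mean squared VIP of exactly 1; features above 1.2 count as
distinctive, and the robustness comparison crosses selections across the
method grid into a robust set (selected everywhere) and a dropped set
(selected only without correction).

## What the generator emulates — and what it does not

`generateBatchExperiment` draws the full study design: 3 days × 6 slides,
3 tissue groups × 6 replicate slides balanced across days, 6 QCS spots per
slide split before/after 2 tissue sections, 200 tissue features of which
30% are "lipid-like" (m/z > 700) with negative drift slopes drawn from
$[-0.004, -0.002]$ per order unit, one designated sprayer-failure slide
(S04, attenuated by $-1.5$ log units, sitting in day 1), and slide order
randomized within day.

Default magnitudes (log-sd 0.3 per spot, 0.2 per slide, 0.25 per day, 0.08
residual) are *calibrations*, not estimates: they were chosen once so the
simulated experiment reproduces the qualitative QCS regime of a real batch
study — raw interday CV in the ~40–65% range with the worst day first,
IS-ratio CV near 11–13% (under the 15% ceiling), the outlier slide
reliably flaggable, and every corrected variant below raw. Day effects are
modelled as a fixed zero-sum contrast of magnitude `sigma_day` ascending
from day 1 rather than as independent draws: days in a serial experiment
differ systematically (instrument and cleaning state), and with only three
days independent draws would, on a sizeable fraction of runs, produce no
day structure at all — a regime the study this emulates did not exhibit.
The low-response day is day 1, which also carries the designated outlier
slide, mirroring the common failure pattern where the worst day is the one
with preparation problems.

The generator does **not** simulate spectra, peak shapes, pixel images,
missing features, or censoring at the detection limit; observations are
region-level abundances only. Passing tests therefore demonstrate that the
statistical machinery behaves correctly under the stated multiplicative
model — not that any particular instrument's artifacts are fully captured.

## Numerical choices and degenerate inputs

* CSV interchange uses shortest round-trip decimal representation, so
  write-then-read is bit-exact; the reader rejects (with located errors)
  missing values, negatives, duplicate ids and unknown region labels.
* TIC refuses zero-sum observations, IS refuses zero IS intensities, and
  z-scoring refuses zero spread — each names the offending observations or
  features rather than emitting NaN.
* ComBat guards the method-of-moments scale prior against zero across-
  feature variance, and falls back to pass-through for single batches and
  constant features.
* The outlier rule falls back to exact-inequality flagging when the MAD is
  zero (all reference slides identical).
* ICA initialisation uses a fixed recorded seed, and the caller's RNG state
  is saved and restored around every internal use of randomness, so library
  calls never perturb user code.

## Known limitations

* **Step-like batch boundaries and WaveICA.** A sharp day-aligned step is a
  binary direction in observation space, and deflation ICA splits such a
  direction across several components at realistic sample sizes (confirmed
  against an independent FastICA implementation). Thresholding per-component
  batch $R^2$ then removes the step only partially — in simulation roughly
  half to two-thirds of an injected day gap. Smooth order-dependent drift,
  the method's designed target, is handled much better; the tests assert
  the honest partial-removal behaviour.
* **ComBat and within-batch anomalies.** Full location-scale ComBat pools
  per-batch variances; a sprayer-failure slide inflates its day's variance
  estimate, and the rescaling can push variance into clean days. Under the
  default conditions day-shift removal dominates and every corrected
  variant still lands below raw, but the margin shrinks when day structure
  is weak.
* **Outlier-rule specificity.** See above; flags are advisory.
* **IS scope.** IS normalization transforms the declared analyte only; the
  package deliberately does not ratio endogenous tissue features against
  the standard.

## Problem sizes used by the tests

The packaged checks run the default 144-observation × 202-feature design;
parameter-recovery and efficacy properties are verified across 20 simulated
replicates, the large-sample ComBat oracles use two batches of 200
observations, and the closed-form CV limit is additionally checked at 540
QCS spots. The full suite and the acceptance script each complete in a few
minutes on one CPU.

## A minimal session

```{r example, eval = FALSE}
sim <- generateBatchExperiment(simulationConfig(), seed = 1)
part1 <- runPart1(sim$table)          # evaluation; advisory outlier flags
report <- runPart2(sim$table)         # correction grid + re-evaluation
report
```
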