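---
title: "Motion synchrony analysis and diagnostic classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion synchrony analysis and diagnostic classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The scientific problem

Autistic and non-autistic interactants differ, on average, in how tightly
their movements align during conversation.  `dyadsync` implements a complete
pipeline for testing whether that difference carries diagnostic signal in
videotaped patient--clinician interviews: movement is quantified per video
frame by motion energy analysis (MEA), interpersonal alignment by windowed
cross-lagged correlation, each dyad is reduced to a fixed vector of
summary-statistic features, and a linear support vector machine (SVM) embedded
in a repeated nested stratified cross-validation (CV) estimates how well
diagnostic group membership can be predicted from those features alone.
Because clinical videos cannot be redistributed, the package ships a
synthetic dyad generator that reproduces the statistical structure the
pipeline assumes, so every stage is testable end to end.

## Motion energy

Motion energy of a frame transition is the *count* of pixels inside a region
of interest (ROI) whose absolute gray-level change exceeds a threshold
(default 8 gray levels, strict inequality).  Four ROIs are used: head and
upper body of each interactant.  A count, rather than a summed magnitude,
is used because the definition is robust to lighting gain and because the
downstream standard-deviation scaling removes the unit in either case.
Color frames are converted to gray with Rec. 601 luma weights
(0.299, 0.587, 0.114).

*Movement quantity* is the fraction of frame transitions with nonzero
motion energy.  The natural denominator is the number of transitions
(`nframes - 1`); dividing by the frame count instead is exposed as an
option (`denominator = "frames"`) since verbal definitions of this measure
are ambiguous about the off-by-one.  At interview length the difference is
negligible.

## Synchrony

Each series is scaled by its standard deviation and smoothed with a 0.5 s
centered moving average whose window shrinks at the series edges (no
invented padding values; a trailing window is the documented alternative
and changes nothing material at interview length).  Scaling requires
nonzero variance; a constant series is a degenerate input and raises an
error rather than propagating NaNs.

Interpersonal synchrony is the windowed cross-lagged correlation: Pearson
correlations between 60 s segments of the two series at lags from -5 s to
+5 s in 1 s increments, repeated every 30 s.  Intrapersonal head--body
coordination uses 30 s windows, +-5 s lags and 15 s steps.  Design choices:

* **Lag increment.** 1 s, the convention of the established MEA tooling;
  only the +-5 s range is externally constrained.  Configurable.
* **Seconds to samples.** `round(sec * fps)`; at 29.95 frames per second
  every second-valued parameter would otherwise give fractional spans.
* **Window coverage.** A window enters the grid only if *every* lag on the
  grid stays inside the series; partial windows are dropped entirely so
  that all rows of the matrix average over the same lag support, avoiding
  partial-window bias at the recording edges.
* **Fisher transform.** Entries are `|atanh(r)|` with `r` clipped to
  `1 - 1e-7` in magnitude, so entries are finite by construction and the
  downstream pruning of non-finite features never triggers on this path
  (it remains implemented for arbitrary external feature tables).
* **Zero-variance windows.** No movement in a window makes `r` undefined;
  the entry is recorded as missing and excluded from all summaries.

The chance baseline is a set of *pseudodyads*: participant series paired
with administrator series from different dyads.  Pairing is
role-preserving -- a participant is only ever paired with an administrator
-- because the two roles have systematically different movement statistics
(interviewing vs being interviewed), and a chance baseline should not be
inflated by role mismatch.  Pairings are sampled uniformly without
replacement from all non-genuine combinations (individuals may recur).
Genuine and pseudodyad per-dyad mean synchrony are compared with Welch's
t-test; the precise test behind the published comparison is not stated, and
Welch is the safe default under unequal variances.

## Features

Each synchrony matrix is pooled across windows and lags into seven summary
statistics (min, max, mean, median, sd, skew, kurtosis).  Pooling the whole
matrix -- rather than summarizing per lag -- follows the definition of the
feature set and keeps the feature-to-sample ratio workable.  Skew is the
adjusted Fisher--Pearson sample skewness and kurtosis the moment-based
Fisher excess; the conventions are recorded in the feature-table sidecar,
and since a linear SVM is invariant to monotone rescalings of single
features the choice does not affect rank-based conclusions.  The full
vector per dyad is 7 (interpersonal head) + 7 (interpersonal body) + 7
(participant intrapersonal) + 4 (movement quantities) = 25 features; the
demographic variant appends IQ and sex (0/1 coded, mapping logged; the
in-fold 0--1 scaling makes the direction immaterial).  Age is *never* a
feature: it is carried as metadata and regressed out inside every training
fold.  Missing IQ is imputed in-fold by k-nearest-neighbor imputation
(k = 5 by default, unspecified externally; distances over the fully
observed columns, donors restricted to training rows).

## Classification

The classifier is a linear soft-margin (hinge-loss) SVM solved by LIBSVM
via `e1071`, with per-class misclassification weights `N / (2 n_c)`
(inverse prevalence -- the concrete reading of "hyperplane weighting").
The cost grid is the 11-point default `0.0156 ... 16`.  The CV scheme is
10 outer folds x 10 outer repetitions, 10 inner folds x 1 repetition:
the inner loop selects the C maximizing mean inner-validation balanced
accuracy (ties to the smallest C, preferring stronger regularization); the
winning inner models then score the held-out outer fold, so each dyad
accumulates `10 x 10 = 100` decision scores, none from a model that saw it
in training or tuning -- the strict-exclusion reading of ensemble score
aggregation, which the recorded training-index sets make auditable
(`audit_leakage()`).  The pooled per-dyad score is the median (the mean is
exposed as an option; descriptions of the published figure suggest a mean
may have been displayed there, and the discrepancy is deliberately left
visible rather than resolved silently).  All preprocessing -- 0--1 scaling
from training extrema with test clipping, pruning of zero-variance or
non-finite training columns, optional kNN imputation, least-squares age
residualization -- is fitted strictly on training partitions.

Stratified folds keep every fold's class counts within one sample of an
even class split, and balance fold sizes by placing the leftover members of
successive classes at opposite ends of the fold sequence.  The solver
tolerance is fixed at `1e-6`; LIBSVM is deterministic for fixed data, so
identical seeds reproduce fold plans, selected costs and pooled scores
exactly.

Significance is assessed by label permutation: the full nested CV is rerun
with permuted labels and `p = (1 + #{BAC_perm >= BAC_obs}) / (B + 1)`.
Feature stability uses two complementary scores.  The cross-validation
ratio (CVR) of feature *j* sums, over outer folds, the median of the inner
models' weights divided by their standard error, divided by the number of
outer folds; a zero standard error yields a capped, flagged ratio, and
features pruned in some models are summarized over the models that
retained them (with the retained count reported).  Sign-based consistency
tests the count of positive weights across the whole ensemble against a
fair coin (two-sided exact binomial), reported as `-log10(p)` with
Benjamini--Hochberg false-discovery-rate flags at 0.05 -- the procedure the
methods specify, preferred over the conflicting figure-caption attribution
to Holm.  Performance metrics include number needed to diagnose
`1/(sens + spec - 1)`, positive likelihood ratio `sens/(1 - spec)`, the
rank-statistic AUC of pooled scores, and the diagnostic odds ratio by its
standard formula `tp*tn/(fn*fp)` (published odds ratios that disagree with
that formula on their own printed counts are not chased).

## Post-hoc statistics

Group comparisons use Welch's t-test computed from group summaries
(n, mean, sd), with Welch--Satterthwaite degrees of freedom, Holm
adjustment across the variable family (which variables form a family is a
configuration input, as published practice is not explicit) and Cohen's d
with the *unweighted* root-mean of the two variances -- the variant that
reproduces published effect sizes from their own summary rows; the
n-weighted pooled variant is an option.  Sex-by-group independence uses
the Yates continuity-corrected chi-square, which likewise reproduces the
published statistic (the uncorrected value is five times larger).
Decision-score associations with clinical scales (ADOS-2 calibrated
severity scores, consumed as inputs, never computed; ADI-R domain scores)
are Pearson correlations on pairwise-complete rows with BH q-values across
the battery.

## The synthetic generator

Each dyad is driven by a unit-variance AR(1) latent `u` (default
`ar_coef = 0.95` at 29.95 fps, i.e. roughly 0.7 s autocorrelation time --
smooth movement bursts rather than white flicker).  The administrator's
latent is `rho * u` delayed by `lag_sec` (default 1 s), completed to unit
variance by an independent AR(1); `rho` is the group-level coupling.  Head
and body latents of one person mix the shared person drive with weight
`intra_coupling` and an independent AR(1) with the complementary weight.
Observed counts are shot noise: `Poisson(burst_rate * exp(scale * z))`,
giving nonnegative, heavy-tailed series with exact zeros -- necessary for
movement quantity to be informative, which purely Gaussian observations
(almost surely never zero) would make identically 1.

Two generator parameters deserve comment:

* **`intra_coupling` (default 0.85).**  The channel-level interpersonal
  correlation is attenuated by the *square* of this mixing weight (both
  channels dilute the shared drive), on top of the shot-noise attenuation.
  An early draft used 0.6, which cuts the coupling signal to roughly a
  fifth and makes realistic group contrasts undetectable at cohort sizes;
  0.85 (attenuation 0.72) represents strongly coordinated gross head and
  body movement within a person and lets a coupling contrast of
  `rho = 0.1` vs `0.5` be detected end to end (balanced accuracy
  ~0.68--0.78 at 40--80 dyads).
* **Couplings and clip lengths.**  No external estimate of the group
  synchrony effect size exists for this population, so group couplings are
  free parameters (defaults 0.25 vs 0.45, a mild contrast).  Clip duration
  defaults to uniform 315--877 s, mirroring heterogeneous real interview
  excerpts; clinical scores are drawn from group-shifted truncated normals
  whose ASD/control means and spreads follow published module-3 summary
  tables, with 16% missing IQ by default.

What the generator deliberately does **not** emulate: real human
kinematics, camera or lighting artifacts, administrator documentation
behavior (clipboard writing), facial movement, or speech.  Passing tests
on synthetic cohorts therefore demonstrate the *correctness and
statistical calibration* of the pipeline -- null behavior at zero
coupling, monotone sensitivity in the coupling difference, valid
permutation inference -- not that any particular accuracy is attainable on
clinical video.

The toy video renderer drives a bright vertical bar per ROI whose length
follows a supplied nonnegative series, so frame-differencing recovers the
absolute driving increments exactly and spatial disjointness of ROIs can
be asserted to the pixel.

## Problem sizes used by the test suite

The shipped tests run the full scheme only where it is cheap and scale the
Monte-Carlo suites to keep the whole run at a few minutes: null-BAC
calibration uses 94-dyad feature tables with a 5-fold x 2-repetition outer
scheme over 20 runs; permutation-test calibration uses 24-dyad tables,
B = 50, 20 replicates, a 3 x 1 outer / 2-fold inner scheme; pseudodyad
calibration uses 100 cohorts of 8 dyads at 8 fps; the coupling-trend and
end-to-end demonstrations use 32--40 dyads with 4--5-minute clips (the
end-to-end run at the native 29.95 fps with a 10-fold x 3-repetition outer
scheme).  These sizes are the package's own validation design; all
statistical conclusions they support are reported with the sizes attached.

## Known limitations

* Pearson windows assume approximately linear, stationary-in-window
  coupling; no dynamic time warping, wavelet coherence or multiscale
  variants are provided.
* The pseudodyad null preserves roles but not within-session context
  (topic, furniture, camera), which real chance baselines partially share.
* `inner_perms` is fixed at 1; repeating the inner loop is not
  implemented.
* Decision scores of a linear SVM are uncalibrated margins; no probability
  calibration is offered.
* Container video decoding is out of scope: numbered PNG directories are
  the canonical frame-sequence interface, and anything else should be
  converted externally.
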