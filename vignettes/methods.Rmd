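---
title: "SVM-assisted non-targeted screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SVM-assisted non-targeted screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`svmscreen` implements a non-targeted screening workflow for pesticide and
veterinary drug (P&VD) residues in a plant matrix, driven by an LC-MS
feature table from a spiked three-concentration study design. This
vignette explains the statistical machinery, the tunable parameters, what
the synthetic-data generator does and does not emulate, and the design
choices made where the methodology was genuinely open.

## The study design and data model

The workflow assumes a spiked design: a pool of reference compounds spiked
into blank matrix at three theoretical concentrations (20, 50 and
100 ng/mL), each measured in nonuplicate, plus 12 pooled-QC injections —
39 columns in total. A compound present in the spike mix must produce a
feature whose intensity tracks concentration; matrix background must not.
The screening question is therefore: *which aligned features respond to
the spiked concentration, and which library compound does each correspond
to?*

A `feature_table` holds the variables x samples intensity matrix with
per-variable accurate mass and retention time (ids in the
`M{nominal m/z}T{RT seconds}` dialect of peak-alignment platforms) and
per-sample group/type labels.

## Recovery calibration and reproducibility filtering

Pretreatment losses differ per sample. Two isotope-labelled internal
standards (enrofloxacin-d5 and atrazine-d5) are quantified through
matrix-matched response curves; each sample's combined recovery is the
harmonic mean `2 / (1/r1 + 1/r2)` of the two percent recoveries — the
harmonic mean penalises a sample in which either standard was lost. Each
concentration group is rescaled by `kappa = 100 / mean(combined recovery)`
so the group-mean recovery becomes 100%; QC columns receive the mean of
the group coefficients (the pooled QC aggregates all groups; the source
methodology is silent on QC calibration). A per-sample variant
(`per_sample = TRUE`) exists but is off by default: averaging within
groups is what the reference procedure describes, and per-sample
coefficients would also rescale the biological signal of interest.

Variables must show RSD (sample standard deviation over mean, n - 1
denominator) strictly below 30% within QC and within every concentration
group. The strict inequality follows the stated rule ("less than 30%");
at the boundary a variable with worst-group RSD 29.9% is kept, 30.0% is
dropped. Internal-standard features are never dropped but are excluded
from all candidate ranking.

## Multivariate diagnostics

PCA (SVD on the unit-variance-scaled matrix) with a 95% Hotelling T2
ellipse on the first two components checks that QC injections gather
tightly and the groups separate; Ward hierarchical clustering cut at
k = 3 should reproduce the group partition. Unit-variance scaling is the
default throughout (the convention of the chemometrics software family
this workflow mirrors); Pareto scaling is available by configuration.

## OPLS-DA, VIP and the permutation test

Each one-vs-rest contrast (20 vs rest, 100 vs rest) is modelled by
OPLS-DA in regression form: labels encoded -1/+1 and centered, one
y-orthogonal component removed by OSC-style deflation, and a single
predictive component fitted on the deflated matrix. `n_orthogonal`
defaults to 1; in `"auto"` mode components are added only while each
removes at least 1% of the X variance. R2Y is the training-data fraction
of label variance explained; Q2 uses 7 deterministic interleaved
("venetian blind") cross-validation folds, refitting the column scaling
inside every fold so no test statistics leak into training. With one
predictive component, VIP reduces to `sqrt(p) |w_j| / ||w||` and its
mean square over variables is exactly 1, making VIP > 1 the natural
"above average importance" cut. The S-plot pairs each variable's
covariance and correlation with the predictive score; both always share a
sign.

The permutation test refits the model 200 times under shuffled labels and
regresses permuted R2Y and Q2Y against the absolute label correlation,
including the unpermuted point at correlation 1. A model is valid when
the R2Y-intercept is at most 0.4 (the upper end of the conventional
0.3-0.4 band, with a caution flag above 0.3), the Q2Y-intercept is at
most 0.05, and the empirical p-value `(1 + #[Q2_perm >= Q2]) / (n + 1)`
is below 0.05.

One subtlety deserves emphasis: the permuted refits use the
**PLS-equivalent model** (zero orthogonal components). Refitting the
orthogonal filter under permuted labels removes exactly the
label-orthogonal variance for *any* labelling, after which the predictive
component can interpolate even random labels in a p >> n table — we
measured permuted R2Y around 0.6-0.7 on rank-1-dominated matrices, which
would make the intercept rule fail for every model regardless of quality.
Building OPLS permutation plots from the corresponding PLS model is also
the convention of the major chemometrics software, whose intercept
guidance the validity rules quote. `perm_orthogonal` exposes the choice.

## SMOTE balancing

A one-vs-rest contrast is 9 vs 18 samples; class imbalance biases the
decision rule, so the minority class is oversampled to parity with SMOTE:
each synthetic sample interpolates a random minority sample toward one of
its k = 5 nearest minority neighbours (k = 5 is SMOTE's canonical
default and is feasible with 9 minority samples). Interpolation happens
in the calibrated intensity space *before* scaling, and the scaling is
refit afterwards, so synthetic rows cannot leak scaling statistics. The
same balanced design feeds both OPLS-DA and the SVM stage
(`smote_for_svm = TRUE`), keeping the two rankings comparable; the
t-tests and fold changes later use only original samples — synthetic
rows would fabricate degrees of freedom.

A known limitation follows from balancing before validation: synthetic
minority rows are convex combinations of originals, so internal
cross-validation folds contain near-relatives of training rows and Q2 (and
SVM CV accuracy) are optimistic on the balanced design. This is inherent
to the balance-then-model protocol reproduced here; the permutation test
still provides a guard because shuffled labels break the
minority/synthetic association.

## SVM tuning and SVM-RFE ranking

An RBF soft-margin SVM is tuned over c, g in 2^-10 ... 2^10 (powers of
two; the reference best values near 0.0039 = 2^-8 sit on this grid) by
stratified 3-fold cross-validation, ties broken toward the smallest c
then the smallest g; the tuned model's accuracy is reported as the mean
of 10 repeats of stratified 10-fold cross-validation.

Under a nonlinear kernel there is no primal weight vector, so SVM-RFE
uses the kernel-space ranking criterion: with the trained multipliers
held fixed, variable i is scored by the margin change
`DJ(i) = 1/2 a'Ka - 1/2 a'K(-i)a`, where `K(-i)` is the kernel matrix
recomputed without variable i. Variables are eliminated one at a time
(worst first; chunked elimination is available for larger tables), each
recorded at its elimination-time score as the weight-squared value w2,
with a sign from the univariate class-mean difference giving the signed
weight `w = sign * sqrt(w2)`. Negative DJ values (possible since the
multipliers are not re-optimised) are clamped to zero. Features are
unit-variance scaled before fitting.

## Candidate selection and confirmation

Per contrast, the retained candidate set is the smallest w2-descending
prefix of the weight table containing every VIP > 1 variable — variables
with VIP < 1 that outrank the worst VIP > 1 member are deliberately kept,
since the weight ranking is the more reliable of the two. The reported
overlap ratio is `100 |VIP ∩ prefix| / |prefix|`. The two prefixes are
intersected into consensus candidates, which must then pass univariate
confirmation: all three pairwise Welch t-tests (20 vs 50, 20 vs 100,
50 vs 100) below p = 0.05 and both fold changes (50/20, 100/20) above 2.
Welch's unequal-variance form is used because group variances scale with
concentration; p-values are raw (no multiplicity adjustment, matching the
reference procedure; Benjamini-Hochberg is available behind a flag).

## Identification and detection limits

An eligible variable is annotated to the library compound with
|mass error| strictly below 5 ppm and |RT difference| within 0.25 min;
among multiple in-tolerance candidates the smallest |ppm| wins, ties
broken by RT. The RT window is our operational choice: confirmed-marker
RT discrepancies between the published observed and reference tables
reach about 0.18 min, and no explicit window is stated. Unmatched
eligible variables are reported as unknowns rather than dropped.
Duplicate library records (same name and mass) collapse to one compound
when counting, so the shipped 124-entry library screens 123 distinct
compounds.

Detection limits follow the EPA MDL procedure: replicate low-level spikes
are converted to concentrations through the mean intensity
(`c_i = I_i * spike / mean(I)`), and LOD = t(0.99, n-1) * sd(c) — 3.143
for the seven-replicate reference design. The µg/kg conversion uses the
2.0 g sample / 1 mL extract preparation (factor 0.5). The integrated
pipeline estimates per-hit LODs from the nine 20 ng/mL replicates (t =
2.896) since the synthetic design has no separate seven-replicate
experiment; `lod_estimate()` accepts any replicate vector.

## What the synthetic generator emulates — and what it does not

The generator reproduces the study conditions: three groups in
nonuplicate plus 12 QCs; marker intensities
`base * concentration * recovery * (1 + eps)` with per-sample recoveries
drawn uniformly inside the printed ranges (72.9-93.6% and 72.9-96.4% for
the two standards) and 10% multiplicative intensity noise (truncated at
-0.9 to keep intensities positive, emulating log-normal-like LC-MS
noise); accurate masses jittered within ±5 ppm and retention times within
±0.25 min; QC columns as the pooled spiked mean with noise CV
min(cv, 0.05), matching the tight QC clustering the diagnostics require.

Matrix background is **correlated**, not independent: 1289 features load
on 10 latent factors with a random level per acquisition block (truncated
so background fold changes stay below 2) plus small within-block jitter
and 4% idiosyncratic noise. This low-rank structure is what makes the
permutation diagnostics behave as they do on real data — with independent
background features, a p >> n table lets a single latent component fit
*any* labelling and no model could pass the intercept rules. It also
reproduces clean group clustering, because block-level batch effects are
shared across features rather than scrambling individual distances.
Erratic features alternate non-monotone group patterns with
dose-responsive high-variance patterns at masses matching no library
record, exercising the unmatched-unknown reporting path (the analogue of
confirmed-but-unidentifiable variables).

The generator does not simulate raw spectra, chromatographic peak shapes,
isotope envelopes, adducts, missing values, or retention-time drift
within a run. Passing tests on synthetic data therefore demonstrate the
statistical machinery end to end — recovery of planted markers, absence
of blank false positives, validity diagnostics — but not robustness to
peak-picking artifacts, which enter upstream of this pipeline.

## Numerical choices and degenerate inputs

Constant columns scale with factor 1 (centered only); a variable with
zero variance in both groups of a t-test pair reports p = 1 with a
warning; the OPLS predictive component's sign is fixed so it correlates
positively with the label; NIPALS deflation stops early if an orthogonal
weight vector collapses below 1e-12; SMOTE requires at least 2 minority
samples and k below the minority size; the SVM-RFE kernel must see at
least two distinct rows. All randomness flows from one master seed with
per-stage derived seeds (kept inside the 32-bit integer range), so any
report is byte-reproducible from its configuration.

## Problem sizes used by the test suite

The acceptance checks run the full workflow at the study design (124
markers, 27 + 12 columns) with 400 background features and a
powers-of-four tuning grid, and the permutation criterion at the full 200
iterations; unit tests use smaller tables. These sizes are the package's
own choice of test scale: the background-feature count is a free
parameter of the design (the real-matrix count is a property of maize,
not of the method), and recall, validity and blank behaviour are stable
across it. The `analysis/` scripts run the full 1447-variable, 441-cell
default configuration.
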