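---
title: "Methods: synthetic ECG/HRV cohorts, norm-anchored scoring and leakage-safe feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioscreen)
```

# The problem this package addresses

Self-report psychological questionnaires (PCL-5 for post-traumatic
stress, PHQ-9 for depression, the Beck Anxiety Scale) are the workhorse
of screening in stressed populations, but their quality depends on the
respondent's willingness to answer carefully. Electrocardiography offers
an objective complement: autonomic state modulates both heart rate
variability (HRV) and, more subtly, the amplitude–time morphology of the
ECG itself. `cardioscreen` implements the full analysis chain needed to
study such links at small cohort sizes — signal-level feature
extraction, a norm-anchored composite scoring system, correlation
screening, and a forward feature-selection pipeline with held-out
evaluation — together with a synthetic-data module that makes every
stage testable against known ground truth.

# The synthetic world

## Rhythm

`generate_rr_series()` draws interval *k* as

RR_k = mean_rr + lf_amp·sin(2π·0.1·t_k) + hf_amp·sin(2π·0.25·t_k) + ε_k,

with t_k the cumulative time at beat onset and ε_k ~ N(0, noise_sd²).
The 0.1 Hz tone stands in for baroreflex (low-frequency) activity and
the 0.25 Hz tone for respiratory sinus arrhythmia; they give the
spectral estimators known targets (a pure tone must put > 95 % of its
power in its own band). Defaults — mean 900 ms, modulation amplitudes
25 ms, jitter 15 ms, 300 beats — describe a resting adult recording of
about five minutes, the standard duration for short-term HRV. Intervals
are floored at 200 ms so cumulative time stays monotone under extreme
parameterisations.

## Beats and leads

A beat is a static sum of five Gaussian waves per primary lead (I and
II); each wave has a signed amplitude (μV), a centre offset from the R
peak (s) and a width σ (s). Wave onset/offset ground truth is defined
analytically as the 5 % amplitude crossing, which for a Gaussian sits at
±σ·√(2·ln 20) ≈ ±2.448 σ from the centre; this makes the delineator's 5 %
threshold-crossing contract directly checkable. Default centres are
derived from interval targets (PQ 0.16 s, QT 0.38 s, QRS 0.10 s); widths
(σ_Q = 6 ms, σ_R = 8 ms, σ_S = 8 ms) were chosen so that the tail of one
wave contributes < 2 % of any neighbour's amplitude at that neighbour's
centre — without this, no extractor could meet a 2 % amplitude-recovery
contract, because the rendered signal itself would differ from the
template parameters by more.

Only leads I and II are rendered; the remaining limb leads are derived
sample-wise (III = II − I, aVR = −(I+II)/2, aVL = I − II/2,
aVF = II − I/2). This matches the physics of limb-lead derivation and
gives the test suite a free invariant: the algebra must hold to floating
precision on every generated record.

The generator deliberately omits respiratory amplitude modulation,
beat-to-beat morphology variation, baseline wander and pathological
morphologies. A green extraction test therefore establishes correctness
of the measurement definitions, not robustness to clinical artefact.

## Cohorts

`generate_cohort()` draws standard-Gaussian features, rebuilds requested
collinear pairs as f_j ← ρ·f_i + √(1−ρ²)·f_j, and computes each target
as Σβ_j f_j + ε. The population R² implied by the planted covariance,
Var(Σβf)/(Var(Σβf)+σ_ε²), is reported as ground truth. Targets are
computed from the *clean* features; outlier corruption (±8 SD shifts on
15 % of columns, on `floor(outlier_fraction·n)` rows) and missingness
are applied afterwards, so planted outliers genuinely disrupt a naive
fit. The fourth target is discretised to the ordinal 1–4 scale by
quartile cut of its latent score and treated as numeric downstream, as
is conventional when a formalized psychologist's conclusion enters a
regression. Defaults: 90 subjects, 120 features, outlier fraction 0.07
(6–8 corrupted rows out of 90, the order observed in cohorts of this
kind), missing fraction 0.02, per-target population R² of 0.35 / 0.30 /
0.50 / 0.50 — the anxiety-type target carries the strongest signal. The
feature count is a modelling choice, not an empirical fact: studies in
this family report "40 features selected" which only bounds the
candidate pool from below.

# Feature extraction

**R detection.** Band-pass 5–25 Hz (zero-phase, frequency-domain mask),
squared first difference smoothed over 80 ms, threshold at a fixed
fraction of the envelope's 99.5th percentile — a *relative* threshold,
so detection is invariant to overall gain — with a 250 ms refractory
period, then refinement to the extremum of the band-passed signal.

**Delineation.** All morphology is measured on a median beat per lead
(window −0.40 s to +0.60 s around each R), which suppresses additive
noise roughly as 1/√n_beats. The baseline is the median of the PQ
segment (40 ms ending 4 ms before QRS onset). Wave boundaries are 5 %
threshold crossings of each wave's baseline-relative excursion, with two
numerical guards: the outward walk also stops at a sign reversal
(adjacent opposite waves can meet in a zero crossing too steep for any
sample to land inside the 5 % band), and deflections below 2 % of the R
excursion are declared absent (amplitude 0, duration 0) rather than
delineated as noise. The J point is the QRS offset.

**Measurements.** Amplitudes are signed baseline-relative extrema
(negative Q and S are preserved); durations P, Q, QRS, PQ (P onset →
QRS onset) and QT (QRS onset → T offset) in seconds; P and QRS areas are
trapezoidal integrals of |signal − baseline| (exact for piecewise-linear
signals); QTcF = QT/RR^{1/3}; Macruz index = P/(PQ − P). Undefined
ratios (zero denominators) become missing values and flow into the
imputation stage rather than infinities.

**HRV.** SDNN and SDSD use the population SD (a fixed, documented
convention — at n ≥ 100 the sample/population distinction is far below
measurement noise); pNN50 counts differences *strictly* greater than
50 ms, so a tie does not count. Spectra: the tachogram is
cubic-spline-interpolated to a uniform 4 Hz grid, linearly detrended,
and Welch-averaged (64 s segments, 50 % overlap, Hann window); LF is
[0.04, 0.15) Hz and HF [0.15, 0.40] Hz per the standard short-term
bands. DFA α₁ integrates the mean-centred series and fits the log–log
slope of the per-box linear-detrended fluctuation over box sizes 4–16
(the short-term range); white noise must give α₁ ≈ 0.5 and 1/f noise
α₁ ≈ 1.0. The Baevsky stress index AMo/(2·Mo·MxDMn) uses 50 ms
histogram bins centred on the 50 ms grid (so 800 ms falls in the
775–825 ms bin), which makes small worked examples exact. The
coherence ratio is the power within ±0.015 Hz of the tallest spectral
peak in 0.04–0.26 Hz divided by the remaining power in 0.0033–0.40 Hz.

**The Mashin index** has no fixed published formula that we could adopt;
the default is the lag-1 autocorrelation of the linearly detrended RR
series (a rhythm-stability measure on the same conceptual axis), and it
is explicitly swappable via the `mashin_fun` argument so a user with the
authoritative definition can inject it.

# Norm-anchored scoring

Each parameter value is mapped to points by piecewise linear
interpolation between three anchors: the normal mean M (100 points), the
norm boundary at one SD (75 points), and a side-specific extreme
pathology bound (0 points), clamped to [0, 100]. The published systems
this emulates state only that the final scale is a 100-point interval
scale; the specific anchor values are configuration
(`scale_anchors()`), with the 100/75/0 defaults documented here. The
extremes are deliberately asymmetric per side because ECG quantities are
physiologically asymmetric (an R amplitude can be ten times its norm,
a PQ interval cannot).

Composites are unweighted means through a four-level hierarchy —
parameters, groups of related indicators, functional blocks (regulation,
myocardial condition, arrhythmia, psycho-emotional status), and a single
integral indicator — with missing children skipped and a node missing
only if all its children are. The bundled norm table
(`inst/extdata/norm_ranges.csv`) carries literature-style ranges for the
basic amplitude-time quantities and ranges tagged `normative-database`
for the HRV and psycho-emotional quantities, regenerable from a
synthetic normative cohort; the exact group memberships of the shipped
hierarchy are a documented reconstruction, since published composite
names do not enumerate their member lists.

Two cohort-level diagnostics gate a composite index: a **Huber
robustness check** (location by iterative reweighting, tuning constant
1.345, MAD scale, tolerance 1e-8) flags an index when the robust
location and the plain mean disagree by more than 0.25 × MAD — the
threshold spread must itself be robust, because a contaminated index
inflates its own SD and could otherwise never be flagged — and a
**homogeneity check** clusters the 1-D index values with a purpose-built
density method (per-point core distances to the k-th neighbour, mutual
reachability between sorted neighbours, splits where that distance
exceeds four times its median, minimum cluster size 10). A healthy-
cohort index should form exactly one dense cloud.

# Correlation screening

Pearson r with the two-sided p-value from t = r√((n−2)/(1−r²)) on n−2
degrees of freedom; Spearman as Pearson on mid-ranks. Missing data are
dropped pairwise per feature–target pair at this stage (screening
describes each pair on its own evidence; imputation belongs to the
modelling stage, where a single design matrix is required). Tier counts
use *exclusive* bins — a p = 0.005 feature counts under "p < 0.01", not
also under "p < 0.05" — which is how published tier summaries add up
against their per-feature tables; an inclusive mode and a
Benjamini–Hochberg adjustment exist but are off by default, since raw
p-values are what screening tables of this kind conventionally report.
Both the strict (p < 0.01) and extended (p < 0.05) per-target tables are
returned, explicitly labelled.

# The selection pipeline

Per target, in order, with every statistic fitted on training data only:

1. **Split**: 25 % held out, stratified by target quartile. The
   originating studies do not state their split fraction; 0.25 is the
   default and is configuration.
2. **Outlier removal** on training rows only, by an isolation forest
   (200 trees, subsample 256) flagging the `contamination` fraction
   (default 0.08 ≈ 6–8 of 90) with the highest anomaly scores. The test
   set is never cleaned — held-out data must be what the field would
   actually see.
3. **Imputation** by train-column medians, applied to both halves.
4. **Collinearity filter**: repeatedly find the pair with the largest
   pairwise |r| above 0.7 and drop the member with the weaker absolute
   correlation to the training target (ties to column order); the
   retained set provably satisfies max |r| ≤ 0.7.
5. **Transformer grid**: feature transformer ∈ {none, quantile-to-
   normal, Yeo-Johnson} × target transformer ∈ {none, Box-Cox,
   Yeo-Johnson}; Box-Cox cells are skipped with a logged message when
   the training target has non-positive values. Lambdas are fitted by
   maximum likelihood on the training side. Cross-validated and
   held-out R² are always computed on the *original* target scale
   (fold/test predictions are back-transformed first) so grid cells are
   comparable; the winning cell is the argmax of mean CV R² at its
   chosen size, and the test set is touched exactly once, by the winner.
6. **Forward selection**: from the empty set, each step adds the
   candidate maximising the mean five-fold CV R² of OLS on
   (current set + candidate), ties to the lowest column index, up to 40
   features. The chosen size maximises the mean CV R² along the path;
   by default the smallest size within one standard error of that
   maximum is preferred (`one_se = FALSE` restores the plain argmax).

Fold assignment, the split, and the isolation forest all draw from named
substreams of one seed (`substream_seed()`), so a change in one module's
draws cannot shift another's, and a full rerun at a fixed seed is
byte-identical.

# Known limitations

**Selection-bias of the CV curve, and an honestly red acceptance
check.** The mean CV R² recorded along the forward path is optimistically
biased: each step reports the *maximum* over ~100 candidates of a noisy
CV estimate. In the package's hardest synthetic test (n = 90, 100
independent candidates, five unit-beta planted features, population
R² = 0.5), this bias makes the curve climb far past the true model size;
the chosen sets (8–26 features) do contain ≥ 4 of the 5 planted features
(median over 20 seeds), but the surplus noise regressors at n_train ≈ 68
drive the median held-out R² to ≈ −0.25, far below the [0.25, 0.60] band
that a perfect selector would reach (an oracle OLS on the five true
features achieves median test R² = 0.43). The gap is structural, not an
implementation defect: each true feature carries a marginal correlation
of ≈ 0.32 while the expected maximum spurious correlation among 95 noise
features at this n is ≈ 0.37, so no greedy CV-based selector can have
both high recall in its first few steps and a compact model. Rebuilding
the path inside each fold (a fully nested k-chooser) picks honest small
sizes (1–6) but then recovers only 2–3 planted features — the same
trade-off from the other side. The corresponding acceptance test is left
failing rather than weakened, as a quantified statement of what this
method class cannot do at this sample size. On real cohorts, where
candidate features are heavily inter-correlated, the effective candidate
dimension is far lower and held-out R² near 0.3–0.4 is attainable — but
that is a property of the data, not of the algorithm.

Other limitations: the beat model is static (no respiratory amplitude
modulation, no morphology drift), so extractor robustness claims are
limited to additive noise; the homogeneity check is a 1-D analogue of
hierarchical density clustering, not the full excess-of-mass algorithm;
Sylvester/CIIS-style external infarct scores are accepted as
pre-computed input columns only, since their formulas are not public in
the sources this package draws on.
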