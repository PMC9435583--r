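---
title: "Methods: imaginary-coherency FC classification of seizure subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imaginary-coherency FC classification of seizure subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`seizfc` classifies complex (CPS) versus simple (SPS) partial seizures from
resting-state MEG parcel time series. This vignette is the package's own
account of the model and the design choices behind it: what is estimated,
under which assumptions, which knobs matter, and what the synthetic cohort
does and does not establish.

## The estimand: lagged interactions, not shared signal

All stages hinge on one estimator choice. For two parcel time courses the
coherency at frequency $f$ is the normalised cross-spectrum

$$C_{ij}(f) = \frac{S_{ij}(f)}{\sqrt{S_{ii}(f)\,S_{jj}(f)}},$$

and the per-segment connectivity value of a parcel pair is the 1–40 Hz
band average of $|\mathrm{Im}\,C_{ij}(f)|$. Any instantaneous mixing of
sources — the signature of volume conduction and of field spread in
source-reconstructed MEG — contributes only to the real part of the
coherency: a mixed copy of a signal is in phase (or antiphase) with it at
every frequency. A non-zero imaginary part requires a consistent non-zero
phase lag, i.e. a genuinely time-lagged interaction. This is why the
synthetic generator plants group differences as *lagged* coupling and
refuses zero lags: a zero-lag "difference" would be invisible to the
estimator by construction, and the package treats asking for one as an
error rather than a silent no-op.

The cross-spectra come from Welch's method: 1-s Hann-tapered, demeaned
windows with 50% overlap, so a 4-s segment at 100 Hz yields 7 windows and
a 1 Hz frequency grid. The estimator itself is not prescribed by the
problem; 1-s windows are the shortest giving a 1 Hz grid that resolves the
1–40 Hz band, and 7 averages is the most stability a 400-sample segment
affords. Both parameters (`window_s`, `overlap`) are exposed.

### Absolute versus signed band averaging

The imaginary part per bin can be averaged signed or as a magnitude.
The package defaults to the magnitude, $|\mathrm{Im}\,C|$ per bin before
averaging, because the sign of the imaginary part flips with the sign of
the lag and with frequency (a fixed delay $\tau$ gives a phase
$2\pi f \tau$ whose sine changes sign across the band), so a signed band
average of a real lagged interaction largely cancels — the worked positive
control in the test suite shows a 20-ms lag at strength 0.6 reaching
FC $\approx 0.66$ under the magnitude convention while the signed average
stays near zero. The magnitude convention has one cost that users should
know about: under the null (no interaction), $\mathrm{Im}\,\widehat C$ is
approximately zero-mean Gaussian with variance $\sim 1/(2W)$ for $W$
windows, so its magnitude has a *half-normal floor* of about
$(\pi W)^{-1/2}$ — roughly 0.22 for the 7 windows of a 4-s segment, 0.06
for a 4000-sample stream. This floor is a property of the estimator, not a
leak: random instantaneous mixings do not raise it above the unmixed null
(the suite checks this), and strong real coherence in fact *lowers* it by
shrinking the variance of $\mathrm{Im}\,\widehat C$. Group contrasts ride
on top of a common floor and are untouched; absolute FC values should not
be read as zero-baselined coupling strengths. The signed convention
(`absolute = FALSE`) is available where a zero-baselined quantity is
needed.

## Preprocessing rules

Segments are the classification unit, and the extraction rules are fixed:
±10 s exclusion around every annotated spike; left-anchored tiling of each
clean interval into 10-s cuts; a trailing partial cut is kept only if at
least 4 s long; every kept cut is trimmed to its first 4 s. The tiling
anchor (left edge of each clean interval) is a convention the package
fixes because an unanchored "non-overlapping cut" is ambiguous; the count
consequences of the whole rule set are pinned against a 1-ms-grid brute
force in the tests.

Filtering is zero-phase throughout — phase distortion would corrupt
exactly the quantity the pipeline measures. The 1–70 Hz band edges are
realised as a 4th-order Butterworth high-pass plus low-pass cascade
(numerically robust for a wide band at 1200 Hz, identical magnitude
intent to a band-pass design), the 50 Hz line notch is the standard
audio-EQ biquad with $Q = 30$, and all IIR filtering is applied
forward–backward with odd-reflection end padding to keep start-up
transients out of the data. A $Q = 30$ notch rings for a few hundred
milliseconds; on block-length recordings this is negligible, which is why
filtering happens at the block level before cutting.

Downsampling to 100 Hz uses a windowed-sinc (Hamming) FIR anti-alias
filter cut at 40 Hz, delay-compensated to zero phase. 40 Hz — not the
70 Hz analogue low-pass — because the post-decimation Nyquist is 50 Hz:
keeping the 70 Hz edge would alias 50–70 Hz content into the analysis
band, while nothing above 40 Hz is analysed downstream. The FIR length
(~0.6 s of taps) gives a transition band of a few hertz and >50 dB
stop-band rejection.

Artifact rejection is automated, replacing what is usually a manual step:
a segment is dropped when any channel's amplitude exceeds `amp_z_max`
(default 6) standard deviations of that channel across the subject
(muscular proxy), or any channel's first difference exceeds `grad_z_max`
(default 6) pooled standard deviations (jump proxy). The thresholds are
conventions and are exposed; the synthetic data carries no artifacts by
default, so these defaults act as a no-op there unless artifacts are
injected.

## Feature space, F-score, and selection

A symmetric $74 \times 74$ FC matrix is vectorised as its lower triangle
plus main diagonal in row-major order, $p(p+1)/2 = 2{,}775$ features. The
diagonal is identically zero under imaginary coherency and always scores
zero, but it is *kept* so that the feature count and the index arithmetic
(feature $= i(i-1)/2 + j$, $i \ge j$, 1-based) stay canonical across
folds and schemes — overlap counting requires a stable index.

The F-score of a feature is the ratio of between-class squared mean
deviations to the sum of within-class sample variances ($n-1$
denominators). It is affine-invariant per feature and requires at least
two samples per class. A zero within-class-variance feature is defined to
score 0 (it carries no usable contrast; a config flag offers `Inf`
instead). "Top 1%" is implemented as $k = \lceil 0.01\,m \rceil$: for
$m = 2{,}775$ this gives 28, and a floor would give 27, which could never
produce a 28-feature stable set. Ties break by ascending feature index so
that selections are deterministic.

## Cross-validation, stability, and the final test

Subjects are paired into subsets — one CPS with one SPS subject of
matching segment-count rank — so that each subset is approximately
class-balanced even though per-subject yields vary several-fold. Two
subsets are held out for testing (seeded draw, or pinned via
`test_subsets`); the remaining 14 run a leave-one-subset-out loop in which
F-scores, the top-1% selection, and the SVM fit all use the 13 sub-training
subsets only. The alternative scheme pools all training segments and
repeats seeded 90/10 sample-level splits, deliberately ignoring subject
identity — its folds are easier (segments of one subject can appear on
both sides), which is exactly the contrast the two schemes are meant to
expose.

Features selected in at least 12 of the 14 folds are the stable set; each
stable feature's mean F-score is averaged over the folds where it was
selected (folds that did not select it never ranked it in a comparable
context), and stable features above 75% of the maximum mean F-score are
flagged strong. The final classifier is retrained on the full training
pool restricted to the stable set — the "retrain" reading of an ambiguous
protocol, adopted because reusing an arbitrary fold model would make the
report depend on fold order — and evaluated once on the held-out subsets,
with CPS as the positive class for sensitivity/specificity.

The SVM uses the RBF kernel with $C = 1.2$, $\gamma = 5$ fixed everywhere,
no feature standardisation (FC values already live in $[0,1]$; a
config flag exists). Hyperparameter search hooks are deliberately not the
default: fixed values make every fold, and the final model, reproducible.

One stability caveat the null simulations expose: with 14 folds sharing
12–13 of 14 subsets, fold F-scores are strongly correlated, so
*subject-level* idiosyncrasies can push a handful of edges over the 12/14
threshold even when no group difference exists. The validation and test
accuracies stay at chance in that case — stable sets should therefore be
read together with the held-out accuracy, never alone.

## The synthetic cohort: what it emulates, what it does not

The generator produces two groups of 16 subjects, 74 parcels, and 4-s
100 Hz segments (segment mode) or continuous 1200 Hz annotated blocks
(raw mode, twenty 120-s blocks). Parcel signals are unit-variance Gaussian
noise band-limited to 1–45 Hz — populating the full analysis band with a
margin — with white observation noise (default SD 0.5, i.e. half the
signal amplitude) on top. Group structure enters only through
`coupling_spec`: a target parcel receives `strength` times the source
parcel delayed by `lag_ms` (default 20 ms, two samples at 100 Hz), with
edges carried by one group or both. Per-subject segment yields are drawn
from a configurable range (default 33–169, matching the strong imbalance
real cohorts show); in raw mode the yield is realised physically, by
tuning each subject's Poisson spike annotations until the exclusion and
partition rules produce the drawn count. All randomness descends from one
root seed; cohorts are bit-reproducible.

The study-scale validation cohort used by the tests and the acceptance
script fixes ~60 segments per subject (drawn from 55–65), five planted
CPS-only edges at strength 0.6, and the default noise level. At these
settings the pipeline recovers all five planted edges in the stable set
and classifies held-out subjects essentially perfectly, while 20 null
cohorts (no coupling) stay at chance — the conditions are deliberately
clear-cut, probing correctness of the machinery rather than its detection
threshold.

What the generator does **not** emulate: MEG sensor physics, head
movement, realistic 1/f spectra, ICA-removable blink/ECG artifacts,
spatially correlated source noise, or volume conduction beyond the
instantaneous-mixing robustness checks. Passing the recovery tests
therefore shows the pipeline is correct and leak-free, not that clinical
effect sizes of any particular magnitude are detectable; on real data the
contrast will be weaker and the stable-set caveat above proportionally
more important.

## Numerical and degenerate-input conventions

- Lags shorter than one sample at the working rate are errors, not
  roundings (they would silently test nothing).
- A channel with zero auto-spectrum inside the band is an error
  (degenerate input), not an `NaN` propagation.
- `exclude_event_windows` clips event windows to the block and merges
  overlaps before complementing; intervals are half-open.
- Resampling refuses upsampling; equal rates are an exact identity.
- Random 90/10 splits that lose a class are redrawn with the next derived
  seed, with a message.
- The stability threshold is validated against the fold count before any
  computation; `flag_strong_edges` and the final evaluation refuse empty
  stable sets explicitly.

## Problem sizes used by the shipped studies

The validation studies run at the full study scale — 32 subjects, 74
parcels, ~1,900 segments, 2,775 features, 14 folds per scheme — once per
seed; the 20-seed null band and all property suites (200 random
segmentation layouts, 100 random F-score tables, 50 random mixings) were
sized so the whole suite completes in minutes on one CPU while keeping
every Monte-Carlo band at least several standard errors wide.
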