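---
title: "Clustering ECG morphology against chronic-disease labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering ECG morphology against chronic-disease labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgclust)
```

## What the package does and why

Classical automatic ECG analysis targets overt cardiac disease
(arrhythmia, infarction). Conditions such as diabetes, obesity,
hypertension and habitual smoking are *not* read off an ECG clinically,
yet each has documented electrophysiological correlates — prolonged QRS
duration in diabetics, left-ventricular-hypertrophy voltage changes under
chronic hypertension, amplitude attenuation with body habitus, elevated
resting heart rate in smokers. `ecgclust` operationalizes a simple
question: if you extract morphology features from resting single-lead
ECGs and cluster subjects *without looking at the labels*, do the
labeled subjects concentrate in particular clusters?

Because real clinical archives cannot be bundled, the package's first
module is a *labeled synthetic cohort generator* whose statistical
structure matches what the analysis assumes. Every downstream stage is
then testable against generator ground truth: true R-peak times, true
fiducial-point locations, true effect sizes.

## The synthetic cohort: what it emulates, what it does not

Each beat is a sum of five Gaussian bumps — P, Q, R, S, T — with
per-component amplitude (mV), center offset from the R apex (ms) and
width (ms). Defaults describe a typical adult lead-II-like beat
(R ≈ 1.1 mV; QRS spanning roughly −35 to +35 ms; T at +280 ms). Beats are
placed at RR intervals drawn from Normal(60000/hr, rr_sd) ms, clipped
positive. This "sum-of-Gaussians" model (in the spirit of dynamical ECG
simulators) was chosen over spliced real templates because its fiducial
points are analytically known, which makes waveform-feature tests exact.

Per-subject variability: amplitudes and widths get lognormal jitter
(σ_log = 0.08 and 0.06), centers get small Gaussian jitter (3 ms for
Q/S, 8 ms for P/T), heart rate is Normal(72, 8) bpm clipped to
[45, 120]. These are one-time realism choices: QRS-duration spread of a
few milliseconds and ±10% amplitude spread are in the range reported for
healthy adults.

Five noise classes are modeled additively: baseline wander (a sum of
five random-phase sinusoids inside 0.05–2.00 Hz), power-line sinusoid,
band-limited EMG noise, sparse electrode-motion transients
(Poisson-timed ~150 ms bumps), and white noise. A zero-amplitude
specification is the identity, and each class is independently seeded.

Condition effects are *configurable multiplicative/additive deltas*, not
measured clinical effect sizes — the clinical literature motivates their
direction, not their magnitude. Shipped defaults: diabetes widens the
QRS complex ×1.4 and flattens T ×0.7; hypertension raises R ×1.3;
smoking adds 15 bpm; obesity scales all amplitudes ×0.8. Default
prevalences follow the diagnostic-class proportions of a well-known
public diagnostic ECG archive (diabetes 29/268, obesity 20/268,
hypertension 63/268, smoker 73/268).

What the generator does **not** emulate: multi-lead geometry (a single
synthetic lead; multi-lead would be repeated generation sharing the RR
stream), pathological beat-to-beat morphology change, arrhythmia,
co-morbidity interactions beyond independent flags, or real electrode
artifacts. A green parameter-recovery test therefore establishes that
the pipeline can recover *planted* morphology differences at realistic
noise — not that real cohorts carry equally clean signal.

## Preprocessing

**Denoising** is a zero-phase FIR band-pass, default 0.5–40 Hz: the low
edge removes baseline wander, the high edge suppresses EMG and mains
interference. The filter is a Hamming-windowed ideal band-pass of order
`round(4 * fs / low)` applied forward-backward (squared magnitude, exact
zero phase) with odd-reflection padding. Two numerical facts worth
knowing: the passband gain is normalized at the band's geometric-mean
frequency, and any padded FIR produces an edge transient of roughly the
filter length — with a 0.5 Hz low edge that is several seconds, so
filter-quality assessments should be made in the signal's steady-state
interior. An optional narrow mains notch and optional wavelet
soft-threshold shrinkage (universal threshold, MAD noise estimate on the
finest detail band) are off by default.

**QRS detection** scores candidates on a QRS-band (5–25 Hz) filtered
copy — the matched-band trick that makes the sharp R deflection dominate
the broad, similar-amplitude T wave. Candidates are
positive-to-negative zero crossings of the first derivative of that
detection signal; two non-linear suppressions follow: an amplitude floor
of 0.3 × the running median of the last eight accepted peak amplitudes
(initialized from per-2-second block maxima), and a 200 ms refractory
interval. Accepted candidates are refined to the local maximum of the
input signal within ±40 ms. The refractory constant and floor are
standard ECG practice, configurable; on generator output at ≥ 20 dB SNR
the detector's sensitivity and positive predictivity exceed 0.95, and on
clean signals it is sample-exact.

**Beat segmentation** emits one beat per interior R peak, windowed from
the previous R to just before the next R (the first and last peaks have
no complete cycle and are dropped). Note these 2-RR windows overlap by
one RR interval by construction; the disjoint tiling units are their
leading R-R cycles, which is what the wavelet feature consumes.

## The three feature extractors

**RBP.** The binarization rule maps ties to 0 ("decrease"), so constant
runs are decreases; words are sliding (stride-1) windows of *m* bits,
first bit most significant. *m* is not fixed by the method's lineage;
the default *m* = 8 gives a 256-bin histogram. Any consistent bit order
permutes bins and leaves clustering unchanged. RBP is computed on the
denoised full record without segmentation; it is invariant to amplitude
scale and offset, which is verified property-style in the tests.

**Wavelet.** Each R-R cycle contributes its first 169 and last 85
samples. 169 + 85 = 254, not 256 — the two stated numbers are mutually
inconsistent, so the package follows the stated slice literally and
edge-pads two samples (repeating the final value adds no spurious
discontinuity); `strict_254 = TRUE` keeps the raw 254-vector instead.
Cycles shorter than 254 samples are skipped with a logged count — note
this effectively requires fs ≥ ~500 Hz at resting heart rates (the rule
is calibrated to 1 kHz archive data). Segments are grouped in fours;
each segment gets a periodized orthogonal DWT (haar/db2/db4; default
db4). Periodization keeps the coefficient count exactly 256 at every
level and makes the transform orthonormal, so perfect reconstruction and
Parseval equality are testable to floating-point precision. The maximal
level for 256 points under periodization is 8; a 9-level example in the
method's lineage cannot apply to 256-point inputs and is not guessed at —
the default is *n* = 6. The four coefficient vectors are concatenated
(1024 dims) and group vectors are averaged into the subject vector
(aggregation is not dictated by the method; the mean makes the subject
vector invariant to group order, which is tested).

**Waveform.** Fiducial windows around the known R apex: Q is the minimum
in (R−80 ms, R), S the minimum in (R, R+80 ms), P the maximum in
(R−300 ms, R−80 ms), T the extremum of |signal − median| in
(S+80 ms, S+400 ms). The windows are standard physiological bounds (the
method's description gives no delineation algorithm) and all are
configurable. The 24 features use fixed conventions that the method's
description leaves open, each chosen for clustering sanity and
documented: positions are R-relative (absolute positions would depend on
record cropping); amplitude features are signed differences amp(X) −
amp(Y) in the order written (PQ = P − Q); durations are absolute time
differences; slopes are Δamplitude/Δtime with time signed; the QRS area
is the shoelace area of the Q-R-S triangle. Beats aggregate by
element-wise median, robust to occasional mis-delineation. `pos_R` is
identically zero under the R-relative convention; the standardizer maps
zero-variance columns to zero rather than dividing by zero.

## Clustering and metrics

K-means is implemented natively (Lloyd iteration): initial centers are
*k* data points drawn at random — the classical scheme, seeded;
k-means++ seeding and explicit `init_idx` starts exist for users who
want them. Iteration stops when assignments are unchanged, |ΔE| <
1e-8, or 300 iterations — tolerances are implementation choices. An
empty cluster is re-seeded at the point farthest from its nearest
center. Equidistant assignment ties break to the lowest cluster index,
making runs deterministic given the seed. E is recorded per iteration
and is non-increasing, which every pipeline run asserts.

Random restarts matter: on tiny instances a single classical start can
converge to a local Lloyd fixed point a fraction of a percent above the
exhaustive-partition optimum. The pipeline defaults to `nstart = 10`;
the optimality test suite exhausts every distinct k-point
initialization.

Standardization defaults to "auto": on for waveform features (mixed
units — ms, mV, mV·ms — would otherwise let large-valued durations
dominate the Euclidean metric), off for RBP (already relative
frequencies) and wavelet coefficients (homogeneous units).

The crosstab counts, per cluster, positives for each condition among
members whose flag is known; unknown (`NA`) flags are excluded from that
condition's numerator *and* denominator only — subjects are still
clustered. The ratio criterion flags a (condition, cluster) pair
significant above 50%; concentricity is the largest single-cluster share
of all known positives, with the achieving cluster. Both are exact
arithmetic on the crosstab and are verified against the published
worked percentages (e.g. diabetes counts 8 and 21 across two clusters
give 21/29 = 72.41%).

## Numerical and testing choices

- One master seed; per-subject and per-noise-stream child seeds derive
  by fixed integer arithmetic (kept below 2³¹), so any subject or stream
  regenerates independently and cohorts are bit-reproducible.
- Sample indexing is 1-based (R convention), times in seconds,
  amplitudes in mV.
- Near-null stochastic properties are tested on means over several fixed
  seeds: a single run's concentricity under no effect is close to a coin
  flip, so one-seed comparisons of near-null levels would be noise. The
  headline recovery bound (concentricity ≥ 0.9 at the ×1.4 QRS effect)
  holds at every tested seed individually.
- The WFDB reader supports format-16 single-segment records only —
  enough to substitute the public diagnostic archive's records for the
  synthetic cohort — and errors loudly on anything else. Which of the 15
  leads the analysis should use is not knowable from the method's
  description; the reader takes a lead label or index explicitly.

## Known limitations

- Disease effect magnitudes are plausibility stand-ins; recovered
  concentricities quantify the pipeline, not clinical effect sizes.
- The fiducial localizer assumes the generator's single-bump-per-wave
  morphology; notched QRS complexes or biphasic T waves would need a
  richer delineator.
- The wavelet feature silently loses subjects whose records yield fewer
  than four usable 256-point segments (short records, fast heart rates,
  or low sampling rates); the pipeline logs and excludes them.
- EMD/EEMD denoising and neural-network clustering are out of scope, as
  is elbow-method selection of k: the analysis deliberately compares
  fixed k ∈ {2, 4, 8}.
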