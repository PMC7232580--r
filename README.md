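# ecgclust

Unsupervised clustering of ECG morphology against chronic-disease and
habit labels.

Resting electrocardiograms carry subtle morphological imprints of
conditions that are not classical heart disease: diabetes is associated
with a prolonged QRS complex and flattened T waves, ventricular
hypertrophy (a hypertension correlate) with taller R waves, body habitus
with globally attenuated amplitudes, and smoking with elevated heart
rate. `ecgclust` asks whether such imprints are strong enough for an
*unsupervised* method to recover: it extracts per-subject feature vectors
from single-lead ECGs, clusters them with k-means, and cross-tabulates
the clusters against medical-record flags (diabetes, obesity,
hypertension, smoker).

The package is aimed at biomedical-signal researchers who want a
reproducible, fully synthetic testbed for this kind of
phenotype-clustering analysis: every stage, from the labeled cohort
generator to the association metrics, is seeded, tested and inspectable.

## The method

For subjects *i = 1…n*, a feature vector *X<sub>i</sub>* is built from
one of three extractors:

- **RBP (reduced binary pattern)** — symbolic dynamics. Each consecutive
  sample pair is reduced to a bit, *y<sub>i</sub>* = 1 if
  *x<sub>i+1</sub>* > *x<sub>i</sub>*, else 0; sliding *m*-bit words are
  read as integers and the feature is the relative frequency of each of
  the 2<sup>m</sup> words (default *m* = 8, a 256-vector). Invariant to
  amplitude scale and offset by construction.
- **Waveform** — 24 fiducial descriptors per beat: R-relative positions
  of P, Q, R, S, T; ten pairwise amplitude differences; five durations;
  three slopes; and the Q–R–S triangle area. Aggregated across beats by
  the element-wise median.
- **Wavelet** — each R-R cycle is reduced to a 256-point segment (first
  169 + last 85 samples, edge-padded by 2), segments are grouped by four,
  each segment gets an *n*-level periodized discrete wavelet transform
  (default db4, *n* = 6), and the four coefficient vectors are
  concatenated (a 1024-vector), averaged over groups.

Vectors are clustered by Lloyd k-means under the Euclidean metric
*D(X<sub>i</sub>, X<sub>j</sub>)* = ‖X<sub>i</sub> − X<sub>j</sub>‖₂,
minimizing the square error

&nbsp;&nbsp;*E* = Σ<sub>i=1..k</sub> Σ<sub>p∈C<sub>i</sub></sub> |p − m<sub>i</sub>|²,

with *m<sub>i</sub>* the mean of cluster *C<sub>i</sub>*. Two
association metrics summarize each (condition, clustering):

- **ratio** — the fraction of a cluster's members positive for a
  condition (> 50% read as a significant correlation);
- **concentricity** — the largest single-cluster share of *all* positives
  for a condition (high values mean the condition concentrates in one
  cluster even when no ratio exceeds 50%).

## Worked example

```r
library(ecgclust)

cfg    <- cohort_config(n = 40, fs = 500, duration = 10, seed = 7)
cohort <- generate_cohort(cfg)         # signals + labeled records
res    <- run_pipeline(cohort, features = "waveform", k = 2, seed = 7)
report_text(res)
```

```
== waveform features, k = 2 (E = 670.8) ==
Group      Number  Obesity  Smoker  Hypertension  Diabetes
Group 1        35        4      11             8         0
Group 2         5        0       2             1         4
  concentricity obesity       100.00% (group 1)
  concentricity smoker        84.62% (group 1)
  concentricity hypertension  88.89% (group 1)
  concentricity diabetes      100.00% (group 2)
```

With the default disease effects (diabetes: QRS width ×1.4, T amplitude
×0.7), all 4 diabetic subjects of this 40-subject cohort land in their
own small cluster — diabetes concentricity 100% — while obesity, smoking
and hypertension spread with the majority group, mirroring the
strong-diabetes / weak-others pattern the method is designed to probe.
Individual stages are available too:

```r
sig   <- denoise(cohort$signal[[1]])          # 0.5–40 Hz zero-phase FIR
peaks <- detect_qrs(sig)                      # derivative + refractory
subject_waveform_feature(sig, peaks)          # named 24-vector
fit   <- kmeans_lloyd(waveform_features(cohort), k = 2,
                      seed = 7, standardize = TRUE)
glance(fit)                                   # k, E, iterations, n
crosstab(fit, cohort_records(cohort))
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete analysis from scratch against the installed
package: it generates a fresh 60-subject synthetic cohort at the given
seed, extracts all three feature sets, clusters at k = 2, 4, 8, prints
the crosstab/metric report for every combination, and writes the JSON
results object to `--out`.
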