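---
title: "Methods: direct-infusion MS fingerprinting of manuscripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct-infusion MS fingerprinting of manuscripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the data model

A direct-infusion (DI) measurement produces, per sample, a short series of
MS1 scans with no chromatographic separation; each scan is a centroided
list of (m/z, intensity) pairs. The study design `msforge` targets has two
author classes, several documents per author, two substrates (ink stroke,
bare paper), about three technical replicates per document × substrate,
and solvent blanks. The question is whether the chemical fingerprint —
plasticizers, plant metabolites, ink components leached from the surface —
separates the two authors, and which ions carry that separation.

Assumptions baked into the pipeline:

* input spectra are centroided and positive-mode, singly charged;
* scan order is the only time axis (no retention-time structure);
* intensities are comparable across files only after normalization to
  total usable signal;
* missing features are truly absent or below detection, and are
  represented as explicit missing values until the statistics stage.

# Stage by stage

## Trace consolidation

Ions that matter are present across the infusion, not in a single scan.
All centroids from all scans of one file are pooled, sorted by m/z (ties:
scan-major), and clustered by the same greedy running-mean rule used for
alignment (below). A cluster seen in at least `min_scan_fraction` of scans
(default 0.5) becomes one peak with the mean member m/z and the mean
member intensity. One clustering algorithm therefore serves both the
within-file and the cross-file step; it is fully specified, deterministic,
and testable against a brute-force reimplementation, which is why we
prefer it over delegating to an external trace-detection tool whose
defaults we cannot pin.

## Normalization

Each file's intensities are divided by the file total ("total usable
signal") and scaled by 1000, so every sample sums to exactly 1000 relative
units. We normalize the consolidated trace list — i.e. after trace
detection, before alignment — reading "the resulting spectrum for each
file" as the consolidated one. Normalizing twice is an error rather than a
no-op, because the operation is only meaningful on raw counts.

## Greedy ppm alignment

Peaks of all files are pooled and sorted ascending by m/z; ties are broken
by sample id, then intensity descending (the sort had to be made total for
determinism). Scanning left to right, a peak joins the open peakset iff
its m/z is within `ppm_tol` (default 5 ppm) of the *running mean* of the
members admitted so far — the mean is updated after every admission, not
frozen at the first member. When a peak fails the test the peakset closes
and a new one opens. After all peaksets close, a file contributing more
than one peak to a peakset keeps only its most intense one (ties: lower
m/z); dedup does not feed back into the admission means.

A note on a property we assert in tests: within one peakset the pairwise
ppm spread is bounded by about twice the tolerance *when the data are
clustered*, i.e. true features separated by well over the tolerance with
per-file jitter well under it. The bound is not a theorem of the greedy
rule in general — on sorted input the running mean only drifts upward, and
an adversarial chain of peaks spaced near the tolerance can exceed 2×
slightly — so the property test generates the clustered regime the claim
is about (features ≥ 25 ppm apart, ~1 ppm jitter).

## Screening

Feature inclusion follows two rules: present in at least `min_present`
(default 3) non-blank samples, and absent from *every* solvent blank.
Differential statistics are computed on the unfiltered matrix so that
"absent from blanks" remains a meaningful per-feature flag alongside the
q-value; the diagnostic selection then takes q < 0.05 *and* blank-free.

Missing cells are imputed at 1e−5 (relative-intensity units, far below any
observed normalized intensity) and all values logged. Design choices the
method description leaves open, and what we chose:

* *t-test variant*: Welch (unequal variances) — the robust default when
  group sizes and spreads differ; configurable.
* *log base*: 10, the convention for MS intensities; the t statistic is
  scale-invariant so the base only affects reported means (asserted as a
  test property).
* *zero-variance groups*: p = 0 when the means differ, p = 1 when equal,
  avoiding NaN propagation from degenerate imputation patterns; groups
  with fewer than 2 values yield NA and are flagged rather than tested.
* *strata*: the default report combines ink and paper samples; per-stratum
  analyses are available as an option.

BH correction is the standard step-up procedure (`stats::p.adjust`),
cross-checked in tests against a hand-rolled implementation of
q(i) = min over j ≥ i of p(j)·m/rank(j).

## Classification

A hard-margin SVM cannot be requested literally from a soft-margin
library, so "hard margin" is emulated with penalty C = 1e8: identical to
the hard-margin solution whenever the data are separable, and numerically
robust when they are only quasi-separable. The RBF width uses the standard
scale heuristic γ = 1/(n_features · var(training values)), deterministic
and configurable (`gamma_mode = "fixed"`).

Cross validation is leave-one-document-out: all technical replicates (and
both substrates) of one document form the test set, so replicate
correlation can never leak across the split. Two further choices guard
statistical validity, both reversible with `paper_faithful = TRUE`:

* *Per-fold feature filtering.* The presence/blank rules are recomputed on
  each training fold; filtering once on the full data lets test-set
  presence influence the model's feature set. The faithful variant filters
  globally before CV.
* *Training-document balancing.* Holding out one document leaves its class
  under-represented in training (e.g. 4 vs 5 documents). A maximally
  overfit classifier then scores the held-out document systematically
  toward the over-represented class — an anti-learning artifact that
  drags the pooled AUC of a *signal-free* corpus far below 0.5. (Class
  weights do not help: at hard margin the penalty never binds.) The
  default therefore drops just enough documents of the over-represented
  class per fold to equalize document counts; the dropped documents are
  chosen by a stable hash keyed on the test document, so the procedure is
  deterministic and consumes no random numbers. Our null-corpus
  calibration tests assert the pooled AUC is back at chance under this
  scheme.

Out-of-fold decision values are pooled into one ROC curve, thresholding
with ties grouped; the trapezoidal area then equals the tie-corrected
Mann–Whitney AUC (asserted against a rank-statistic oracle). Pooling
real-valued scores rather than binary predictions is an interpretation:
with few documents a stepped ROC from binary votes cannot produce
intermediate AUC values, so scores are the only reading under which a
pooled ROC is informative. Scores are oriented so that larger values
favour the second author label in sorted order.

## Annotation

Monoisotopic masses are computed from a pinned element table (C
12.0000000, H 1.0078250319, N 14.0030740052, O 15.9949146221, P
30.97376151, S 31.97207069, K 38.9637069; electron 0.00054858 Da — values
pinned so tests are bit-stable). Adduct m/z is neutral mass plus the
adduct atom mass minus the electron mass, charge +1 only. A formula is
assigned the observed peak with the smallest |ppm error| within 5 ppm, or
nothing. The shipped diagnostic table carries the eight ions per author;
rows without a printed formula (including two suspected inorganic cluster
ions and one fractional-m/z ion) are carried unannotated, and a
schematic-figure ion whose relation to a tabulated one is unresolved is
kept out of the default candidate list (`in_table = 0`) rather than
silently merged. Ink calls are empirical marker lookups (iron gall
90.9479, ivory black 130.5259) at the same tolerance; both markers firing
in one sample is reported as a mixed-ink signature, not an error.

# The synthetic corpus generator

`generate_corpus()` emulates the sampling design: 2 authors × 5 documents
× {ink, paper} × 3 replicates + 4 blanks (64 files) by default. Its
components:

* ~300 background ions present in all real samples (not in blanks —
  solvent blanks see solvent chemistry, not manuscript chemistry), m/z
  drawn uniformly on 70–700 with ≥ 30 ppm mutual spacing so ground truth
  maps 1:1 onto aligned peaksets;
* 8 diagnostic ions per author at the shipped diagnostic table's m/z
  values, present only in that author's samples at `fold_change` (default
  8) times the baseline intensity scale, so annotation tests run on
  synthetic output unchanged;
* 20 blank contaminants present in all blanks, half of them also planted
  into 1–3 real samples so the blank filter is exercised on non-trivial
  cases;
* per-sample multiplicative lognormal intensity noise (sd 0.5 on the log
  scale), Gaussian m/z jitter (sd 1 ppm, well under half the alignment
  tolerance), and 10% missingness, with each diagnostic guaranteed present
  in ≥ 3 samples of its author so the planted truth stays detectable by
  construction.

Randomness is one seed for the global feature layout plus a per-file
substream keyed by a stable hash of the sample id, so adding a sample
never perturbs the others, and equal seeds give byte-identical corpora.
The generator emits raw (unnormalized) intensities to exercise the
normalization stage, and writes either the TSV dialect or minimal
centroided mzML.

What the generator deliberately does **not** model: isotope envelopes,
adduct correlations between features, chromatographic or spray-stability
drift, document-level random effects, heteroscedastic noise, and
instrument-specific m/z bias. Passing tests on synthetic corpora therefore
demonstrate that the algorithms are implemented correctly and calibrated
under the stated noise model — not that real manuscripts of any particular
pair of authors are separable; the study-scale performance on real data
depends on chemistry the generator does not imitate.

# Problem sizes used in the checks

The acceptance-style checks run the full pipeline on default-size corpora
(64 files, ~336 features) over 10 seeds for the signal condition and 10
for the null condition, plus 1000-instance randomized oracle comparisons
for alignment, BH and AUC; unit tests use a smaller 3-document corpus.
These sizes give stable pass/fail behaviour for the properties asserted
(separability, chance-level null AUC, FDR calibration, recall of planted
ions) while keeping the default suite fast.

# Known limitations

* Only two author classes; multiclass designs would need a different
  decision-score pooling scheme.
* The greedy alignment is order-dependent by construction; its mean-drift
  behaviour on adversarially spaced peaks is documented above.
* "Automatic kernel parameter tuning" is a fixed heuristic, not a search;
  no hyperparameter optimization is performed anywhere.
* The annotation stage matches formulae from a fixed embedded list; it
  does not generate candidate formulae from mass, score isotope patterns,
  or consult external databases.
* mzML support covers centroided MS1 only; profile data and MS2 scans are
  rejected or skipped by design.
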