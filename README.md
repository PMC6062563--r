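# msforge

Chemical authentication of handwritten documents from direct-infusion
nanospray mass spectra of ink and paper surface extracts.

Historic manuscripts are routinely forged, and stylistic authentication
requires scarce expertise. A minimally destructive alternative is to extract
a microliter-scale droplet from the document surface, infuse it directly
into a high-resolution mass spectrometer, and treat the resulting peak list
as a chemical fingerprint of the ink and paper. `msforge` implements the
full analysis for a two-author study design (genuine author vs. forger,
several documents each, ink and paper substrates, technical replicates,
solvent blanks):

1. **Spectrum processing** — centroided MS1 scans (mzML via `mzR`, or a
   simple TSV peak-list format) are consolidated into per-file *mass
   traces* (m/z values consistently present across the infusion), then
   normalized to *total usable signal*: every intensity is divided by the
   file total and scaled by 1000.
2. **Alignment** — peaks from all files are pooled, sorted by m/z, and
   collected greedily into cross-file *peaksets*: a peak joins the open
   peakset while |m/z − mean| / mean ≤ 5 ppm against the running mean; a
   file contributing several peaks to one peakset keeps only its most
   intense one. Peaksets become rows of a features × samples matrix with
   explicit missing values.
3. **Screening** — features are kept if present in ≥ 3 non-blank samples
   and absent from every solvent blank. Differential features between the
   authors are found by Welch t-tests on log₁₀ intensities (missing values
   imputed at 1e−5 before logging) with Benjamini–Hochberg FDR correction.
4. **Classification** — a hard-margin SVM with RBF kernel
   exp(−γ‖x−y‖²), γ = 1/(n_features · var), C = 1e8, evaluated by
   leave-one-document-out cross validation: all technical replicates of a
   document are held out together, feature filtering is recomputed inside
   each training fold, and training documents are class-balanced to avoid
   the grouped-CV anti-learning bias. Out-of-fold decision scores are
   pooled into one ROC curve; the trapezoidal AUC equals the tie-corrected
   Mann–Whitney statistic.
5. **Annotation** — diagnostic ions are matched against molecular formulae
   as [M+H]⁺ / [M+K]⁺ adducts (monoisotopic masses, electron mass
   subtracted, 5 ppm tolerance), and per-sample ink signatures are called
   from empirical marker ions (iron gall m/z 90.9479, ivory black
   m/z 130.5259; both at once indicates a mixed ink).
6. **Synthetic corpora** — `generate_corpus()` emits a deterministic,
   fully labelled two-author corpus (background ions, author-diagnostic
   ions, blank contaminants, ppm jitter, lognormal noise, missingness) so
   the entire pipeline is testable end to end; `generate_null_corpus()`
   removes the author signal for calibration checks.

## Worked example

```r
library(msforge)

gen <- generate_corpus(corpus_config(seed = 1), "demo")
cfg <- validate_run_config(list(manifest = "demo/manifest.csv",
                                out_dir = "demo_out", seed = 1))
run_all(cfg)
#> [manifest] 64 samples (4 blanks)
#> [load] read and normalized 64 files from demo
#> [align] 336 peaksets at 5 ppm
#> [screen] 316/336 features pass the presence/blank filter; 16 diagnostic (q < 0.05, blank-free)
#> [classify] 10 folds, pooled AUC 1.0000
#> [annotate] 8 formula assignments; ink calls for 60 samples
#> [done] summary written to demo_out/summary.json
```

The 64 samples are 2 authors × 5 documents × 2 substrates × 3 replicates
plus 4 solvent blanks. Of 336 aligned features, the 20 planted blank
contaminants are removed by the blank rule (316 remain); exactly the 16
planted author-diagnostic ions come out significant at Q < 0.05 and absent
from all blanks; and the pooled leave-one-document-out AUC is 1.0 because
each author's diagnostic ions separate the classes perfectly at the default
8-fold intensity effect.

Formula annotation of a diagnostic ion:

```r
match_formula(diagnostic_peaks()$mz, "C18H15O4P", adducts = "M+H")
#> C18H15O4P [M+H]+ : theoretical 327.0781, observed 327.0782 (+0.39 ppm)
```

The same machinery is scriptable from a shell through the bundled CLI
(`inst/scripts/msforge`): `simulate`, `extract-peaks`, `align`, `screen`,
`classify`, `annotate` and `run-all` subcommands, each a thin wrapper over
the functions above.

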