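# stresspipe

Perceived-stress detection from wrist-worn wearable signals, with an
emphasis on the question that matters for field deployments: **does a model
trained in the laboratory transfer to daily life better than a model
trained on noisy daily-life self-reports?**

`stresspipe` is a tidyverse-native R package for psychophysiologists and
digital-health researchers working with smartwatch recordings
(Empatica-E4-style exports: 4 Hz electrodermal activity, 4 Hz skin
temperature, 32 Hz tri-axial accelerometer, and an interbeat-interval
event list derived from PPG). It implements the full analysis chain:

1. **Preprocessing** — non-overlapping 2-minute windows; RR-interval
   artifact detection by the 20 % successive-difference rule (reference =
   last clean interval) with cubic-spline replacement; rejection of
   windows with more than 10 % flagged intervals; a deterministic
   rule-based EDA artifact screen (steep conductance step co-occurring
   with an accelerometer burst, or plausibility-bound breaches) on 5 s
   epochs; zero-phase low-pass tonic/phasic EDA split (0.05 Hz, order 4).
2. **Feature extraction** — 13 HRV features (mean RR, SDNN, RMSSD, pNN50,
   triangular index, TINN, VLF/LF/HF band powers of the 4 Hz-resampled
   tachogram periodogram, LF/HF, LF and HF spectral peaks, SDSD) plus 7
   features for each of the phasic and tonic EDA components (mean, SD,
   peak and strong-peak counts, 20th/80th percentiles, quartile
   deviation): 27 features per window, averaged to session level.
3. **Labeling** — 5-item ambulatory Perceived Stress Scale scoring
   `score = (7 − H) + (7 − C) + A + S + F`, binarized at 15
   (relaxed < 15 ≤ stressed), and known-context labels for lab protocol
   phases (baseline → relaxed, stressor → stressed, recovery excluded).
4. **Modeling** — correlation-based feature selection (rank or CFS subset
   search), random undersampling to exact class balance, train-fitted
   min-max normalization, and five classifiers (MLP 2×5, random forest
   with 100 trees, kNN k = 3, RBF SVM, logistic regression at 0.5) under
   stratified 10-fold CV, an 80/20 split, and lab→daily transfer. The
   five-way model matrix crosses training/testing environments with label
   families: **LLKC, LLSR, DDSR, LDKC, LDSR**.
5. **Synthetic study generator** — seeded, fully deterministic simulation
   of a lab (baseline/stressor/recovery) plus daily-life (EMA) cohort:
   sinusoid-plus-noise RR series with state-dependent mean and HF
   amplitude, tonic + Poisson-SCR EDA, motion/contact artifacts with
   ground-truth masks, and self-report label noise that is larger in the
   field than in the lab.

## Worked example

```r
library(stresspipe)
library(dplyr)

study <- simulate_study(study_design(n_participants = 14, n_daily_sessions = 4),
                        seed = 42)
study
#> <stress_study> 14 lab + 56 daily recordings, 98 labelled sessions

sess <- process_study(study)   # preprocess, extract, aggregate, join labels

res <- run_model_matrix(sess, classifiers = c("rf", "svm"),
                        modalities = c("hrv", "combined"), folds = 10, seed = 42)
res |> filter(eval_method != "split") |>
  select(model_type, eval_method, modality, classifier, accuracy, fold_sd, n_test)
#>    model_type eval_method modality classifier accuracy fold_sd n_test
#>  1 LLKC       cv          hrv      rf            100       0       28
#>  5 LLSR       cv          hrv      rf             95      10.5     42
#>  9 DDSR       cv          hrv      rf             58.8    25.5     56
#> 11 DDSR       cv          combined rf             65.7    24.1     56
#> 17 LDSR       transfer    hrv      rf             78.6    NA       56
#> 19 LDSR       transfer    combined rf             78.6    NA       56
#> # ... (20 rows in total)
```

Reading the output: laboratory models with known-context labels (LLKC)
separate the stressor from baseline essentially perfectly on this
synthetic cohort; daily-to-daily self-report models (DDSR) suffer from
the noisier field labels; and lab-trained self-report models tested in
the field (LDSR, 78.6 %) beat DDSR — the lab-to-field transfer effect the
package is built to study. `plot_model_matrix(res)` draws the matrix;
`tidy()` / `glance()` on any `result` entry give confusion counts and
headline numbers.

Sessions round-trip through plain CSV (`write_feature_table()` /
`read_feature_table()`, `write_e4_session()` / `read_e4_session()`), so
real E4 exports drop into the same pipeline via
`read_e4_session("<dir>", environment = "daily")`.

## Documentation

The methods vignette (`vignettes/stress-pipeline-methods.Rmd`) describes
the signal models, every tunable threshold with its default and unit,
what the synthetic generator does and does not emulate, and the
package's design decisions on ambiguous points (artifact reference
intervals, boundary conventions, leakage-free preprocessing order).
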