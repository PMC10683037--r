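# pwavebrs

Identification of the **atrial phenotype of Brugada syndrome (BrS)** from
the P-wave of a standard 12-lead ECG. BrS is conventionally diagnosed from a
ventricular signature (the coved-type ST elevation), which is intermittent
and often requires a sodium-channel-blocker challenge to unmask. BrS
patients also show subtle P-wave abnormalities — longer atrial
depolarization and a larger terminal force in lead V1 — even while the
ventricular pattern is concealed. `pwavebrs` implements, as a tested R
package, the full analysis chain needed to ask whether the P-wave alone
separates BrS-positive from BrS-negative subjects, together with a synthetic
12-lead ECG cohort generator so that every stage is verifiable without
clinical recordings.

The pipeline, per subject:

1. zero-phase mains notch (50/60 Hz, Q ≈ 30) and 5th-order Chebyshev type I
   low-pass at 100 Hz;
2. segmentation into 15 s epochs (a 30 s–5 min recording yields 2–20
   epochs);
3. Pan–Tompkins-style R-peak detection on lead II;
4. per beat, a 300 ms P-window starting 350 ms before the R-peak; per lead,
   cross-correlation template selection, rejection of ectopic/noisy beats
   (peak correlation < 0.8), alignment at the optimal lag (±50 ms) and
   sample-wise averaging;
5. 67 features per epoch: P duration, PR interval, terminal force in V1
   (PTFV1 = |depth| × |duration| of the terminal negative deflection,
   µV·s), FWHM and P axis (5 global); area, peak count, maximum amplitude,
   histogram entropy and sample entropy for each of the 12 leads (60
   local); age and sex;
6. Mann–Whitney/Fisher group statistics with Bonferroni correction over the
   65 feature comparisons;
7. a classifier benchmark — KNN, SVM, decision tree, random forest,
   bagging, majority voting, stacking, AdaBoost, gradient boosting × seven
   imbalance treatments (none, random oversampling, SMOTE, SVM-SMOTE,
   Borderline-SMOTE, ADASYN, class weighting) — under a strictly
   patient-wise, age/sex-matched 80/20 split with patient-grouped 10-fold
   CV tuning on the positive-class F1.

See `vignettes/pwave-methods.Rmd` for the measurement conventions, the
simulator's assumptions, and the design decisions.

## Worked example

A noise-free cohort at study scale (79 positive / 44 negative subjects,
30 s recordings — about two minutes end to end):

```r
library(pwavebrs)

spec   <- cohort_spec(n_pos = 79, n_neg = 44, duration_range = c(30, 30),
                      noise = noise_free(), seed = 1)
cohort <- generate_cohort(spec)
feats  <- cohort_features(cohort)     # 246 observations x 67 features

tab <- compare_features(feats)
tab[tab$lead == "global", c("feature", "positive", "negative", "p_value", "significant")]
#>      feature        positive         negative  p_value significant
#>  duration_ms   139 (128-148)    126 (117-137) 3.53e-08        TRUE
#>        pr_ms   185 (171-197)    174 (165-187) 6.42e-04        TRUE
#>     ptfv1_au 2.17 (1.57-2.8)  1.6 (1.26-2.02) 5.27e-07        TRUE
#>      fwhm_ms      66 (60-72)       61 (55-67) 8.22e-05        TRUE
#>     axis_deg    65 (59-68.5) 62.8 (55.2-67.8) 1.17e-01       FALSE

cfg <- benchmark_config(models = c("svm", "bagging", "adaboost"),
                        balancing = c("none", "weight"), folds = 10, seed = 1)
run_benchmark(feats, cfg)
#>     model balancing accuracy sensitivity specificity   mf1   wf1 note
#>       svm      none    84.0%       93.8%       66.7% 81.6% 83.5%
#>       svm    weight    80.0%       81.2%       77.8% 78.8% 80.2%
#>   bagging      none    84.0%       93.8%       66.7% 81.6% 83.5%
#>   bagging    weight    64.0%       75.0%       44.4% 59.9% 63.5%
#>  adaboost      none    76.0%       84.4%       61.1% 73.3% 75.7%
#>  adaboost    weight    82.0%       93.8%       61.1% 79.0% 81.2%
```

Each comparison row prints the per-class `median (25–75 percentile)`; the
`significant` flag applies the Bonferroni-corrected threshold 0.05/65 ≈
0.00077. The generated classes differ in P duration (medians 136 vs 124 ms
by construction, recovered as 139 vs 126 here) and in the V1 terminal
force — the same discriminators reported for real BrS cohorts — and the
benchmark metrics are computed on a held-out, age/sex-matched test set that
shares no patient with training.

`run_pipeline("out_dir", spec)` executes the whole chain and writes the
feature table, both statistics tables, the benchmark report and a manifest
with seed, config hash and attrition counts. A command-line wrapper with
`synth`/`features`/`stats`/`benchmark`/`all` subcommands is installed at
`inst/cli/pwavebrs.R`.

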