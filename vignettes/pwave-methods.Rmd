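---
title: "Signal-averaged P-wave analysis for Brugada syndrome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-averaged P-wave analysis for Brugada syndrome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwavebrs)
```

## The problem

Brugada syndrome (BrS) is diagnosed from a ventricular ECG signature — the
coved-type ST elevation in the right precordial leads — which is intermittent
and often only unmasked by a sodium-channel-blocker challenge. BrS patients,
however, also carry an *atrial* phenotype: subtly abnormal P-waves (longer
duration, larger terminal force in V1) even while the ventricular pattern is
concealed. `pwavebrs` implements a complete pipeline that asks whether the
P-wave alone carries enough information to identify BrS: epoch-wise P-wave
signal averaging, morphological/entropy feature extraction, group statistics,
and a patient-wise classifier benchmark. Because no public recordings exist
for this task, the package ships a parametric 12-lead ECG simulator whose
ground truth makes every stage testable.

## The pipeline

1. **Conditioning.** Mains interference is removed with a zero-phase biquad
   notch (Q ≈ 30, 50 or 60 Hz); residual noise with a 5th-order Chebyshev
   type I low-pass (0.5 dB ripple, 100 Hz cutoff), applied forward–backward.
   Zero-phase filtering matters: a causal filter would shift wave onsets,
   and all downstream features are timing-sensitive. A true adaptive mains
   canceller would only pay off on drifting real-world interference; on a
   fixed-frequency tone the notch is equivalent and simpler.
2. **Epoching.** The filtered recording is cut into contiguous 15 s epochs
   (half-open intervals, trailing partial epochs discarded so averaged-P
   quality is uniform). A 30 s recording yields 2 epochs, a 5 min recording
   20 — hence 2–20 observations per subject.
3. **R-peak detection** on lead II (the conventional rhythm lead) with the
   canonical Pan–Tompkins stages: 5–15 Hz band-pass, derivative, squaring,
   150 ms moving-window integration, adaptive signal/noise thresholds with a
   200 ms refractory period. The integrator window is centered so that —
   with the zero-phase band-pass — no group-delay correction is needed.
4. **P-window extraction.** Each beat contributes a 300 ms window starting
   350 ms before its R-peak; windows that would start before the epoch are
   skipped.
5. **Template matching.** Per lead, every window is tried as template; the
   one with the highest mean peak cross-correlation against the others wins.
   Correlation is Pearson on the overlapping samples, maximized over lags
   bounded to ±50 ms: unnormalized correlation would confound amplitude
   with similarity, and an unbounded lag lets the matcher lock onto QRS
   remnants. Windows correlating below 0.8 with the template (ectopic atrial
   beats, noise bursts) are rejected; survivors are shifted to their optimal
   lag and averaged sample-wise, window edges not covered by any shifted
   beat taking the template's samples.
6. **Features (67).** Five global: P duration, PR interval, terminal force
   in V1 (PTFV1), FWHM, P axis. Five per lead (60 local): area, peak count,
   maximum amplitude, histogram entropy, sample entropy. Plus age and sex.
7. **Statistics.** Mann–Whitney U per feature, Fisher's exact test for
   categorical tables, Bonferroni correction over the 65 feature
   comparisons (threshold 0.05/65 ≈ 0.00077).
8. **Benchmark.** Patient-wise 80/20 split (no subject spans partitions;
   the test set is age- and sex-matched between classes), nine classifiers
   (KNN, SVM, decision tree, random forest, bagging, majority voting,
   stacking, AdaBoost with 50 depth-limited trees, gradient boosting),
   seven imbalance treatments (none, random oversampling, SMOTE, SVM-SMOTE,
   Borderline-SMOTE, ADASYN, class weighting), hyperparameters tuned by
   patient-grouped 10-fold CV on the positive-class F1.

## Measurement conventions

The source of essentially all measurement ambiguity is that clinical P-wave
"duration" has no single operational definition. The package uses one
convention end to end:

* **Duration** is the support of the smoothed (5 ms moving average) RMS
  composite across the 12 leads above 5% of its peak. The simulator defines
  its duration parameter as the support of the Gaussian P kernel at the same
  5% relative threshold, so generated and measured durations are directly
  comparable.
* **Delineation** scans outward from the composite peak rather than taking
  the first/last suprathreshold crossing in the window, and the peak search
  starts 70 ms into the window. Both guards exist for short RR intervals,
  where the tail of the *preceding T-wave* enters the start of the P window:
  a naive first-crossing rule latches onto it and can report nonsense
  durations (a P peaking earlier than 70 ms into this window would sit
  > 280 ms before the QRS, outside any physiologic PR interval).
* **PR interval** runs from the delineated P onset to the QRS onset, the
  latter found by backtracking the same 5% rule on the RMS composite from
  the R-peak. The simulator computes its ground-truth QRS onset with the
  identical rule, keeping the two PR definitions consistent.
* **PTFV1** is |depth| × |duration| of the terminal negative P deflection
  in V1 (µV·s, the "au" of the clinical tables); deflections shallower than
  5% of the V1 peak count as monophasic (value 0).
* **Entropy** is Shannon entropy of the amplitude histogram over 22 uniform
  bins between the segment's min and max (natural log — uniform profiles
  approach ln 22 ≈ 3.09, the magnitude clinical reports show). **Sample
  entropy** uses m = 2, r = 0.2 × SD, the physiological-time-series default;
  it is computed by a vectorized routine that replicates
  `pracma::sample_entropy` exactly (verified to machine precision in the
  tests) at ~60× its speed.
* Gain invariance: entropies, widths, counts and axis are unchanged under
  signal rescaling; area, amplitude and PTFV1 scale linearly. The tests
  assert this.

## The simulator and what it does (not) emulate

Each beat is a sum of Gaussian kernels per lead (P, Q, R, S, T), with a
biphasic P in V1 (positive lobe plus terminal negative deflection). This is
deliberately the simplest model whose parameters map one-to-one onto the
measured features — not a dipole/torso model, and not intended to look
clinically realistic beat-to-beat.

Defaults encode the study conditions: 79 positive vs 44 negative subjects;
P-duration medians 136 vs 124 ms (SD 15 ms ≈ IQR/1.349); terminal-force
medians 2.5 vs 1.7 µV·s; per-lead P amplitudes at the published per-class
medians; PR 177 vs 170 ms; heart rate 82 ± 12 vs 78 ± 10 bpm; age 47 ± 14 vs
36 ± 14; male fraction 0.696 vs 0.636; recordings 30 s–5 min at 1 kHz. The
PR draw is floored at P duration + 30 ms: a P-wave must end a realistic PR
segment before the QRS (unconstrained draws produce P-waves overlapping the
QRS, which are both unphysiological and unmeasurable in an R-locked window).
Noise defaults (50 Hz mains 0.02 mV, 0.25 Hz wander 0.05 mV, broadband SD
0.01 mV, ectopic probability 0.02/beat) are *placeholders*: clinical
reports do not characterize the recordings' noise floor, so these are set
to plausible post-filter magnitudes and should be treated as free
parameters, not as facts about clinical data. Ectopic beats are rendered with an inverted, advanced P
solely to exercise the correlation-rejection stage.

What passing tests on this cohort demonstrates is therefore *method
correctness* — parameter recovery, leak-free evaluation, metric identities —
not clinical performance: real P-waves vary within subject, noise is
non-stationary and lead placement differs; none of that is emulated.

## Numerical choices and degenerate inputs

* Filters come from the `signal` package; `filtfilt` supplies zero phase.
* Cross-correlation ties break to the lowest beat index; the template is
  always retained regardless of threshold.
* Epochs with fewer than 2 detected beats yield no observation; epochs
  retaining fewer than 3 beats in any lead are flagged low-quality
  (configurably droppable). Flat windows, composite peaks under 10 µV, or
  an undefined axis (both net limb areas zero) invalidate the observation —
  exclusion, never imputation.
* Constant segments get entropy 0 and sample entropy 0 with a flag; SMOTE
  variants fall back to random oversampling (with a warning) when the
  minority class is smaller than the neighbourhood.
* The Q = 30 notch's ring-down under the P offset biases measured duration
  by about −3 ms on clean signals (QRS energy at 50 Hz is redistributed by
  the notch). The bias is small and class-symmetric, and is accepted.

## Problem sizes

The test-suite and acceptance-script cohorts use 30 s recordings (the
clinical minimum length, 2 epochs/subject) at the full 79/44 subject count,
and benchmark subsets of the roster; these sizes were chosen as the smallest
that still exercise every stage at study scale. The simulator's own default
remains 30–300 s.

## Known limitations

* Per-lead (not global) beat rejection: a beat rejected in lead V1 may still
  contribute to lead II's average. The shared information is the R-peak set
  only.
* The delineation threshold (5%) is the largest single source of deviation
  from any particular clinical measurement convention; it is exposed as a
  parameter.
* The Bonferroni default divides by the 65 feature comparisons actually
  run; published thresholds in this literature sometimes imply 66. The
  corrected threshold is printed in the output rather than silently matched.
* WFDB/EDF containers are not read in this build; recordings travel as
  delimited tables with a JSON sidecar.
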