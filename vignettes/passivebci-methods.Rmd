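---
title: "Passive-BCI neurometrics: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive-BCI neurometrics: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passivebci)
```

## What this package computes

`passivebci` implements an offline analysis pipeline for passive
brain-computer interfaces that monitor three human factors — mental
workload, stress and vigilance — from an eight-channel frontal/parietal
EEG montage (AFz, AF3, AF4, AF7, AF8, Pz, P3, P4). The pipeline has five
stages:

1. **Preprocessing** — zero-phase fifth-order Butterworth band-pass
   (2–30 Hz), template-based blink detection on the frontal channels,
   multi-channel Wiener-filter (MWF) subtraction of the ocular component,
   segmentation into 1-s epochs, and rejection of any epoch exceeding
   ±80 µV on any channel.
2. **Spectral analysis** — Welch power spectral densities with Hann
   windows matched to the 1-s epoch length; estimation of the individual
   alpha frequency (IAF) from the closed-eyes resting spectrum; frequency
   bands anchored on the IAF: theta `[IAF−6, IAF−2)`, alpha
   `[IAF−2, IAF+2)`, beta `[IAF+2, IAF+16)` and high beta
   `[IAF+11, IAF+16)` Hz. Band powers are PSD integrals per channel;
   the global field power (GFP) of a channel set is their arithmetic
   mean.
3. **Neurometrics** — workload = frontal-theta GFP (AF7, AF8, AF3, AF4,
   AFz) divided by parietal-alpha GFP (P3, P4, Pz); stress =
   parietal-high-beta GFP (P3, P4); vigilance = the negated
   right-frontal-beta GFP (AF4, AF8), so that vigilance decrement (beta
   rise) lowers the index.
4. **Classification** — per-subject Random-Forest classifiers on
   per-epoch GFP features (8 features for workload, 2 for stress and
   vigilance), with ADASYN oversampling of an imbalanced training class,
   hyperparameters searched over 50–500 trees and depth 1–50, and AUC
   evaluated after averaging the per-second probability scores over
   windows of T = 1…60 s. Calibration is run-split (train on one
   repetition, test on the other, both directions averaged) when two
   repetitions per condition exist, and 3-fold cross-validation with
   contiguous time blocks otherwise. Cross-task transfer trains on one
   task and scores another, and score traces are compared by Pearson
   correlation and RMSE.
5. **Signal quality** — for paired recordings from two systems:
   impedance trajectories interpolated to a 10-min grid over 40 min with
   Wilcoxon signed-rank tests against baseline (Bonferroni over the four
   later timepoints), frontal/parietal artifact percentages with paired
   tests, and per-channel per-band Pearson correlations of the open-eyes
   spectra thresholded at the critical r for the Bonferroni-corrected
   alpha (0.05/20 = 0.0025).

Because no public recordings accompany the protocol this pipeline
targets, the package ships a synthetic session generator with full
ground truth; every contract above is validated against it.

## The synthetic session model

`simulate_session()` builds each recording as

$$x_c(t) = \sum_{s} a_s\, g_{cs}\, \gamma_s(t)\, u_{cs}(t) + \sigma_n\, n_c(t) + \text{blinks} + \text{artifacts},$$

with four oscillatory sources $s$ (frontal theta, parietal alpha centred
on the configured IAF, right-frontal beta, parietal high beta), fixed
topographic gains $g_{cs}$, per-source RMS amplitudes $a_s$, a
per-sample condition gain $\gamma_s(t)$ determined by the run plan, and
1/f background noise $n_c$. Key modelling choices:

* **Sources are narrowband noise, not sinusoids.** Each source is white
  noise band-passed to its band (the alpha source to IAF ± 1 Hz so its
  spectral bump peaks at the IAF). Narrowband noise carries a stochastic
  amplitude envelope decorrelating within ~1/bandwidth seconds — fast
  enough that run-averaged power is stable. An explicit slower envelope
  was deliberately **not** added: modulation on the scale of a run acts
  as a random confound of the condition effect and makes long-window
  AUC seed-dependent in both directions.
* **Deterministic normalization.** Sources and noise are scaled by the
  analytic white-noise gain of their shaping filters, not by the
  realized session standard deviation. Normalizing by the realized SD
  pins the total session power and forces per-run mean powers to
  anti-correlate — a compositional constraint that would act as a
  spurious condition effect at long temporal resolutions.
* **Partial spatial coherence (0.45).** Channels driven by the same
  rhythm mix a shared component with channel-specific components.
  Nearby electrodes are strongly but not perfectly coherent within a
  band; a rank-1 source would make multi-channel features fully
  redundant, capping single-epoch discriminability at the
  time-bandwidth limit of one source.
* **Condition effects.** During "high workload" runs theta power is
  multiplied by the effect factor and alpha power divided by it; "high
  stress" multiplies high-beta; "low vigilance" multiplies right-frontal
  beta (vigilance decrement = beta rise). The closed-eyes rest boosts
  alpha power (factor 6) to produce the resting alpha peak used for IAF
  estimation.
* **Artifacts.** Blinks are a 300-ms half-sine template with
  frontal-dominant topography (AFz/AF3/AF4 > AF7/AF8 ≫ parietal),
  ±20% amplitude jitter, 120 µV default peak — a realistic frontal
  blink amplitude, and large enough that the MWF has a well-defined
  component to estimate. Gross artifacts are square pulses of
  120–300 µV lasting 0.2–0.8 s, guaranteeing known rejection ground
  truth at the ±80 µV criterion; the generator records which 1-s epochs
  exceed the threshold by construction.

### Reference conditions and amplitude calibration

The default run plan is the reference study structure: 1 min closed
eyes, 1 min open eyes, then two repetitions of paired low/high 60-s runs
for each construct. The default effect factor is 1.5 per construct.
Source amplitudes (theta 7.5, alpha 8.5, beta 6, high beta 5 µV RMS)
and background level (5.5 µV RMS, 1/f) were chosen so that single-epoch
discriminability under factor 1.5 mirrors what passive-BCI studies
report on real data — AUC roughly 0.7–0.8 at 1-s resolution, rising
above 0.9 once scores are averaged over ~10 s. These are generator
design constants, fixed once; tests and the acceptance script treat them
as the study conditions.

What the generator does **not** emulate: volume-conduction head
modelling, EMG/ECG artifact families, line noise, electrode drift in the
signal (only in the impedance logs), non-stationary fatigue trends, and
inter-subject topography variability beyond the IAF. Passing tests
therefore demonstrate the pipeline's internal correctness and its
behaviour under controlled, favourable signal models — not performance
on real recordings.

## Numerical and procedural choices

* **Zero-phase filtering.** All analyses are offline; causal filtering
  would bias band powers near run boundaries with phase distortion. The
  forward–backward pass has the squared magnitude of the one-pass design
  (effective order 10). The filter runs as cascaded second-order
  sections with odd-reflection padding: the expanded order-10
  polynomial is numerically ill-conditioned, and plain zero padding
  leaves large boundary transients. Linearity holds to ~1e-13 relative.
* **Blink-detector stand-in.** The published detector this stage mirrors
  is proprietary; the stand-in cross-correlates the mean frontal channel
  with the blink template *as it appears after the 2–30 Hz band-pass*
  (a raw half-sine mismatches badly — its ~1.7 Hz fundamental is
  filtered out), thresholds the trace at 4 robust SDs, requires
  candidate events to be ≥ 5 robust SDs and ≥ 15 µV in amplitude
  (blinks have a physical scale; a purely adaptive threshold fires on
  blink-free records), and suppresses matched-filter sidelobes within
  two template lengths of a stronger detection.
* **MWF.** One spatial (lag-0) covariance pair: `Ryy` from blink
  samples, `Rvv` from the rest; `Rdd = Ryy − Rvv` eigenvalue-clipped to
  positive semidefinite; the estimated ocular component `(Ryy⁻¹Rdd)ᵀ y`
  is subtracted within the blink intervals, so samples outside them are
  untouched by construction. High-amplitude non-ocular artifacts should
  be left to the ±80 µV rejection stage — a 300 µV channel pop inside a
  blink interval corrupts the covariance contrast.
* **Epoch labels by midpoint.** Deterministic and order-independent;
  an epoch straddling a condition boundary takes the midpoint's label.
* **Rejection is strict.** `|v| > 80 µV` rejects; exactly 80.0 µV is
  retained (the criterion names the permitted range).
* **Band integration.** Trapezoid rule over the closed band interval
  with linear interpolation at fractional edges, so a flat density c
  over width w integrates to exactly c·w. A band edge shared by two
  adjacent bands contributes half weight to each — equivalent in effect
  to the half-open labelling of shared edges, without under-counting
  the interior. High beta is a sub-band of beta; that overlap is by
  definition.
* **IAF.** Peak of the channel-averaged PSD in 7–13 Hz, refined by
  parabolic interpolation; fallback to 10 Hz with a low-confidence flag
  when the window has no interior local maximum or the peak sits on the
  boundary; an exact tie returns the lower frequency, flagged. The
  fixed comparison bands (theta 3–7 Hz) and the IAF formulas at IAF = 10
  (theta 4–8 Hz) disagree by 1 Hz by design of their sources; both
  schemes are provided and callers choose — the package does not
  reconcile them.
* **GFP convention.** Channel-set aggregation is the arithmetic mean
  (not the sum), making the 5-channel workload numerator and 3-channel
  denominator comparable in scale; configurable at the call sites that
  aggregate.
* **Workload denominator guard.** ε = 1e-12 µV² with a warning;
  heavily rejected short windows can produce near-zero alpha power.
* **Temporal aggregation acts on scores, not features.** One model is
  evaluated at all resolutions, which is only possible post hoc on its
  per-second probabilities; window label = the run's condition; trailing
  partial windows are dropped. Resolutions longer than a run's retained
  epochs yield `NA` rather than a value from partial windows.
* **ADASYN after the split, training side only** — synthetic rows must
  never leak into evaluation. Synthetic rows carry `NA` run/time ids so
  they can never enter a test fold.
* **Grid search.** The 50–500 tree and 1–50 depth ranges are searched on
  a coarse grid ({50, 150, 300, 500} × {1, 3, 5, 10, 25, 50}) with an
  inner 3-fold stratified split; ties resolve to the first (smallest)
  entry; fixed seeds make selection deterministic.
* **k-fold folds are contiguous time blocks** within each run, limiting
  temporal-autocorrelation leakage between training and test.
* **Run-split directions are both evaluated and averaged**; the
  procedure's two directions are reported individually in the returned
  object.
* **AUC** is the Mann–Whitney probability with ties counted ½ —
  validated against exhaustive pair counting.
* **Wilcoxon signed-rank**: zeros discarded, average ranks for ties,
  exact permutation distribution (dynamic programming over sign
  assignments) up to n = 25, normal approximation with continuity and
  tie corrections above — validated against exhaustive sign-flip
  enumeration and against `stats::wilcox.test`.
* **Spectral-agreement threshold.** The critical r is recomputed from
  (α, number of band bins) at run time via the t-distribution of
  Pearson's r; the conventional printed value 0.423 (α = 0.0025,
  ~49 bins) is retained as a labelled reference constant. The
  open-eyes comparison uses 4-s Welch windows (0.25 Hz bins) so each
  band holds enough bins (16–52) for a meaningful correlation; at 1-Hz
  resolution theta would have 4 bins and a critical r near 1.
* **Impedance rules.** Linear interpolation only within the measured
  span (no extrapolation); acceptability uses strict `<` against
  40 kΩ (gel) and 100 kΩ (water).

## Validation design and problem sizes

The test suite generates all data in code. The heavier simulation checks
run at reduced but statistically meaningful sizes, chosen as fixed
design points: IAF recovery over 100 closed-eyes sessions with bump
centres uniform in 8–12 Hz (mean absolute error < 0.25 Hz);
discrimination on 10 simulated subjects under the reference conditions
(median run-split AUC at T = 10 s above 0.9 for each construct);
type-I control on 20 null-effect seeds, averaging the AUC over seeds and
constructs at every T (band 0.4–0.6; at terminal resolutions each run
contributes a single window, so per-seed values are heavily quantized
and only the average is a stable statistic); cross-task transfer on
12 matched and 8 direction-reversed seed pairs. Both arms keep the full
contamination model; a session contributes nothing at a resolution whose
windows are incomplete after rejection (`NA`), and averages skip those
entries. Equivalence
oracles (pairwise AUC counting, sign-flip enumeration, brute-force
window means) run exhaustively at small n, where exhaustiveness is
cheap.

Determinism is part of the contract: identical configuration and seed
reproduce sessions bit for bit and pipeline outputs byte for byte; all
randomness is routed through explicitly derived child seeds, and the
Random-Forest backend runs single-threaded with a fixed seed.

## Known limitations

* The ±80 µV ground-truth epochs are defined on the raw generated
  signal; after filtering and MWF correction the pipeline's rejected set
  can legitimately differ on epochs whose peak is near the threshold
  (blink epochs, for instance, are corrected rather than rejected).
* The blink detector's recall on realistic sessions is ~0.8 at the
  default settings; the MWF contract is therefore validated with
  ground-truth intervals, and residual undetected blinks fall through to
  amplitude rejection.
* `estimate_iaf` assumes a single dominant alpha peak; split alpha peaks
  return the lower one with a low-confidence flag.
* Cross-subject calibration, online/streaming inference, source
  localization and multitaper spectra are out of scope.
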