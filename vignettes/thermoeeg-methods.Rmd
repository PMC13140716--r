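---
title: "Methods: staged cold-exposure EEG analysis with thermoeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged cold-exposure EEG analysis with thermoeeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoeeg)
```

## The analysis problem

Whole-body cold exposure engages the cortex in stages: a thermoneutral
baseline (NC), the first minutes of still-air cold (CE), the onset of cold
wind (WE), a habituation plateau (HB), and rewarming after exit (PR).
`thermoeeg` implements a complete analysis chain for multichannel EEG
recorded across such a protocol:

1. **Features** per 1-s window and channel: signed mean amplitude, absolute
   band power $P_x = \frac{1}{n}\sum_{k=1}^n S_k^2$ of the band-limited
   signal for $x \in \{\delta, \theta, \alpha, \beta\}$, relative power
   $PR_x = P_x / (P_\delta + P_\theta + P_\alpha + P_\beta)$, and the Hjorth
   parameters (activity, mobility, complexity). Skin physiology is reduced
   to the eight-site weighted average skin temperature,
   $\mathrm{WAST} = 0.070\,T_{head} + 0.175\,(T_{chest}+T_{shoulder}) +
   0.070\,(T_{upperarm}+T_{forearm}) + 0.050\,T_{hand} + 0.190\,T_{thigh} +
   0.200\,T_{calf}$, whose weights sum to exactly 1.
2. **Statistics**: a condition-pooling check, then a per-channel stage
   battery (one-way repeated-measures ANOVA with partial $\eta^2$, Welch's
   heteroscedastic ANOVA as the assumption-gated fallback),
   Benjamini–Hochberg correction across the channel family, and the a
   priori sample-size computation for the design.
3. **Channel specificity**: one-vs-rest classifiers (random forest, SVM,
   MLP) on windowed mean-amplitude features with subject-grouped
   cross-validation, per-channel Shapley attributions of the classifier
   score, and the consensus (intersection) of the FDR-significant channel
   set with the top-$k$ important channels.
4. **Latency**: per-subject response onset by (i) short-time Fourier
   band-power deviation from baseline and (ii) reconstruction-error
   exceedance of a participant-specific autoencoder trained only on
   baseline windows.

Because raw recordings of this kind are rarely shareable, the package
ships a synthetic cohort generator with closed-form spectral ground truth;
every recovery claim in the test suite is made against quantities the
generator can state exactly.

## The synthetic cohort generator

Each channel is synthesized in the frequency domain as 1/f-shaped Gaussian
noise (exponent 1) split across delta (0.5–4 Hz), theta (4–7 Hz), the 7–8 Hz
gap, alpha (8–12 Hz) and beta (12–30 Hz), plus one narrowband oscillation
per band and a flat measurement-noise floor. Spectral gains are normalized
so the expected mean-square amplitude per band equals its target exactly;
the default targets put total power at 100 µV² with relative alpha ≈ 0.4 at
baseline, the scale real stage tables report.

Design choices that matter:

* **Oscillation model.** Band oscillations are constant-amplitude carriers
  with a *phase-diffusing* (random-walk) phase, Lorentzian linewidth
  0.15 Hz. Two properties motivated this: frame-level band power stays
  nearly constant (an amplitude-stable rhythm), while the phase
  decorrelates over seconds, so short windows sample every phase — both
  are properties of real cortical rhythms, and both detectors depend on
  them. A fixed-phase sinusoid fails pathologically: at some sampling
  rates 50-ms windows sample only two phases, and any new segment falls
  off the training manifold of a baseline-trained autoencoder.
* **Measurement-noise floor** (`white_noise_uv = 2`, i.e. 4 µV² ≈ 4% of
  total power) models amplifier and residual-artifact noise. Without it
  the signal is a noiseless smooth manifold and autoencoder residuals are
  dominated by heterogeneous capacity error, which makes a Gaussian
  mean + 3 SD threshold uncalibratable.
* **Stage effects.** The alpha amplitude on 14 designated channels is
  multiplied per stage (defaults CE 0.74, WE 0.60, HB 0.81, PR 0.74,
  derived by inverting the relative-alpha stage means reported for real
  cohorts through $PR' = m^2 PR / (1 - PR + m^2 PR)$), so the expected
  alpha-power stage/baseline ratio is exactly $m^2$. An optional per-stage
  mean-amplitude shift (`offset_uv`) exists because windowed *signed
  means* — the classifier feature — are analytically insensitive to
  band-power changes; classifier-recovery tests inject a 3–6 µV shift, the
  magnitude real stage tables show.
* **Onsets.** `generate_onset_segment()` switches from baseline to stage
  parameters instantaneously at the configured onset (defaults CE 0.5 s,
  WE 2 s, PR 1 s), so true latency is unambiguous; a linear cross-fade is
  available behind `onset_ramp_s`.
* **Seeds.** One master seed; per-subject/stage/purpose substreams are
  derived by a fixed affine counter modulo $2^{31}-19$, making cohorts
  bit-reproducible.
* **Condition structure.** Subjects are allocated 3/3/3/3/3/2/3 across
  seven ambient-temperature/wind conditions. By default conditions affect
  only the physiology drift rates (via a severity factor computed from
  temperature and wind), not the EEG — matching the pooled analysis the
  statistics assume; `condition_offsets_uv` can inject an EEG condition
  effect for power studies.

What the generator does *not* emulate: ocular/muscle artifacts, shivering
EMG, burst-like alpha amplitude modulation, volume-conduction correlations
between channels, or biophysically grounded topographies. Passing recovery
tests therefore demonstrate the correctness of the analysis chain under the
stated statistical structure, not robustness to real-world artifacts.

## Preprocessing

The 0.1–30 Hz zero-phase bandpass is realized as a cascade: a 10th-order
Butterworth low-pass with its prototype cutoff 27% above the upper edge,
and a 2nd-order high-pass at 0.1 Hz, each applied forward–backward. A
single band-pass section is numerically unstable in transfer-function form
when the low edge sits four decades below Nyquist, and a conventional
low-order low-pass at exactly 30 Hz attenuates the band edge so strongly
that repeated filtering changes beta-band power by several percent. The
cascade keeps the passband flat through 30 Hz (gain ≈ 0.99), suppresses
50 Hz below 1% and reaches −44 dB one octave above the edge; re-filtering
changes band powers by well under 2%.

Bad channels are repaired by the unweighted mean of their montage
neighbours (pairs within 1.65 units on the schematic flat 10-20 layout;
every channel of the default 30-channel montage has at least two
neighbours). Windowing into 1-s segments drops a trailing partial second.

## Band power

`band_power()` offers two routes. The default Fourier route sums the
periodogram over the half-open band $(low, high]$; by Parseval this is the
mean square of the in-band component. The time-domain route isolates the
band with an *ideal zero-phase band selector* (spectral masking) and takes
the mean square of the filtered samples. A recursive (Butterworth-family)
band isolator was measured and rejected: on the 4-Hz-wide alpha band its
in-band attenuation reaches ~30% (a unit 10-Hz sinusoid returns 0.35
instead of 0.5), which would bias narrow-band powers and break the
equivalence between the two routes.

## The statistical battery

* `rm_anova()` computes the classical subject × stage decomposition
  ($df = (m-1), (n-1)(m-1)$; partial
  $\eta^2 = SS_{stage}/(SS_{stage}+SS_{error})$). With 20 subjects and 5
  stages the design df are (4, 76).
* `channel_battery()` gates on Mauchly's sphericity test and Levene's
  variance test at $\alpha = 0.05$: channels failing either are tested
  with Welch's ANOVA instead, and both results are always reported. BH
  correction runs across the channel family and significance is called at
  FDR-corrected $p < 0.05$.
* `pooling_check()` reports, per stage, Shapiro–Wilk (on centred
  residuals), Levene, the classical one-way F and Welch's F across
  conditions, on per-subject mean amplitudes. The poolability flag gates
  on the *classical* F after BH correction across the stage family:
  simulation at the exact 3/3/3/3/3/2/3 allocation shows Welch's test
  rejects 10.4% of null cohorts at nominal 5% (variance estimates from 2–3
  observations), while the classical F is exact under the normality the
  Shapiro gate verifies (measured 4.4%). Welch's statistics remain in the
  report. Levene's test is reported as `NA` when every group has ≤ 2
  observations (its auxiliary ANOVA is degenerate there).
* `rm_sample_size()` implements the standard within-factors noncentral-F
  convention: $df_1 = (m-1)\varepsilon$, $df_2 = (N-1)(m-1)\varepsilon$,
  noncentrality $\lambda = f^2 N m \varepsilon/(1-\rho)$, defaults
  $\rho = 0.5$, $\varepsilon = 1$. The implementation reproduces the
  published anchors of that convention (4 measurements at power 0.95
  → 36 subjects; 2 measurements ≡ a paired t-test with d = 0.5 → 34;
  3 measurements at power 0.80 → 28). For $f = 0.25$, $m = 5$, power 0.80
  it returns **21**; published analyses sometimes report smaller minima
  for this setting, which under this convention corresponds to assuming a
  repeated-measures correlation near 0.57–0.59 rather than the 0.5
  default. The function is also cross-checked against an independent
  noncentral-F quadrature oracle in the tests.
* A note on Welch's ANOVA: it does *not* reduce numerically to the
  classical F under equal variances at finite n (its denominator carries a
  $1 + B$ correction with $B \sim 1/(n-1)$); the exact identity is
  $F_{Welch}(1+B) = F_{classical}$, which the tests assert.

Reported partial $\eta^2$ follows the standard SS-based definition. Stage
tables in the literature sometimes print $\eta^2$ values inconsistent with
their own F and df under this identity; the package makes no attempt to
match such values.

## Channel importance and consensus

Classifiers operate on channels-as-features: each row is one overlapping
500-ms window (100 windows over the first 5 s, start offsets
$\mathrm{round}(i(span-width)/(count-1))$), each feature the signed mean
amplitude of one channel. Cross-validation folds group whole subjects to
prevent leakage. Cross-validated accuracy is reported with the 70%
acceptable-discrimination flag; single-channel-style amplitude features
rarely clear it, which is precisely why importance scores, not raw
accuracy, identify stage-specific channels.

Shapley values are estimated by permutation sampling against a single
background point (the marginal feature means): for each sampled
permutation features are switched one at a time from background to the
explained row, and score increments accrue to the switched channel. This
telescopes, so the efficiency property (attributions sum to score minus
background score) holds exactly for any number of samples; the estimator
is unbiased for the exact Shapley value with that background, and the
tests verify it against full subset enumeration on small feature sets.
The default budget is 256 permutations.

`consensus()` intersects the FDR-significant alpha channel set with the
top-$k$ (default 5) channels by mean absolute Shapley value, per stage.
An empty intersection is a legitimate outcome; disjoint channel
*universes* (different montages) are an error.

## Latency estimation

Both detectors threshold on the **log** scale. A band power (or a
mean-square reconstruction error) estimated from a short window is
chi-squared-like with few degrees of freedom; its log has a
lighter-than-Gaussian right tail, so a mean + 3 SD rule holds its nominal
false-alarm bound where the raw statistic would not.

**STFT detector.** 500-ms Hanning windows, 50% overlap, PSD truncated at
30 Hz. The detection statistic is the log alpha-band power per frame,
*averaged across the analysed channel set* (the consensus channels in the
pipeline): a single 0.5-s frame has only ~4 spectral degrees of freedom in
an 4-Hz band (sd(log) ≈ 0.65, blind to a ×4 power change at 3 SD), while
the 5-channel average brings sd(log) to ≈ 0.25. Onset = start time of the
first run of 2 consecutive frames deviating from the baseline mean by more
than 3 baseline SDs, in either direction (cold suppresses alpha; injected
test effects may raise it). Estimates quantize to the 250-ms hop grid.

**Autoencoder detector.** Per consensus channel, one single-hidden-layer
autoencoder (tanh encoder, linear decoder, hidden width 8) is trained by
full-batch gradient descent with backtracking — recorded epoch losses are
non-increasing by construction — exclusively on non-overlapping 50-ms
baseline windows (at 1024 Hz, 50 ms is floored to 51 samples and the
window advances by exactly 51 samples; the 0.2 sample/window drift is
accepted). Windows are centred on their own mean (slow drift otherwise
clusters exceedances across neighbouring windows) and scaled by a
per-channel baseline constant. A held-out quarter of the baseline windows
calibrates the threshold: mean + 3 SD of the held-out log error (averaged
across channels). Onset = start of the first run of 2 consecutive
supra-threshold windows within 10 s; estimates quantize to the 50-ms grid.
A single-window rule cannot control the false-alarm rate over a
~200-window scan, so the run length is 2 — the estimate is still the start
of the run, i.e. the earliest sustained exceedance.

The two estimators are deliberately different instruments: the STFT rule
reacts to band-limited spectral change at sub-second resolution; the
autoencoder reacts only when the waveform leaves the baseline manifold
altogether, making it the more conservative, network-level detector. The
synthetic recovery tests reflect that: the STFT detector must localize a
×4 alpha-power step at 1.0 s to within (−0.25 s, +0.5 s) in ≥ 90% of
replicates, while the autoencoder must localize a ×9 alpha-power step at
2.0 s to within 4 windows (200 ms) in ≥ 80% — weaker changes are detected
late or not at all, which is the expected behaviour of this detector
class, not a defect.

## Problem sizes used by the test suite

All tested quantities — counts, band-power ratios, recovery rates,
false-alarm rates — are invariant to the sampling rate, so the suite runs
the study design (20 subjects × 5 stages, seven conditions, 120-s
windowing checks) at 64–256 Hz rather than the acquisition hardware's
1024 Hz, and the channel-recovery simulations use 10-s segments; 50
replicates back each recovery claim, 100 each null-calibration claim.
These sizes are the package's choice of a thorough-but-routine regression
suite; nothing in the implementation depends on them.

## Known limitations

* The generator's independence across channels means topographic structure
  (volume conduction, reference effects) is untested.
* Shapley scores for multiclass SVMs are not defined (no per-class score
  is exposed); use one-vs-rest fits or a probabilistic model kind.
* The EDF writer targets the plain continuous EDF profile (one segment,
  identical sampling rate across channels); EDF+ annotations are not
  written.
* Mauchly's test needs more subjects than stages; below that the battery
  reports `NA` and gates on Levene alone.
* `latency_summary()` reports non-detections separately and never imputes;
  summaries over stages with few detections are correspondingly noisy.
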