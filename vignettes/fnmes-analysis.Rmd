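---
title: "Methods: EEG and behavioural analysis of facial electrical stimulation"
author: "fnmesEEG authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG and behavioural analysis of facial electrical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnmesEEG)
```

# The experimental setting

Facial neuromuscular electrical stimulation (fNMES) delivers brief trains
of current pulses to facial muscles under computer control. Stimulating
the bilateral *zygomaticus major* (the smiling muscle) while a participant
categorises neutral, happy or sad faces as "happy" or "sad" manipulates
proprioceptive facial feedback with millisecond precision — either during
early visual processing (a 500 ms train spanning −250 to +250 ms around
face onset) or late, when spontaneous facial mimicry typically arises
(500–1000 ms). The analyses this package implements ask three questions:

1. Does stimulation bias the categorisation of neutral faces toward
   "happy"? (logistic mixed choice models)
2. Does early stimulation change the N170, the face-sensitive
   occipito-temporal ERP at 150–200 ms, and does that change mediate the
   choice bias? (double subtraction + mass-univariate maps + trial-level
   N170 extraction)
3. Does late stimulation change beta-band (13–22 Hz) coherence between
   somatomotor and occipital cortex? (time–frequency coherence + cluster
   permutation + repeated-measures ANOVA)

# The synthetic world

Real stimulation EEG is contaminated by a large pulse-train artifact and
the effects of interest are small; validating an analysis chain on real
data alone is therefore circular. The generator
(`buildTrialDesign()`, `simulateEpochs()`, `injectFnmesArtifact()`,
`simulateChoices()`, `simulateAuTimeseries()`) instead produces data whose
ground truth is known exactly, with defaults fixed to the published
experimental conditions:

* **Design**: 722 trials per subject — 16 identities × {neutral ×6,
  happy ×4, sad ×4} × 3 stimulation conditions (off/early/late) + 50
  stimulation-only trials — in pseudo-random order with no more than four
  consecutive trials sharing a stimulation or emotion level. Order is
  found by shuffle + bounded local repair and *errors out* rather than
  silently relaxing the constraint.
* **Epochs**: 64 channels (10–20 montage), 512 Hz, half-open
  [−1000, 1200) ms ⇒ 1126 samples. The half-open convention is used for
  every window in the package because it gives unambiguous sample counts
  (e.g. the −500…−260 ms baseline is exactly 122 samples).
* **Background noise**: 1/f^α with α = 1 plus white noise (defaults 5 and
  2 µV SD) — the minimal realistic EEG spectrum. Both SDs may be set to 0
  for noise-free construction tests.
* **N170**: a Gaussian bump (SD = 1/6 of the window) centred in
  150–200 ms on the 18 occipito-temporal electrodes, *rescaled so its
  window mean equals the nominal amplitude exactly* — this makes
  noise-free recovery an equality test, not an approximation. Amplitude =
  base (−5 µV, a typical N170) + emotion increment + stimulation
  increment. The published results do not report the reduction in µV, so
  it is a free parameter (default +1.5 µV under early stimulation). The
  purely additive default cancels exactly in the double subtraction; an
  optional emotion × stimulation interaction term (default 0) is what the
  recovery tests plant, mirroring the published early-stimulation
  modulation of the happy−sad difference.
* **Beta coupling**: a shared band-limited (13–22 Hz) source added to the
  central and left-occipital ROI channels from 650 ms onward (50 ms cosine
  ramps, off at 1100 ms), mixed as `sqrt(c)·s + sqrt(1−c)·noise` per
  channel. This construction makes the across-trial magnitude coherence
  converge to the coupling strength `c` — the analytic common-source
  oracle used in the tests. Default couplings are the published
  condition-mean coherence levels (0.316–0.340, with the choice effect
  reversing between off and late stimulation).
* **Artifact**: 35 biphasic pulses at 70 Hz over 500 ms. At 512 Hz a
  100 µs phase is far below one sample, so each pulse is realised as a
  +A/−A sample pair — the model targets what the artifact does to
  epoch-domain analyses (it is identical across emotions within a
  condition, hence cancelled by differencing), not its microsecond shape.
  The spatial profile defaults to large anterior/temporal and small
  occipital gains.
* **Choices**: `logit P(happy) = intercept_s + emotion + stimulation` with
  the published log-odds (happy +5.50, sad −4.23, early +0.17, late
  +0.133). The subject intercept SD defaults to 1.36, back-derived from
  the published conditional R² of 0.36 for the neutral-face model
  (`var_r = R²c/(1−R²c) · π²/3` with negligible fixed-effect variance).
* **AU traces**: 4 s clips at 30 fps, baseline level 1.0 with 0.05 SD
  noise, AU12 lifted by the published proportion-of-baseline condition
  means (off 0.002, early 0.137, late 0.156) during the 500 ms
  stimulation window.

All randomness flows from one explicit master seed through a documented
splitting scheme (`label → 31-bit stream seed`), so every artefact is
bit-reproducible.

What the generator does **not** emulate: volume conduction from a head
model, eye-blink/EMG artifacts, line noise, trial-to-trial latency
jitter, or non-stationary noise. A green test therefore establishes that
the *statistics* behave as specified on data carrying the assumed
structure — not that the pipeline is robust to every pathology of real
recordings.

# Preprocessing

The pipeline mirrors standard epoch conditioning: 0.5–80 Hz band-pass →
rejection of trials with any |v| > 100 µV → baseline correction
(−500…−260 ms) → 40 Hz low pass → common-average reference. Each step logs
itself; applying a step out of this canonical order warns but proceeds.
Choices the source experiment leaves open:

* **Filter realisation**: zero-phase 4th-order Butterworth applied
  forward–backward (squared magnitude response, zero phase — standard ERP
  practice because it preserves component latencies). With no DSP package
  in the environment, the bilinear-transform design and the
  odd-reflection-padded filtfilt are implemented in-package and tested
  against the analytic Butterworth response (including the frequency
  pre-warping of the bilinear transform).
* **Rejection boundary**: "exceeded ±100 µV" is read strictly — a sample
  at exactly 100 µV is retained.
* **Interpolation**: inverse-distance neighbour averaging on a schematic
  template grid (weights sum to 1, ≥3 good neighbours required) instead of
  spherical splines — dependency-free and directly testable.
* **Line noise**: the synthetic world carries none; no notch is applied by
  default.
* ICA-based artifact removal is out of scope by design: the synthetic
  artifact is built to be handled by differencing + rejection, which is
  the analytically guaranteed route (see below).

# ERP statistics

The central trick is the **double subtraction**: first happy − sad within
each stimulation condition, then condition − off. Any signal that is
additive and identical across emotions within a condition — in particular
the stimulation artifact — cancels *exactly*, to machine precision, which
the tests assert. The mass-univariate stage then runs one-sample t tests
across subjects at every channel × time cell with Benjamini–Hochberg FDR
applied jointly over all cells (the FDR variant and the
across-vs-within-subject orientation are unspecified in the source;
across-subject maps with BH is standard mass-univariate practice and is
the documented assumption). Under the global null the suite verifies the
family-wise false-positive rate empirically. Trial-level N170 amplitude
defaults to the *fixed published ROI* (18 electrodes, 150–200 ms) for
comparability, with the data-driven mask route available through
`massUnivariate()`.

# Coherence

`coh(f,t) = |Σ_trials X·conj(Y)| / sqrt(Σ|X|²·Σ|Y|²)` — **magnitude**
coherence, not squared; the published condition means (~0.32–0.34) are
consistent with magnitude coherence at these trial counts, and a
`squared = TRUE` toggle is provided. Spectra come from a Hanning-tapered
short-time Fourier transform with 5 cycles per frequency on a 5–40 Hz ×
0–1000 ms grid (0.5 Hz / 10 ms); windows are centred on the time point
and may draw on samples outside 0–1000 ms (the epoch extends to −1000 and
+1200 ms), and cells whose window would leave the epoch are missing, not
zero-filled — missingness propagates through ROI averages. Coherence is
pooled across trials within subject × condition × choice (it is not a
single-trial quantity); group statistics act on subject-level maps.
Estimator facts the tests pin down: self-coherence ≡ 1, the 1/n
small-sample bias on independent signals, convergence to the
common-source variance ratio, and invariance to per-channel gain.

# Cluster permutation

Cluster-forming threshold: two-tailed t at α = 0.01 on the
dependent-samples t map; clusters: 4-connected components (no diagonals),
positive and negative separately; cluster statistic: **mass** (sum of
member t values, the field-standard "maxsum"); null: the maximum
absolute mass over 2000 whole-subject sign flips (exact under
exchangeability of the within-subject pairing), sampled without enforcing
uniqueness; p = (1 + #{null ≥ obs}) / (nPerm + 1), so p is never exactly
0 and is bounded below by 1/(nPerm+1). Positive and negative clusters are
pooled into one max-|mass| null and tested at α = 0.05 (the documented
alternative — per-tail at α/2 — is noted but not default, matching the
printed "final alpha = 0.05"). Significant clusters from several
contrasts are unioned into a mask; masked condition means feed a 3 × 2
fully within-subject ANOVA with Greenhouse–Geisser correction
(implemented from the orthonormal-contrast covariance definition and
cross-checked in the tests against `stats::anova.mlm(test =
"Spherical")`), partial η², and Bonferroni paired-t post-hocs.

# Behavioural models

Choice models are Laplace-approximation logistic mixed models
(`lme4::glmer`) with the published fixed-effect structures; requested
random-slope structures are automatically simplified on singular or
failed fits (full slopes → random intercept → fixed-effects glm), and the
simplification path is recorded in the `ModelFit` — never silent. The
effect-size conversion is `d = b / (π/√3)` (dividing the log-odds by the
logistic SD). Of the four published (b, d) pairs, three reproduce exactly
at two decimals; for b = 0.17 the formula gives 0.094 → 0.09 while the
publication prints 0.10, evidently computed from the unrounded
coefficient — the package reports the computed value. Points of
subjective equality come from per-subject-per-condition logistic fits on
the −1/0/+1 emotion continuum (pse = −intercept/slope), with
all-one-category cells flagged as non-identifiable. The power simulation
takes the subject-intercept SD as an explicit input because the variance
components behind the published 87% power figure came from a prior
study's fit and are not printed; no claim is made to reproduce 87%.
Stimulation safety arithmetic: duty = pulse width × rate; RMS current =
peak × √duty; density = RMS / electrode area — 22.60 mA, 100 µs, 70 Hz
and 16 × 19 mm electrodes give 0.62 RMS mA/cm², below the 2 mA/cm²
threshold.

# End-to-end demonstration

```{r pipeline, eval = FALSE}
# Scaled-down but complete run (a few minutes):
params <- effectParams(betaCoupling = c(off.happy = 0.6, off.sad = 0.2,
                                        late.happy = 0.2, late.sad = 0.6),
                       n170BaseAmp = 0, n170Channels = "Cz",
                       n170EmotionDelta = c(neutral = 0, happy = 0, sad = 0))
design <- do.call(rbind, lapply(1:8, function(s) {
  d <- expand.grid(fnmes = c("off", "late"), choice = c("happy", "sad"))
  d <- d[rep(1:4, each = 16), ]
  data.frame(subject = s, trial_index = seq_len(64), identity = 1L,
             emotion = "neutral", fnmes = d$fnmes, repetition = 1L,
             choice = d$choice)
}))
rois   <- coherenceRois()
ep     <- simulateEpochs(design, params, seed = 1,
                         noise = list(alpha = 1, pinkSd = 2, whiteSd = 1),
                         channels = unique(unlist(rois)))
maps   <- roiCoherence(ep, tfGrid(fmin = 8, fmax = 30, fstep = 1,
                                  tstep = 25))
dmaps  <- pairedDifferenceMaps(maps, cond = "late")
result <- clusterTest(dmaps, nPerm = 500, seed = 2)
result                      # significant beta-band cluster from ~650 ms
mask   <- integrateMasks(list(lateOff = result))
anova  <- maskedAnova(maskedMeansTable(maps, mask$mask))
```

# Numerical choices and limitations

* ms → sample mapping is by floor with half-open windows, everywhere.
* Filtfilt padding is odd-reflection with up to 512 samples; the residual
  0.5 Hz high-pass transient is below 1% of signal RMS in the epoch
  interior.
* Zero-variance cells in t maps get t = 0, p = 1, with a warning.
* Monte-Carlo p values use the plus-one rule and a required seed;
  cluster results are invariant to subject order.
* The permutation null assumes exchangeability of subject-level
  difference maps under the null (standard for within-subject designs).
* BH-FDR assumes positive regression dependency across cells — satisfied
  by the smooth Gaussian-like maps here, but heavy-tailed artifacts in
  real data can distort it.
* `lme4` Wald p values are used for the choice models (the published
  z values are Wald as well); profile or bootstrap intervals are out of
  scope.
* The suite's stochastic calibration checks are binomial by construction:
  at 5% nominal and 2 MC-SE bounds they fail with probability ≈ 2%
  under a perfectly calibrated implementation.
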