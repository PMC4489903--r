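---
title: "Decoding hand movements from slow magnetic fields: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hand movements from slow magnetic fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A magnetoencephalography (MEG) based brain–machine interface must answer
two questions from a continuous multichannel recording, online and
without a cue: *when* does the user intend to move, and *which* movement
(grasp or open) do they intend? This package implements a complete,
testable version of such a pipeline: the slow-magnetic-field feature,
a movement-type classifier, a two-stage movement-onset detector, linear
mapping of sensor features onto sensorimotor cortex, offline evaluation
statistics, and a simulated closed-loop session that drives a virtual
prosthetic hand. Because no public recordings accompany this class of
experiment, a synthetic MEG generator is a first-class module: every
claim the test suite makes is made against data whose ground truth is
known by construction.

## The SMF feature

The decoding feature is the *slow magnetic field* (SMF): for each
channel, the mean of the signal over a 500-ms window, z-scored against
rest statistics. The rest statistics come from 50 non-overlapping
1000-ms windows (50 s of rest at the start of a session): per channel,
the mean and standard deviation of the 50 window means
(`compute_baseline_stats()`).

Two conventions needed fixing where the procedure leaves room:

* **Window alignment.** The 500-ms window *ends* at the labelled time
  (trailing/causal alignment). Online, only past samples exist, so the
  causal choice is forced there; we apply the same convention offline so
  that offline and streamed features agree exactly on shared time points
  (`stream_smf()` is tested to be bit-identical to the epoch path).
* **Baseline SD.** The normalised quantity is itself a window mean, so
  the z-score divisor is the SD across the 50 baseline *window means*,
  not across raw samples (the two differ by roughly the square root of
  the window length). Under this convention z-scoring the baseline
  segment itself yields mean 0, SD 1 exactly, which the tests assert.

Offline, SMFs are evaluated on a lag grid from −2000 ms to +1000 ms in
100-ms steps relative to each execution cue (31 lags); online they are
recomputed every 200 ms from the trailing buffer.

## Movement-type decoder

An RBF-kernel support vector machine classifies a single SMF vector
into grasp vs open. Its training lag `t*` is the lag of peak 10-fold
cross-validated accuracy within ±500 ms of the cue (`scan_accuracy()`,
ties to the earliest lag). Hyperparameters are selected by repeated
stratified cross-validation over log-spaced grids.

Numerical choices:

* **Kernel width.** Grids are expressed relative to the variance-scaled
  heuristic `gamma = 1 / (d · mean feature variance)`. Sensor-space
  z-scores and vertex-space currents live on very different scales; an
  absolute default width that works for one is badly mis-scaled for the
  other, while the variance-scaled heuristic is appropriate for both.
* **Grid size.** The default grids are deliberately coarse
  (cost `2^{-1}, 2^5`; width factors `2^{-2}, 2^1`): with 40-trial
  sessions, inner 10-fold × 10-repeat selection over a fine grid mostly
  fits fold noise, and every function accepts user-supplied grids.
* **Inner CV engine.** Inner accuracies use libsvm's stratified
  cross-validation (one C call per repeat), which draws its shuffles
  from R's RNG, so all model selection is reproducible under a seed.

## Movement-onset decoder

Onset detection combines two signals, each thresholded:

1. A **mutual-information estimator**: Gaussian-process regression from
   an SMF vector to the expected mutual information (MI, bits) between
   actual and inferred movement type. The observed MI course over lags
   comes from cross-validated predictions at each lag
   (`compute_mi_course()`), via the plug-in estimator
   `I = Σ p(a,b) log2 p(a,b)/(p(a)p(b))`. The estimator is trained on
   SMF vectors at three lags — `t*` and one lag before and after it —
   chosen by maximising the Pearson correlation between the observed MI
   course and the course predicted by the trained estimator
   (`select_time_triple()`). Each trial contributes one training sample
   per triple lag whose target is that lag's population MI; this
   reading keeps the estimator a function of a *single* SMF vector, as
   the online loop requires.
2. A **movement detector**: an RBF-SVM trained to separate SMF samples
   from a pre-movement period R_off (starting at −2000 ms, duration
   `d_off`) and a movement period R_on (starting at `t*`, duration
   `d_on`). Its signed decision value, oriented so that R_on is
   positive, is the movement confidence. The raw margin is used rather
   than a calibrated probability: nothing downstream needs a
   probability scale, and it avoids an extra fit.

Onset is declared when the estimated MI and the confidence both reach
their thresholds (inclusive comparisons). Durations and thresholds are
set by exhaustive grid search (`optimize_onset_params()`) maximising
the number of training trials whose *first* detection lands within
±500 ms of `t*` with a correct type classification at that moment.
Threshold candidates are quantiles (0.1–0.9) of the training-set MI
estimates and confidences — data-driven and scale-free. Ties prefer
larger thresholds (a conservative detector), then shorter periods.
Fixed thresholds can be supplied instead (`theta_mi_fixed`,
`theta_conf_fixed`), the analogue of thresholds set by hand before a
closed-loop run.

Duration grids default to 200-ms steps between 200 and 1000 ms: the
online loop re-evaluates every 200 ms, so a finer duration grid cannot
change which tick fires first; 100-ms grids remain available through
the arguments.

The GP uses a squared-exponential kernel with the deterministic median
heuristic for the kernel width and a fixed observation-noise variance,
through `kernlab::gausspr` with centred targets. Evidence (marginal
likelihood) maximisation was considered and rejected: the established
GP implementation available does not expose it, the regression targets
here are smooth and low-dimensional, and a deterministic width makes
the whole training path reproducible without extra optimisation state.
One behaviour is worth knowing: far from the training support an RBF GP
reverts to the target mean, so during long rest stretches the MI
estimate drifts toward the mean training MI. The movement detector's
confidence stays low at rest, which is why onset detection is the
*conjunction* of the two thresholds.

## Source mapping

The sensors-to-vertices conversion is a linear operator, and the
package accepts any vertices × sensors matrix
(`inverse_operator()`). For self-contained use a Tikhonov-regularised
minimum-norm operator `W = L'(LL' + λI)^{-1}` is provided. The default
`λ` is the mean diagonal of the sensor Gram matrix `LL'` (the mean
sensor power produced by unit sources), which keeps noise amplification
of the same order as signal gain; `λ = 0` on a square full-rank
leadfield reproduces the exact inverse, which the tests verify by a
forward–inverse round trip. Per-vertex movement-type contrasts use
one-way ANOVA at a single lag (the cue), masked at p < 0.05 without
multiple-comparison correction — deliberately matching the display
convention for such maps rather than an inferential claim.

## Closed-loop state machine

`run_session()` replays the online rules exactly: every 200 ms the SMF
of the trailing 500-ms buffer is computed, the onset decoder is
evaluated, and on a detection the virtual hand moves to the predicted
type. For 1.5 s after a detection further detections are suppressed
(before logging, so a suppressed crossing is not a logged detection);
after 20 s without detection the hand returns to rest. Accuracy counts
*movements* — state changes triggered by detections — and scores them
against the instruction active at the detection tick. Selectivity
partitions the session into one section per 7-s instruction and labels
it same-state or different-state by comparing the instruction with the
hand state at its onset; a one-sided Fisher's exact test asks whether
detections are enriched in different-state sections. The instruction
interval is the natural section unit; the procedure's description does
not define one, and any finer unit would make single detections count
multiple times.

The log header reports the feature-path latency implied by the window
and tick cadence; it is informational only and never shifts decoding.

## The synthetic generator

`generate_open_loop()` and `generate_closed_loop()` emulate the two
session types: 40 cues in randomised blocks of 4 identical movement
types after 50 s of rest; and 22 instructions alternating grasp/open
every 7 s. The movement-related cortical field is a smooth unimodal
source waveform — half-Gaussian rise from 1000 ms before the cue to a
peak at the cue, half-Gaussian decay over 500 ms, each half-width a
third of its span — projected to the sensors through a toy dipolar
leadfield: vertices on a cortical sphere carry tangential dipoles whose
sensor gains fall off with distance and change sign across the dipole
axis, giving the two-lobed topography characteristic of a cortical
source. Leadfield columns are normalised to unit peak gain so source
amplitudes are in peak-sensor units.

Defaults were chosen once to represent a realistic operating point, and
the tests treat them as the study conditions:

* sensor noise SD 1, grasp amplitude 0.12, open amplitude 0.06
  (single contralateral dipole). This yields SMF peaks of roughly 4–6 z
  and nested-CV accuracies in the mid-70s to mid-80s percent — the
  regime this class of decoder actually reports — rather than a
  noise-free toy. No quantitative amplitude or SNR is published for
  these signals, so SNR is an explicit free parameter.
* "High-SNR" test scenarios lower the noise SD to 0.05–0.3, where the
  pipeline must recover structure essentially perfectly (nested CV
  accuracy 1.0, ≥ 90% of first detections within ±500 ms of `t*`).
* Movement types are coded by source amplitude by default, mirroring
  the observation that the SMF amplitude depends on the movement type.
  Amplitude-only coding has a deliberate confound: early in its ramp, a
  grasp field passes through the open field's amplitude, so
  classification *at detection time* is unreliable even when
  classification at the peak is perfect. `dipole_vertex_open` assigns
  the open movement its own dipole, giving the types distinct
  topographies; the closed-loop demonstrations use this two-dipole
  configuration, and the confound itself is a useful negative control.
* The simulated closed-loop subject follows every instruction
  (compliance 1) with a reaction latency of 1 ± 0.25 s truncated at
  0.3 s.

What the generator does **not** emulate: realistic head geometry or
sensor physics, temporally structured background rhythms (an AR(1)
noise flag exists but defaults to off), artifacts (blinks, cardiac,
head movement), non-compliant or fatigued subjects, and any coupling
between feedback and brain state. Passing tests therefore show that the
*pipeline* is correct and calibrated under its stated assumptions — not
that those accuracies would be achieved on real recordings.

## Statistical notes

* Cross-validated accuracy on null data at these sample sizes is biased
  *below* chance (an established artifact of small-sample CV
  classification: held-out trials anti-correlate with the folds'
  fitted noise). Null tests therefore check the scientifically
  meaningful one-sided bound — no lag decodes *above* chance — and the
  full nested pipeline, whose inner selection removes most of the
  downward bias, is calibrated against the 50% chance line over many
  simulated sessions, combined with the exact binomial test at nominal
  α.
* Label permutation on signal-bearing sessions produces a null accuracy
  distribution that is wide (a permutation can agree with the true
  labelling well above or below half by chance at n = 40), so the
  chance-level calibration is asserted on the *mean* over seeds with a
  t-test across seeds, not on single sessions.
* The one-sided binomial test, Fisher's exact test, plug-in MI, ANOVA F
  and the onset grid-search objective are each verified against
  independent brute-force implementations (tail sums, hypergeometric
  enumeration, entropy identities, naive loops) to 1e-10.

## Problem sizes used by the test suite

Unit tests run on reduced geometries (12 sensors, 6 vertices per
hemisphere, 24 trials) chosen so the full suite exercises every code
path at interactive speed; the acceptance-level checks use the full
default sessions (84 sensors, 84 vertices per hemisphere, 40 trials)
with 20 independent seeds for the chance-level calibration and the
hemisphere-contrast ordering. The nested cross-validation always uses
the complete protocol (10 outer folds, 10×10 inner repeated CV, 11
candidate lags).

## Known limitations

* The sensors-to-vertices operator is generic minimum-norm; a
  hierarchical Bayesian current estimate would localise better, and
  users with such an operator should supply it as a matrix.
* The MI estimator's mean-reversion at rest (above) means its threshold
  alone is not a rest/movement discriminator; detection always requires
  the detector confidence as well.
* With a single amplitude-coded dipole, type classification at
  detection time is intrinsically limited (the ramp-phase confound);
  this is a property of the simulated source coding, not of the
  decoders.
* The virtual hand is a three-state machine (rest/grasp/open); servo
  kinematics and hardware latency are out of scope, and the reported
  feature-path latency is bookkeeping only.
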