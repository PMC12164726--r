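---
title: "Transient-gated decoding: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient-gated decoding: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous ("asynchronous") decoding of intracortical population activity
must cope with a non-stationary neural code: activity that predicts grasp
force in a grasp-only context predicts something else once the arm is
moving, so a continuous regression trained in one context produces phantom
outputs in another. TransientGate implements the alternative architecture:
motor cortex emits brief, *condition-invariant* transient responses at the
onset and offset of any hand action. Detecting these transients tells the
decoder *when* hand-feature information is present; the specific feature
decoder (finger identity or grasp force) is engaged only in a short window
after onset detection, its output is then latched, and the latch is
released by the offset transient. The cost is moment-by-moment adjustment;
the gain is output stability and structural immunity to cross-effector
interference.

## The analysis chain

1. **Preprocessing** (`smoothCounts`). Threshold-crossing counts in 20 ms
   bins are square-root transformed and convolved with a causal
   exponential filter, decay constant `tau = 0.4` s, truncated at `5 tau`
   and renormalized to unit sum. We read the filter's "400 ms" as the
   decay constant, the common laboratory convention; the total kernel
   extent reading is available by setting `tau` accordingly. The kernel is
   applied after the square-root transform, and the output at bin *t*
   depends only on bins up to *t*.

2. **Latent model** (`fitFactorModel`, `projectLatents`). Maximum
   likelihood factor analysis with 20 factors, fit by EM on the sample
   covariance of all within-session bins (not trial averages).
   Initialization is deterministic (principal components with a uniform
   uniqueness estimate from the eigenvalue tail), the log-likelihood is
   monitored with an exact Woodbury-identity evaluation and must be
   non-decreasing, and per-channel uniquenesses are floored at `1e-6`
   times the channel variance so that noiseless inputs cannot collapse
   the model. The latent basis is the left singular vectors of the
   loading matrix; latent trajectories are *projections* of centered
   rates onto this orthonormal basis rather than posterior factor means,
   which makes downstream variance accounting exact (posterior-mean
   scoring is available via `scoring = "posterior"`).

3. **Transient identification** (`findTransients`). Latent responses are
   aligned to action onset (-1.5 to +2 s) and offset (-2 to +1.5 s),
   averaged over all trials with conditions pooled (the transients are
   condition-invariant by hypothesis, so pooling sharpens rather than
   biases them). The latent space is then split into onset-unique,
   offset-unique, and shared subspaces from the eigenvectors of the
   covariance difference `C_on - C_off`. Being eigenvectors of a
   symmetric matrix these are orthonormal, which is what ultimately
   guarantees that the onset and offset components are orthogonal. A
   direction counts as onset-unique when its onset-excess variance (its
   eigenvalue) is at least 10% of the largest excess. We use this
   *relative-excess* rule rather than an absolute purity rule ("at most
   10% of the direction's variance is offset-related") deliberately: with
   realistic, variable hold durations the opposite event always bleeds
   into the alignment window, so absolute purity is unattainable for any
   direction, while the variance *excess* still isolates the transients
   cleanly. We also evaluated the whitened generalized eigenproblem
   (maximizing `v'C_on v / v'(C_on + C_off + eps I)v`): whitening
   amplifies near-null-variance directions, and the subsequent
   re-orthogonalization redistributes the onset direction across
   sub-threshold components, measurably degrading recovery on simulated
   sessions. Within each unique subspace a varimax rotation (no column
   normalization -- the columns are latent time courses with meaningful
   scale) exposes temporally sparse components; because an exact
   mixture can leave the identity rotation at a stationary point of the
   varimax criterion, the rotation is restarted from a fixed set of
   deterministic rotations and the best criterion value kept. The single
   component with the largest modulation (peak deviation from the
   baseline-window mean; ties broken toward the earlier peak) on each
   side is selected and sign-flipped so its peak is positive.

   **Width reporting.** The causal exponential filter broadens a 500 ms
   FWHM Gaussian to roughly 740 ms and delays its peak by about 200 ms.
   The template width measured by linear interpolation at half maximum is
   therefore reported twice: raw (`fwhmRawOn`), and corrected
   (`fwhmOn`) by numerically inverting the Gaussian-through-exponential
   width mapping, which recovers the intrinsic transient width. The
   correction is a scalar inversion of a monotone map, so it adds no
   noise amplification.

4. **Condition-dependent variance** (`conditionVarianceTrace`,
   `summarizeT1T2`, `transientVarianceLag`). At each aligned bin the mean
   latent state of every condition is computed and `V(t)` is the mean
   squared distance of the condition means from their centroid (trace of
   the across-condition covariance; denominator `C` so that the
   two-condition toy case is clean, with `C - 1` available). Information
   decay is summarized as the ratio of `V` averaged over two 100 ms
   windows: t1 centered 200 ms after the onset-transient peak on the
   onset-aligned trace, and t2 centered 200 ms before the offset-transient
   peak on the offset-aligned trace. The transient-to-variance lag is the
   argmax over integer-bin lags (within +/-1 s) of the Pearson correlation
   between the onset template and the onset-aligned variance trace,
   computed over overlapping samples only (zero padding would bias the
   lag toward zero); ties break toward the smallest absolute lag.

   A structural property of this estimator is worth knowing: whenever the
   condition code decays monotonically to a fraction rho of its peak, the
   variance trace necessarily holds a sustained level of about
   `rho x V(t1)` through the mid-trial, and that sustained level
   correlates with the exponential tail that the smoothing filter puts on
   the transient template. The argmax is therefore pulled later than the
   true condition-coding delay -- on noiseless traces built from the
   simulator's own profiles the pull is on the order of a hundred
   milliseconds at rho = 0.35. Estimates from this estimator (including
   published ones) are best read as an upper bound on the true delay.

5. **Gated decoder** (`trainGatedDecoder`, `decodeStream`,
   `gateStateMachine`). Onset and offset detectors are binary linear
   discriminants (`MASS::lda`) on the full 20-D latents with equal class
   priors, positives within +/-100 ms of the per-trial transient peak and
   negatives elsewhere outside a +/-300 ms guard band. The streaming
   state machine is strictly causal and total: idle -> (onset posterior
   >= 0.9 on 2 consecutive bins) -> deciding -> latched -> (offset
   posterior, after a 0.5 s refractory) -> idle. For finger tasks the
   feature decoder is a shrinkage-regularized linear discriminant
   (pooled covariance blended 30% toward a scaled identity, the standard
   regularization in BCI discriminant decoding) trained on bins from the
   detector's *actual* firing times on the training stream; its posterior
   is evaluated from 0.3 s after detection (`classDelay`) until it
   reaches 0.9 or a 1 s timeout emits the running argmax. The delay
   matters because detection fires on the transient's rising edge,
   roughly 100 ms before action onset, where condition information does
   not yet exist; decisions land about 200-400 ms after onset. For grasp
   tasks the feature decoder is an ordinary least-squares regression from
   latents to cued force over the first second after onset; its live
   prediction is output for `forceWindow = 1` s after detection and then
   clamped at its current value. Within every latched segment the output
   range is exactly zero by construction, and with no onset detection
   the output is identically null -- the architecture makes phantom
   outputs during reach-only activity impossible rather than unlikely.

6. **Baselines and evaluation** (`fitWienerCascade`,
   `fitContinuousClassifier`, `looCrossValidate`). The continuous
   baselines are a Wiener cascade (ordinary least squares from 10 tapped
   latent history bins to the piecewise-constant cued force, followed by a
   least-squares 3rd-order polynomial from the linear output to the
   target; rank deficiency falls back to a small ridge) and a per-bin
   multiclass discriminant with an explicit null class. Evaluation is
   trial-level leave-one-out: each fold refits the *entire* chain --
   latent model, transients, decoders -- on the remaining trials (event
   times are remapped to the spliced training timeline), then decodes the
   held-out trial's stream segment. Metrics: epoch-mean force R^2 over
   pre/mid/post epochs (the 25th-75th percentile spans of the
   start-onset, onset-offset, and offset-end intervals) against targets
   (0, cued force, 0); normalized mid-epoch range `(max - min)/mean` as
   the stability measure; per-bin timepoint accuracy with inter-trial
   bins included; and per-click duration ratio, where the decoded click
   is the contiguous non-null run with maximal overlap with the cued
   window. Trials where any compared decoder yields an all-null
   prediction (for force: non-positive mid-epoch mean) are excluded from
   aggregates and reported.

## The simulator

`simulateSession` generates the structure the chain is designed for, with
known ground truth (`groundTruth`): ~192 channels binned at 50 Hz, four
task protocols, and a 20-D latent trajectory containing

- Gaussian onset/offset transient bumps (FWHM 0.5 s; `sigma =
  FWHM/2.3548`) on two fixed orthogonal directions, identical across
  conditions, amplitude 6 (in units of the AR-noise-free latent scale) --
  the condition-invariant component dominates the population response, as
  it does in motor cortex;
- condition coding on per-condition mutually orthogonal directions
  (orthogonal to the transient directions, so recovery tests are
  unambiguous): an early bump peaking 200 ms after the onset-transient
  peak plus a sustained component that ramps up over 0.8 s (the
  "prolonged response" of the two-component account of force coding) and
  holds until release, overall gain 3. The early/sustained amplitude
  split is solved analytically so that the *measured* ratio
  `V(t2)/V(t1)` -- which downstream code computes on smoothed rates, in
  windows anchored to the smoothed transient peaks -- equals the
  configured `decayRatio` (default 0.35). Solving in the raw latent
  domain instead would miss the target by a factor of two, because the
  filter attenuates the early bump far more than the plateau; this is
  why the config carries the smoothing constant;
- for carry/drag tasks, translation interference: sinusoidal activity
  (0.4-0.8 Hz, random amplitude and phase per trial) on a fixed direction
  whose cosine with the condition subspace is `interferenceOverlap`
  (default 0.85, pointing at a random direction of the condition code),
  active between onset and offset. Interference also *suppresses* the
  condition-coding amplitude by `overlap x envelope` during that window:
  additive noise on a single fixed direction alone does not degrade a
  discriminant (it is projected out via the within-class covariance),
  whereas the cross-effector phenomenon being emulated is the
  near-disappearance of hand information during concurrent arm use;
- AR(1) latent noise on all 20 dimensions (`phi = 0.9`, stationary sd
  0.35) -- shared variance that lets the factor model pin down the full
  latent space -- followed by emission through a random loading matrix
  (column norms 18 Hz per latent unit), rectification at zero, and
  Poisson draws around a 20 Hz baseline.

Trial timing: 8 s trials (9 s for grasp tasks), onset 2 s after trial
start with +/-100 ms uniform jitter, hold durations drawn uniformly from
1-2 s for finger tasks and 3.5-4.5 s for grasp tasks. Variable holds are
not a nicety: they are what keeps the opposite event diffuse in
trial-averaged aligned data, and for grasp tasks the hold must be long
enough that the middle-of-grasp epoch falls in the latched regime. A
`handSignal = FALSE` session generates the reach-only stream (interference
and noise, no hand transients, no condition coding) used to demonstrate
gated silence in the absence of hand intent.

What the simulator does *not* emulate: electrode nonstationarity and
drift, biophysical spike waveforms, heterogeneous per-channel baselines,
behavioral variability in movement vigor, or genuinely nonlinear
population dynamics. Passing recovery tests here shows the chain is
correct and well-calibrated under its own assumptions, not that those
assumptions exhaust real recordings.

## Numerical choices and degenerate inputs

- EM: uniqueness floor `1e-6 x` channel variance; a finite-precision
  log-likelihood stall reverts to the previous iterate; decreases beyond
  `1e-4` relative abort loudly. Constant channels are dropped with a
  warning and carried as zero loadings.
- Subspace split: ridge `1e-6 x trace/k` in the share computation; a
  relative variance floor (`1e-3` of the largest total variance) keeps
  near-null directions out of the unique subspaces; identical averages
  yield empty unique subspaces, and `findTransients` then fails with a
  diagnostic rather than fabricating a component.
- Varimax: five deterministic starts; orthogonality of the returned
  rotation is checked to `1e-8`; total time-course variance is preserved
  to the same tolerance.
- FWHM: linear interpolation at half maximum; the filter correction
  inverts the width map by `uniroot` on a 4 ms grid and returns `NA`
  when no half-maximum crossing exists.
- State machine: every posterior sequence yields a valid trace; timeout
  emissions are flagged in the event log, never raised as errors.
- Event times snap to the nearest 20 ms bin throughout.

## Problem sizes in the test suite

The acceptance checks run 20 default finger-click sessions (192 channels,
40 trials) for transient and lag recovery, five sessions per configured
decay ratio, and leave-one-out comparisons on 12-15 trial sessions for
the force and classification contrasts; unit tests use 32-96 channel
sessions with 3-12 trials. The "high-SNR" regime used for the
classification accuracy checks is `snrScale = 2`.

## Known limitations

- The transient-to-variance lag estimator carries the structural positive
  bias described above; the package reports what the estimator computes.
- The FWHM correction assumes a Gaussian transient seen through the known
  exponential filter; strongly asymmetric transients would be
  mis-corrected.
- The classifier's shrinkage level (0.3) and decision delay (0.3 s) are
  calibrated for the simulator's posterior landscape; real sessions may
  want different values, and both are exposed.
- Closed-loop use, cross-session transient alignment, and ingestion of
  external recording formats are out of scope; `readSessionBundle`
  defines the expected layout for adapting external data.
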