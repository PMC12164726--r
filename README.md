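# TransientGate

Transient-gated decoding of intracortical population spiking.

## The problem

Continuous brain-computer-interface decoders assume a stable mapping from
neural activity to a movement variable, but the cortical code is
contextual: a regression that reads grasp force beautifully in a
grasp-only task produces strong phantom forces as soon as the user moves
their arm. Motor-cortex population activity does, however, contain brief
**condition-invariant transient components** — ~500 ms bumps in a
low-dimensional latent space that mark the onset and the offset of any
hand-related action, whatever its specifics. TransientGate implements the
decoding architecture built on that observation, for researchers working
on intracortical BCI decoding and population-latent analyses:

1. smooth binned spike counts into firing-rate estimates
   (square-root transform, causal 400 ms exponential filter);
2. fit a 20-factor latent model (EM factor analysis, orthonormal basis
   from the SVD of the loadings) and project the session into latent
   trajectories *z(t)*;
3. identify the single onset and single offset transient component from
   trial-averaged aligned responses, via an onset-/offset-unique
   variance decomposition (eigenvectors of `C_on − C_off`) followed by a
   varimax rotation that exposes temporally sparse components;
4. quantify the decay of condition information: per-bin variance across
   condition means `V(t) = (1/C) Σ_c ‖m_c(t) − m̄(t)‖²`, its ratio
   between 100 ms windows at *t₁* (200 ms after the onset-transient
   peak) and *t₂* (200 ms before the offset-transient peak), and the
   transient-to-variance lag;
5. run the **gated decoder**: linear-discriminant onset/offset detectors
   gate a short-window feature decoder (finger classifier or
   latent-to-force regression) inside a causal state machine
   (idle → deciding → latched → idle) whose output is latched between
   onset and offset detections — so hold-phase output range is exactly
   zero and no output can occur without a detected hand action;
6. compare against the standard continuous baselines (Wiener cascade for
   force, per-bin LDA for fingers) with trial-level leave-one-out
   cross-validation and the four comparison metrics (epoch-mean R²,
   normalized hold range, timepoint accuracy, click-duration ratio).

A seeded Poisson population-spiking simulator with planted ground truth
(`simulateSession`) makes every stage testable without recordings.

## Worked example

```r
library(TransientGate)

cfg <- simConfig("click_drag", snrScale = 2, nTrials = 15, seed = 7)
session <- simulateSession(cfg)
session
#> SpikeSession: 192 channels x 6000 bins (50 Hz, 120.0 s)
#>   15 trials | click_drag | 5 conditions
#>   assays: counts
#>   ground truth available (simulated session)

session <- smoothCounts(session)
model <- fitFactorModel(session)
traj <- projectLatents(session, model)
transients <- findTransients(traj, trialEvents(session))
transients
#> TransientModel
#>   onset : peak +0.200 s, amplitude 2.026, FWHM 555 ms (raw 795 ms)
#>   offset: peak +0.220 s, amplitude 2.016, FWHM 608 ms (raw 844 ms)
```

The transient peaks sit ~200 ms after the true events because the causal
smoothing filter delays and broadens everything it touches; the reported
FWHM inverts that broadening (the raw measured width is kept alongside).
The recovered onset component, mapped back to channel space, points at
the planted direction:

```r
abs(sum(as.numeric(model@basis %*% transients@wOn) *
        groundTruth(session)@uOn))
#> [1] 0.935
```

Leave-one-out comparison of the gated decoder against a continuous
per-bin classifier on this click+drag session (arm translation interferes
with the finger code during the drag):

```r
looCrossValidate(session, "classification")
#> EvalReport (classification): 15 LOO folds, 0 trials excluded
#>   gated_trial_accuracy         1.0000
#>   cont_trial_accuracy          0.9333
#>   gated_timepoint_accuracy     0.9620
#>   cont_timepoint_accuracy      0.8918
#>   gated_duration_ratio_median  0.8051
#>   cont_duration_ratio_median   0.3950
```

Every trial's click is classified correctly by the gated decoder, and its
clicks persist for ~81% of the cued duration, while the continuous
classifier's predictions fragment during the drag and hold only ~40% —
the qualitative signature the gating architecture exists to fix. The
methods vignette (`vignettes/gated-decoding.Rmd`) documents the models,
the simulator, and every numerical choice.

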