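#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration
#'
#' Parameters of the synthetic population-spiking generator. The generator
#' plants a known low-dimensional latent structure -- condition-invariant
#' onset/offset transients, condition-coding activity that decays over the
#' hold period, and (for carry/drag tasks) cross-effector translation
#' interference -- and emits Poisson spike counts through a random linear
#' loading matrix. Construct with [simConfig()].
#'
#' @slot task one of `"grasp_force"`, `"grasp_carry"`, `"finger_click"`,
#'   `"click_drag"`.
#' @slot nChannels number of recording channels.
#' @slot binWidth bin width in seconds (50 Hz bins by default).
#' @slot nLatent dimensionality of the planted latent space.
#' @slot nConditions number of force levels or fingers (2--5).
#' @slot nTrials trials per session.
#' @slot fwhmOn,fwhmOff full width at half maximum of the planted onset and
#'   offset transient bumps, seconds.
#' @slot condPeakLag delay of the condition-coding peak after the onset
#'   transient peak, seconds.
#' @slot decayRatio target ratio of condition-dependent variance at t2
#'   (200 ms before the offset-transient peak) to t1 (200 ms after the
#'   onset-transient peak), in (0, 1].
#' @slot interferenceGain amplitude of translation interference (latent
#'   units); nonzero only meaningful for carry/drag tasks.
#' @slot interferenceOverlap cosine of the angle between the interference
#'   direction and the condition-coding subspace, in \[0, 1\].
#' @slot baselineRate baseline firing rate per channel, Hz.
#' @slot snrScale global scale on all planted signal amplitudes.
#' @slot smoothTau decay constant of the causal exponential smoothing the
#'   downstream pipeline applies, seconds. Used only to solve the
#'   early/sustained condition-coding amplitudes so that the *measured*
#'   variance ratio (which is computed on smoothed rates) hits `decayRatio`.
#' @slot trialLength,holdDuration,holdRange,onsetLead trial template
#'   timing, seconds: each trial occupies `trialLength`, action onset is
#'   `onsetLead` after trial start, and the hold duration is drawn
#'   uniformly from `holdDuration` +/- `holdRange` per trial (variable
#'   holds, as in the emulated protocols, keep the opposite-event
#'   response diffuse in trial-averaged aligned data).
#' @slot jitterSD not an SD: half-range of the uniform +/- jitter applied to
#'   onset and offset times, seconds.
#' @slot arCoef,noiseSD AR(1) coefficient (per bin) and stationary standard
#'   deviation of the latent noise.
#' @slot loadingGain Euclidean norm of each loading-matrix column, Hz per
#'   latent unit.
#' @slot handSignal logical; `FALSE` generates a "reach-only" stream with
#'   translation interference but no hand transients and no condition
#'   coding (used to probe decoder silence in the absence of hand intent).
#' @slot seed integer RNG seed; generation is a pure function of the config.
#' @export
setClass("SimConfig", representation(
  task = "character", nChannels = "numeric", binWidth = "numeric",
  nLatent = "numeric", nConditions = "numeric", nTrials = "numeric",
  fwhmOn = "numeric", fwhmOff = "numeric", condPeakLag = "numeric",
  decayRatio = "numeric", interferenceGain = "numeric",
  interferenceOverlap = "numeric", baselineRate = "numeric",
  snrScale = "numeric", smoothTau = "numeric", trialLength = "numeric",
  holdDuration = "numeric", holdRange = "numeric", onsetLead = "numeric",
  jitterSD = "numeric",
  arCoef = "numeric", noiseSD = "numeric", loadingGain = "numeric",
  handSignal = "logical", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!object@task %in% c("grasp_force", "grasp_carry", "finger_click", "click_drag"))
    msg <- c(msg, "task must be one of grasp_force, grasp_carry, finger_click, click_drag")
  if (object@fwhmOn <= 0 || object@fwhmOff <= 0) msg <- c(msg, "fwhm must be > 0")
  if (object@decayRatio <= 0 || object@decayRatio > 1)
    msg <- c(msg, "decayRatio must lie in (0, 1]")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (object@nConditions < 2) msg <- c(msg, "nConditions must be >= 2")
  if (object@interferenceGain < 0) msg <- c(msg, "interferenceGain must be >= 0")
  if (object@interferenceOverlap < 0 || object@interferenceOverlap > 1)
    msg <- c(msg, "interferenceOverlap must lie in [0, 1]")
  if (object@nLatent < object@nConditions + 4)
    msg <- c(msg, "nLatent too small for the planted directions")
  if (object@holdRange < 0 || object@holdRange >= object@holdDuration)
    msg <- c(msg, "holdRange must lie in [0, holdDuration)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated session
#'
#' Planted directions and noiseless latent trajectory of a synthetic
#' session; the reference object for recovery tests. All direction vectors
#' are unit norm, and the onset and offset directions are orthogonal by
#' construction.
#'
#' @slot uOn,uOff planted transient directions in channel space (unit norm).
#' @slot uCond per-condition coding directions in channel space (columns).
#' @slot interferenceDir interference direction in channel space.
#' @slot dOn,dOff,dInterference the same directions in the planted latent
#'   space (unit norm); `dCond` columns are mutually orthogonal and
#'   orthogonal to `dOn`/`dOff`.
#' @slot dCond latent condition directions (columns).
#' @slot loadings channel x latent loading matrix used for emission.
#' @slot latentTrue noiseless planted latent trajectory (bins x latent),
#'   before AR(1) noise and Poisson emission.
#' @slot plantedLag the configured condition peak lag, seconds.
#' @slot amplitudes named list of solved signal amplitudes.
#' @export
setClass("GroundTruth", representation(
  uOn = "numeric", uOff = "numeric", uCond = "matrix",
  interferenceDir = "numeric", dOn = "numeric", dOff = "numeric",
  dCond = "matrix", dInterference = "numeric", loadings = "matrix",
  latentTrue = "matrix", plantedLag = "numeric", amplitudes = "list"))

#' Session container: binned population spiking plus trial events
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with rows =
#' channels and columns = 20 ms time bins. The `"counts"` assay holds
#' nonnegative integer threshold-crossing counts; preprocessing adds a
#' `"rates"` assay of smoothed square-root firing-rate estimates. The trial
#' event table (cue / action onset / action offset / trial bounds, condition
#' label, cued force) lives in `trialEvents()`, and simulation provenance
#' (config, seed, ground truth) in `metadata()`.
#'
#' @slot trialEvents `DataFrame` with columns `trial_id`, `task`,
#'   `condition`, `force`, `cue_time`, `onset_time`, `offset_time`,
#'   `trial_start`, `trial_end` (all times in seconds from session start).
#' @slot binWidth bin width in seconds.
#' @export
setClass("SpikeSession",
  contains = "SummarizedExperiment",
  representation(trialEvents = "DataFrame", binWidth = "numeric"))

setValidity("SpikeSession", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number")
  if (!"counts" %in% assayNames(object)) msg <- c(msg, "missing 'counts' assay")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
  }
  ev <- object@trialEvents
  need <- c("trial_id", "condition", "cue_time", "onset_time", "offset_time",
            "trial_start", "trial_end")
  miss <- setdiff(need, colnames(ev))
  if (length(miss)) msg <- c(msg, paste("events table missing columns:",
                                        paste(miss, collapse = ", ")))
  else if (nrow(ev)) {
    tmax <- ncol(object) * object@binWidth
    tcols <- c("cue_time", "onset_time", "offset_time", "trial_start", "trial_end")
    tv <- unlist(lapply(tcols, function(cc) ev[[cc]]))
    if (any(tv < 0) || any(tv > tmax + 1e-9))
      msg <- c(msg, "event times must lie within the recording")
    if (any(ev$onset_time >= ev$offset_time))
      msg <- c(msg, "onset_time must precede offset_time in every trial")
  }
  if (length(msg)) msg else TRUE
})

#' Latent factor model
#'
#' Maximum-likelihood factor-analysis fit (EM) of smoothed firing rates,
#' with an orthonormal latent basis obtained from the SVD of the loading
#' matrix. Latent trajectories are, by default, projections of the centered
#' rates onto this basis (posterior-mean scoring is also available), so the
#' latent space is orthonormal and variance accounting downstream is exact.
#'
#' @slot loadings channels x factors loading matrix.
#' @slot channelMeans per-channel means of the fitted rates.
#' @slot noiseVariances per-channel uniqueness (positive).
#' @slot basis channels x factors orthonormal basis (left singular vectors
#'   of `loadings`).
#' @slot nFactors number of factors.
#' @slot converged logical EM convergence flag.
#' @slot logLik per-iteration log-likelihood trace (non-decreasing).
#' @slot keptChannels indices of channels retained in the fit (constant
#'   channels are dropped with a warning; their loadings are zero).
#' @export
setClass("LatentModel", representation(
  loadings = "matrix", channelMeans = "numeric", noiseVariances = "numeric",
  basis = "matrix", nFactors = "numeric", converged = "logical",
  logLik = "numeric", keptChannels = "integer", scoring = "character"))

setValidity("LatentModel", function(object) {
  msg <- character()
  k <- object@nFactors
  if (ncol(object@basis) != k) msg <- c(msg, "basis must have nFactors columns")
  g <- crossprod(object@basis)
  if (max(abs(g - diag(k))) > 1e-8)
    msg <- c(msg, "basis is not orthonormal (tolerance 1e-8)")
  if (any(object@noiseVariances[object@keptChannels] <= 0))
    msg <- c(msg, "noiseVariances must be positive on kept channels")
  if (length(msg)) msg else TRUE
})

#' Latent trajectory
#'
#' Per-bin latent state (bins x factors) produced by projecting smoothed
#' rates through a [LatentModel].
#'
#' @slot z bins x factors matrix of latent states.
#' @slot binWidth bin width, seconds.
#' @slot times bin start times, seconds.
#' @export
setClass("LatentTrajectory", representation(
  z = "matrix", binWidth = "numeric", times = "numeric"))

#' Alignment windows for transient identification
#'
#' @slot onsetWindow seconds relative to action onset (default -1.5 to 2.0).
#' @slot offsetWindow seconds relative to action offset (default -2.0 to 1.5).
#' @export
setClass("AlignmentWindows", representation(
  onsetWindow = "numeric", offsetWindow = "numeric"))

setValidity("AlignmentWindows", function(object) {
  if (object@onsetWindow[1] >= object@onsetWindow[2] ||
      object@offsetWindow[1] >= object@offsetWindow[2])
    "window start must precede window end" else TRUE
})

#' Identified transient components
#'
#' The single onset and single offset transient component in the latent
#' space: unit direction vectors (orthogonal to each other by virtue of the
#' onset-/offset-unique subspace decomposition), their trial-averaged
#' template time courses, and peak statistics. `fwhmOn`/`fwhmOff` are
#' corrected for the broadening of the causal exponential smoothing filter
#' (see [selectTransient()]); the raw measured widths are kept alongside.
#'
#' @slot wOn,wOff unit vectors in the latent space.
#' @slot templateOn,templateOff baseline-subtracted average time courses.
#' @slot templateTimesOn,templateTimesOff times of the template samples,
#'   seconds relative to the aligning event.
#' @slot peakTimeOn,peakTimeOff peak times, seconds relative to the event.
#' @slot peakAmplitudeOn,peakAmplitudeOff peak amplitudes, latent units.
#' @slot fwhmOn,fwhmOff filter-corrected FWHM, seconds.
#' @slot fwhmRawOn,fwhmRawOff FWHM measured directly on the smoothed
#'   template, seconds.
#' @slot droppedTrials number of trials dropped at alignment.
#' @export
setClass("TransientModel", representation(
  wOn = "numeric", wOff = "numeric",
  templateOn = "numeric", templateOff = "numeric",
  templateTimesOn = "numeric", templateTimesOff = "numeric",
  peakTimeOn = "numeric", peakTimeOff = "numeric",
  peakAmplitudeOn = "numeric", peakAmplitudeOff = "numeric",
  fwhmOn = "numeric", fwhmOff = "numeric",
  fwhmRawOn = "numeric", fwhmRawOff = "numeric",
  droppedTrials = "numeric"))

setValidity("TransientModel", function(object) {
  msg <- character()
  if (abs(sum(object@wOn * object@wOff)) > 1e-8)
    msg <- c(msg, "onset and offset components must be orthogonal (1e-8)")
  if (abs(sqrt(sum(object@wOn^2)) - 1) > 1e-8 ||
      abs(sqrt(sum(object@wOff^2)) - 1) > 1e-8)
    msg <- c(msg, "component vectors must be unit norm")
  if (length(msg)) msg else TRUE
})

#' Condition-dependent variance trace
#'
#' Per-bin variance across the condition-mean latent states, aligned to
#' action onset or offset: at each bin the mean latent point of every
#' condition is computed and `V(t)` is the mean squared distance of those
#' points from their centroid (trace of the across-condition covariance,
#' denominator C).
#'
#' @slot times seconds relative to the aligning event.
#' @slot V nonnegative variance per bin.
#' @slot alignment `"onset"` or `"offset"`.
#' @slot nConditions number of conditions entering the trace.
#' @export
setClass("VarianceTrace", representation(
  times = "numeric", V = "numeric", alignment = "character",
  nConditions = "numeric"))

setValidity("VarianceTrace", function(object) {
  if (any(object@V < -1e-12)) "V must be nonnegative" else TRUE
})

#' Gated decoder configuration
#'
#' Thresholds and timing of the streaming state machine. Construct with
#' [gateConfig()].
#'
#' @slot thetaOn,thetaOff posterior thresholds of the onset/offset
#'   detectors, in (0, 1).
#' @slot kConsecutive consecutive supra-threshold bins required to declare
#'   a detection (debouncing).
#' @slot refractory seconds after a transition during which the opposite
#'   detector is disabled.
#' @slot thetaClass classification posterior threshold.
#' @slot classDelay seconds after onset detection before the classification
#'   threshold is first evaluated. Detection fires on the rising edge of
#'   the onset transient, before condition-specific information has
#'   developed; the delay holds the decision until the high-information
#'   period.
#' @slot classTimeout seconds after onset detection at which the classifier
#'   emits its running best guess if the threshold was never reached.
#' @slot forceWindow seconds of regression engagement after onset
#'   detection; the force output is clamped at its value at the end of this
#'   window.
#' @export
setClass("GateConfig", representation(
  thetaOn = "numeric", thetaOff = "numeric", kConsecutive = "numeric",
  refractory = "numeric", thetaClass = "numeric", classDelay = "numeric",
  classTimeout = "numeric", forceWindow = "numeric"))

setValidity("GateConfig", function(object) {
  msg <- character()
  th <- c(object@thetaOn, object@thetaOff, object@thetaClass)
  if (any(th <= 0) || any(th >= 1)) msg <- c(msg, "thresholds must lie in (0, 1)")
  if (object@classTimeout <= 0 || object@forceWindow <= 0)
    msg <- c(msg, "windows must be > 0")
  if (object@classDelay < 0 || object@classDelay >= object@classTimeout)
    msg <- c(msg, "classDelay must lie in [0, classTimeout)")
  if (object@kConsecutive < 1) msg <- c(msg, "kConsecutive must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Trained gated decoder
#'
#' Onset/offset transient detectors (binary linear discriminants with
#' posterior outputs on the 20-D latents), a feature decoder (multiclass
#' discriminant for fingers, or latent-to-force linear regression), and the
#' state-machine configuration.
#'
#' @slot onsetDetector,offsetDetector `MASS::lda` fits with classes
#'   `"bg"`/`"event"`.
#' @slot task `"classification"` or `"force"`.
#' @slot classifier `MASS::lda` multiclass fit (classification task).
#' @slot forceCoef regression coefficients, intercept first (force task).
#' @slot classes condition labels the classifier can emit.
#' @slot peakLagOn,peakLagOff transient peak lag after the event used to
#'   place training windows, seconds.
#' @slot config [GateConfig].
#' @export
setClass("GatedDecoder", representation(
  onsetDetector = "ANY", offsetDetector = "ANY", task = "character",
  classifier = "ANY", forceCoef = "numericOrNULL", classes = "character",
  peakLagOn = "numeric", peakLagOff = "numeric", config = "GateConfig"))

#' Decoded output stream
#'
#' Per-bin decoder output with state annotations and an event log of state
#' transitions. Within every latched segment the output is constant by
#' construction; within idle it is the null class / zero force.
#'
#' @slot times bin times, seconds.
#' @slot output per-bin decoded value: numeric force, or class label with
#'   `"none"` as the null class.
#' @slot state per-bin machine state: `"idle"`, `"deciding"`, `"latched"`.
#' @slot events `DataFrame` log of transitions (time, event, value).
#' @slot task `"classification"` or `"force"`.
#' @slot binWidth seconds.
#' @export
setClass("DecodeTrace", representation(
  times = "numeric", output = "ANY", state = "character",
  events = "DataFrame", task = "character", binWidth = "numeric"))

#' Wiener cascade force decoder
#'
#' Linear stage from tapped latent history to target force followed by a
#' static 3rd-order polynomial read-out; the standard continuous baseline
#' for grasp-force decoding.
#'
#' @slot linearWeights coefficients of the linear stage, intercept first.
#' @slot nTaps number of history bins.
#' @slot polyCoeffs 4 coefficients of the 3rd-order polynomial stage.
#' @slot r2Linear,r2Composite training R-squared of each stage.
#' @slot ridged logical; TRUE when a ridge fallback handled rank deficiency.
#' @export
setClass("WienerCascade", representation(
  linearWeights = "numeric", nTaps = "numeric", polyCoeffs = "numeric",
  r2Linear = "numeric", r2Composite = "numeric", ridged = "logical"))

#' Continuous per-bin classifier baseline
#'
#' Multiclass linear discriminant over latents with an explicit null class;
#' predictions are stateless per-bin maximum-posterior labels.
#'
#' @slot fit `MASS::lda` object.
#' @slot classes class labels including `"none"`.
#' @export
setClass("ContinuousClassifier", representation(
  fit = "ANY", classes = "character"))

#' Leave-one-out evaluation report
#'
#' Per-trial records and session aggregates of the decoder comparison
#' metrics: epoch-mean force R-squared, normalized hold range, per-bin
#' classification accuracy, and click-duration ratios.
#'
#' @slot perTrial `DataFrame` of per-trial, per-decoder records.
#' @slot aggregates named list of session-level metrics.
#' @slot task `"classification"` or `"force"`.
#' @slot nFolds number of cross-validation folds run.
#' @slot excludedTrials trial ids excluded by the all-nonzero inclusion rule.
#' @export
setClass("EvalReport", representation(
  perTrial = "DataFrame", aggregates = "list", task = "character",
  nFolds = "numeric", excludedTrials = "numeric"))
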