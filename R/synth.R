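#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig] describing one synthetic session.
#' Defaults emulate the recording and task structure the analysis chain is
#' designed for: ~192 channels binned at 50 Hz, four task protocols,
#' condition-invariant onset/offset transients of 500 ms FWHM, condition
#' coding that peaks 200 ms after the onset-transient peak and decays to
#' `decayRatio` of its peak variance by the end of the hold, and
#' translation-related interference during carry/drag phases.
#'
#' The early/sustained split of the condition-coding signal is solved
#' analytically so that the variance ratio V(t2)/V(t1), *as measured on
#' exponentially smoothed rate estimates* (decay constant `smoothTau`),
#' equals `decayRatio`; t1 and t2 are the standard 100 ms windows centered
#' 200 ms after the onset-transient peak and 200 ms before the
#' offset-transient peak.
#'
#' @param task task protocol; grasp tasks default to 2 conditions (force
#'   levels), finger tasks to 5 (digits).
#' @param nConditions number of conditions; `NULL` picks the task default.
#' @param interferenceGain `NULL` picks the task default (1.5 for
#'   carry/drag, 0 otherwise). A nonzero value on a non-carry task is
#'   rejected with a warning (gain reset to 0), not an error.
#' @param jitter half-range of the uniform jitter on onset/offset times,
#'   seconds.
#' @param snrScale global scale on planted signal amplitudes; 0 yields a
#'   pure-baseline Poisson session.
#' @param handSignal `FALSE` simulates a reach-only stream: translation
#'   interference and noise, but no hand transients and no condition coding.
#' @param seed integer seed; generation is a pure function of the config.
#' @inheritParams SimConfig-class
#' @param nChannels,binWidth,nLatent,nTrials,fwhmOn,fwhmOff,condPeakLag,decayRatio,interferenceOverlap,baselineRate,smoothTau,trialLength,holdDuration,holdRange,onsetLead,arCoef,noiseSD,loadingGain see [SimConfig].
#' @return a [SimConfig]
#' @export
simConfig <- function(task = c("finger_click", "grasp_force", "grasp_carry",
                               "click_drag"),
                      nChannels = 192, binWidth = 0.02, nLatent = 20,
                      nConditions = NULL, nTrials = 40,
                      fwhmOn = 0.5, fwhmOff = 0.5, condPeakLag = 0.2,
                      decayRatio = 0.35, interferenceGain = NULL,
                      interferenceOverlap = 0.85, baselineRate = 20,
                      snrScale = 1, smoothTau = 0.4,
                      trialLength = NULL, holdDuration = NULL,
                      holdRange = 0.5, onsetLead = 2,
                      jitter = 0.1, arCoef = 0.9, noiseSD = 0.35,
                      loadingGain = 18, handSignal = TRUE, seed = 1) {
  task <- match.arg(task)
  carry <- task %in% c("grasp_carry", "click_drag")
  grasp <- grepl("grasp", task)
  if (is.null(nConditions)) nConditions <- if (grasp) 2L else 5L
  # grasp protocols hold the object for several seconds (long enough that
  # the middle of the grasp falls in the latched regime); finger clicks
  # are brief and variable
  if (is.null(holdDuration)) holdDuration <- if (grasp) 4 else 1.5
  if (is.null(trialLength)) trialLength <- if (grasp) 9 else 8
  if (is.null(interferenceGain)) interferenceGain <- if (carry) 3 else 0
  if (!carry && handSignal && interferenceGain > 0) {
    warning("interference is only defined for carry/drag tasks; gain reset to 0")
    interferenceGain <- 0
  }
  new("SimConfig", task = task, nChannels = nChannels, binWidth = binWidth,
      nLatent = nLatent, nConditions = as.integer(nConditions),
      nTrials = nTrials, fwhmOn = fwhmOn, fwhmOff = fwhmOff,
      condPeakLag = condPeakLag, decayRatio = decayRatio,
      interferenceGain = interferenceGain,
      interferenceOverlap = interferenceOverlap,
      baselineRate = baselineRate, snrScale = snrScale,
      smoothTau = smoothTau, trialLength = trialLength,
      holdDuration = holdDuration, holdRange = holdRange,
      onsetLead = onsetLead,
      jitterSD = jitter, arCoef = arCoef, noiseSD = noiseSD,
      loadingGain = loadingGain, handSignal = handSignal, seed = seed)
}

# Gaussian bump with unit peak.
.bump <- function(t, center, sigma) exp(-(t - center)^2 / (2 * sigma^2))

# Sustained condition-coding profile: the prolonged response builds over
# the first 0.8 s of the action and holds until release.
.sustainedProfile <- function(t, onset, offset) {
  pmin(1, pmax(0, (t - onset) / 0.8)) * (t <= offset)
}

# Solve the sustained/early amplitude ratio of the condition-coding signal
# so that the measured (smoothed) variance ratio over the t1/t2 windows
# equals rho. Profiles are evaluated on the session bin grid for a
# jitter-free template trial.
# t1 lives on the onset-aligned trace and t2 on the offset-aligned trace,
# so each window is evaluated in its own alignment frame (with the mean
# hold standing in for the variable per-trial holds, which only smear the
# opposite event).
.solveCondAmplitudes <- function(cfg) {
  dt <- cfg@binWidth
  sigOn <- cfg@fwhmOn / (2 * sqrt(2 * log(2)))
  on0 <- cfg@onsetLead
  off0 <- on0 + cfg@holdDuration
  tt <- seq(0, cfg@trialLength, by = dt)
  bumpOn <- .bump(tt, on0, sigOn)
  bumpCond <- .bump(tt, on0 + cfg@condPeakLag, sigOn)
  plateau <- .sustainedProfile(tt, on0, off0)
  sm <- .expSmoothCols(cbind(bumpOn, bumpCond, plateau), cfg@smoothTau, dt)
  peakLag <- tt[which.max(sm[, 1])] - on0   # smoothing shifts the peak
  t1 <- c(on0 + peakLag + 0.15, on0 + peakLag + 0.25)
  t2 <- c(off0 + peakLag - 0.25, off0 + peakLag - 0.15)
  w1 <- tt >= t1[1] & tt <= t1[2]
  w2 <- tt >= t2[1] & tt <= t2[2]
  B1 <- mean(sm[w1, 2]); B2 <- mean(sm[w2, 2])
  S1 <- mean(sm[w1, 3]); S2 <- mean(sm[w2, 3])
  r <- sqrt(cfg@decayRatio)
  den <- S2 - r * S1
  x <- (r * B1 - B2) / den
  if (den <= 0 || x < 0)
    stop("decayRatio is unreachable with this trial timing/smoothing")
  list(sustained = x, peakLag = peakLag, t1Window = t1 - on0,
       t2Window = t2 - off0, profileMeans = c(B1 = B1, B2 = B2,
                                              S1 = S1, S2 = S2))
}

#' Generate a synthetic session
#'
#' Simulates one session of binned population spiking with planted latent
#' structure. The noiseless latent trajectory is the sum of (a) a Gaussian
#' onset-transient bump on a fixed direction, identical across conditions;
#' (b) an analogous offset bump on an orthogonal direction; (c) a
#' condition-coding signal (early bump + sustained plateau, amplitudes
#' solved to hit the configured decay ratio) on per-condition orthogonal
#' directions; (d) for carry/drag tasks, translation interference with the
#' configured overlap into the condition subspace; plus (e) AR(1) latent
#' noise. Channel rates are `max(0, baseline + L z)` and counts are Poisson
#' draws at the configured seed; generation is fully deterministic given
#' the config.
#'
#' @param cfg a [SimConfig] from [simConfig()].
#' @return a [SpikeSession]; the planted [GroundTruth] is available via
#'   [groundTruth()].
#' @examples
#' sess <- simulateSession(simConfig(nChannels = 32, nTrials = 4, seed = 7))
#' sess
#' @export
simulateSession <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  .withSeed(cfg@seed, .simulateSessionImpl(cfg))
}

.simulateSessionImpl <- function(cfg) {
  dt <- cfg@binWidth
  k <- cfg@nLatent
  C <- cfg@nConditions
  n <- cfg@nTrials
  nBins <- round(n * cfg@trialLength / dt)
  times <- (seq_len(nBins) - 1) * dt
  sigOn <- cfg@fwhmOn / (2 * sqrt(2 * log(2)))
  sigOff <- cfg@fwhmOff / (2 * sqrt(2 * log(2)))
  grasp <- grepl("grasp", cfg@task)

  # -- trial timing and condition assignment (balanced, shuffled)
  starts <- (seq_len(n) - 1) * cfg@trialLength
  onsets <- starts + cfg@onsetLead + stats::runif(n, -cfg@jitterSD, cfg@jitterSD)
  holds <- cfg@holdDuration + stats::runif(n, -cfg@holdRange, cfg@holdRange)
  offsets <- onsets + holds
  cond <- sample(rep_len(seq_len(C), n))
  condLabels <- if (grasp) paste0("force", seq_len(C)) else paste0("digit", seq_len(C))
  forceLevels <- if (grasp) seq(1, 2, length.out = C) else rep(NA_real_, C)

  # -- planted directions: random orthonormal frame in latent space
  Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  dOn <- Q[, 1]; dOff <- Q[, 2]
  dCond <- Q[, 2 + seq_len(C), drop = FALSE]
  dExtra <- Q[, C + 3]
  ov <- cfg@interferenceOverlap
  # the in-subspace part points at a random direction of the condition
  # code (not its mean), so translation genuinely disrupts discrimination
  dInt <- ov * .unit(as.numeric(dCond %*% stats::rnorm(C))) +
    sqrt(1 - ov^2) * dExtra

  # -- signal amplitudes
  s <- cfg@snrScale
  aOn <- 6 * s; aOff <- 6 * s; condGain <- 3 * s
  amp <- .solveCondAmplitudes(cfg)
  condWeight <- if (grasp) forceLevels else rep(1, C)

  # -- noiseless latent trajectory
  # Translation interference both adds activity along its own direction
  # and suppresses the hand's condition code in proportion to its overlap
  # with the condition subspace (cross-effector interference: concurrent
  # arm translation degrades grasp/finger information).
  z <- matrix(0, nBins, k)
  interEnv <- numeric(nBins)
  if (cfg@interferenceGain > 0 && s > 0) {
    for (i in seq_len(n)) {
      t0 <- if (cfg@handSignal) onsets[i] + 0.2 else onsets[i]
      t1 <- offsets[i]
      w <- which(times >= t0 & times <= t1)
      if (!length(w)) next
      tw <- times[w]
      A <- stats::runif(1, 0.7, 1.3)
      fr <- stats::runif(1, 0.4, 0.8)
      ph <- stats::runif(1, 0, 2 * pi)
      env <- pmin(1, pmin(tw - t0, t1 - tw) / 0.3)
      interEnv[w] <- env
      g <- cfg@interferenceGain * s * A * sin(2 * pi * fr * (tw - t0) + ph) * env
      z[w, ] <- z[w, ] + outer(g, dInt)
    }
  }
  if (cfg@handSignal && s > 0) {
    suppress <- 1 - ov * interEnv
    for (i in seq_len(n)) {
      w <- which(times >= starts[i] & times < starts[i] + cfg@trialLength)
      tw <- times[w]
      f <- condGain * (.bump(tw, onsets[i] + cfg@condPeakLag, sigOn) +
                       amp$sustained * .sustainedProfile(tw, onsets[i], offsets[i]))
      z[w, ] <- z[w, ] +
        outer(aOn * .bump(tw, onsets[i], sigOn), dOn) +
        outer(aOff * .bump(tw, offsets[i], sigOff), dOff) +
        outer(f * suppress[w] * condWeight[cond[i]], dCond[, cond[i]])
    }
  }

  # -- AR(1) latent noise on every dimension
  innov <- matrix(stats::rnorm(nBins * k,
                               sd = cfg@noiseSD * sqrt(1 - cfg@arCoef^2)),
                  nBins, k)
  noise <- matrix(as.numeric(stats::filter(innov, cfg@arCoef,
                                           method = "recursive")), nBins, k)

  # -- Poisson emission through random loadings
  L <- matrix(stats::rnorm(cfg@nChannels * k), cfg@nChannels, k)
  L <- sweep(L, 2, sqrt(colSums(L^2)) / cfg@loadingGain, "/")
  rates <- pmax(0, cfg@baselineRate + L %*% t(z + noise))
  counts <- matrix(stats::rpois(length(rates), rates * dt),
                   nrow = cfg@nChannels)
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("ch%03d", seq_len(cfg@nChannels))

  events <- DataFrame(
    trial_id = seq_len(n), task = cfg@task,
    condition = condLabels[cond],
    force = if (grasp) forceLevels[cond] else rep(NA_real_, n),
    cue_time = starts + 0.5, onset_time = onsets, offset_time = offsets,
    trial_start = starts, trial_end = starts + cfg@trialLength)

  truth <- new("GroundTruth",
               uOn = .unit(as.numeric(L %*% dOn)),
               uOff = .unit(as.numeric(L %*% dOff)),
               uCond = apply(dCond, 2, function(v) .unit(as.numeric(L %*% v))),
               interferenceDir = .unit(as.numeric(L %*% dInt)),
               dOn = dOn, dOff = dOff, dCond = dCond, dInterference = dInt,
               loadings = L, latentTrue = z, plantedLag = cfg@condPeakLag,
               amplitudes = c(list(aOn = aOn, aOff = aOff,
                                   condGain = condGain), amp))

  se <- SummarizedExperiment(assays = list(counts = counts))
  new("SpikeSession", se, trialEvents = events, binWidth = dt) -> sess
  metadata(sess)$config <- cfg
  metadata(sess)$seed <- cfg@seed
  metadata(sess)$groundTruth <- truth
  sess
}
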