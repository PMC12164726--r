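test_that("a zero-signal config yields pure baseline Poisson counts", {
  cfg <- simConfig("finger_click", nChannels = 64, nTrials = 10,
                   snrScale = 0, seed = 5)
  sess <- simulateSession(cfg)
  cts <- spikeCounts(sess)
  lambda <- cfg@baselineRate * cfg@binWidth
  mrate <- mean(cts) / cfg@binWidth
  se <- sqrt(lambda / length(cts)) / cfg@binWidth
  expect_lt(abs(mrate - cfg@baselineRate), 3 * se)
  # Poisson variance ~ mean
  expect_lt(abs(var(as.numeric(cts)) / lambda - 1), 0.02)
})

test_that("generation is a pure function of the config", {
  cfg <- simConfig("finger_click", nChannels = 48, nTrials = 4, seed = 12)
  a <- simulateSession(cfg)
  b <- simulateSession(cfg)
  expect_identical(spikeCounts(a), spikeCounts(b))
  expect_identical(as.data.frame(trialEvents(a)), as.data.frame(trialEvents(b)))
  expect_equal(groundTruth(a)@latentTrue, groundTruth(b)@latentTrue)
  # and the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulateSession(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the planted noiseless transient has the configured FWHM", {
  cfg <- simConfig("finger_click", nChannels = 48, nTrials = 6, seed = 3)
  sess <- simulateSession(cfg)
  gt <- groundTruth(sess)
  proj <- as.numeric(gt@latentTrue %*% gt@dOn)
  tt <- binTimes(sess)
  ev <- trialEvents(sess)
  for (i in 1:3) {
    w <- which(tt >= ev$onset_time[i] - 1 & tt <= ev$onset_time[i] + 1)
    fw <- TransientGate:::.measureFWHM(proj[w], tt[w], baseline = 0)
    expect_lt(abs(fw - cfg@fwhmOn), cfg@binWidth)  # within one bin of 0.5 s
  }
  # closed form: sigma = FWHM / (2 sqrt(2 log 2))
  expect_equal(cfg@fwhmOn / (2 * sqrt(2 * log(2))), 0.2123, tolerance = 1e-3)
})

test_that("onset transient projections are condition-invariant", {
  sess <- simulateSession(simConfig("finger_click", nChannels = 48,
                                    nTrials = 10, seed = 7))
  gt <- groundTruth(sess)
  ev <- trialEvents(sess)
  tt <- binTimes(sess)
  proj <- as.numeric(gt@latentTrue %*% gt@dOn)
  peaks <- vapply(seq_len(nrow(ev)), function(i)
    max(proj[tt >= ev$onset_time[i] - 0.5 & tt <= ev$onset_time[i] + 0.5]),
    numeric(1))
  # identical planted amplitude for every condition on the noiseless
  # latent; the only variation is sub-bin sampling of the bump peak
  expect_lt(max(abs(peaks - mean(peaks))), 0.01)
})

test_that("interference alters the mid-hold condition-variance trace only when active", {
  base <- function(gain, seed = 9) {
    cfg <- simConfig("grasp_carry", nChannels = 48, nTrials = 8,
                     interferenceGain = gain, seed = seed)
    sess <- simulateSession(cfg)
    gt <- groundTruth(sess)
    z <- gt@latentTrue
    traj <- tgToyTrajectory(z)
    al <- alignAndAverage(traj, trialEvents(sess),
                          alignmentWindows(onset = c(-0.5, 2.5)))
    conditionVarianceTrace(al$perTrialOn, al$conditions, al$timesOn, "onset")
  }
  v0 <- base(0); v1 <- base(3)
  mid <- v0@times >= 1.0 & v0@times <= 2.0
  expect_gt(max(abs(v1@V[mid] - v0@V[mid])), 1e-3)
  # the planted structure outside the interference story matches exactly
  pre <- v0@times <= -0.2
  expect_equal(v1@V[pre], v0@V[pre], tolerance = 1e-8)
})

test_that("config validation rejects bad parameters, warns on misplaced interference", {
  expect_error(simConfig("finger_click", decayRatio = 0), "decayRatio")
  expect_error(simConfig("finger_click", decayRatio = 1.2), "decayRatio")
  expect_error(simConfig("finger_click", nConditions = 1), "nConditions")
  expect_warning(cfg <- simConfig("finger_click", interferenceGain = 2),
                 "carry")
  expect_identical(cfg@interferenceGain, 0)
  # carry task keeps its interference without complaint
  expect_silent(simConfig("grasp_carry", interferenceGain = 2))
})

test_that("trial events respect the session invariants", {
  sess <- simulateSession(simConfig("grasp_force", nChannels = 48,
                                    nTrials = 8, seed = 4))
  ev <- trialEvents(sess)
  expect_true(all(ev$onset_time < ev$offset_time))
  expect_true(all(ev$trial_start < ev$cue_time & ev$cue_time < ev$onset_time))
  expect_true(all(ev$trial_end <= ncol(sess) * binWidth(sess) + 1e-9))
  expect_true(all(table(ev$condition) >= 3))   # balanced assignment
  expect_true(all(ev$force %in% c(1, 2)))
  gt <- groundTruth(sess)
  expect_equal(sum(gt@uOn * gt@uOn), 1, tolerance = 1e-12)
  expect_lt(abs(sum(gt@dOn * gt@dOff)), 1e-12)
})
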