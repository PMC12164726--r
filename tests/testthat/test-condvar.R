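test_that("condition variance matches hand arithmetic on a 1-D toy", {
  # two conditions with means 1 and 3 at one bin: grand mean 2, V = 1
  perTrial <- array(0, c(1, 1, 4))
  perTrial[1, 1, ] <- c(1, 1, 3, 3)
  v <- conditionVarianceTrace(perTrial, c("a", "a", "b", "b"), 0, "onset")
  expect_identical(v@V, 1)
  # sample denominator doubles it (C - 1 = 1)
  v2 <- conditionVarianceTrace(perTrial, c("a", "a", "b", "b"), 0, "onset",
                               denom = "sample")
  expect_identical(v2@V, 2)
  # identical condition means give exactly zero
  perTrial[1, 1, ] <- c(2, 2, 2, 2)
  v3 <- conditionVarianceTrace(perTrial, c("a", "a", "b", "b"), 0, "onset")
  expect_identical(v3@V, 0)
  expect_error(conditionVarianceTrace(perTrial, c("a", "a", "a", "a"), 0,
                                      "onset"), "2 conditions")
})

test_that("V is rotation invariant and scales quadratically", {
  set.seed(41)
  nt <- 20; k <- 6; n <- 12
  perTrial <- array(rnorm(nt * k * n), c(nt, k, n))
  labs <- rep(c("a", "b", "c"), each = 4)
  v <- conditionVarianceTrace(perTrial, labs, seq_len(nt) * 0.02, "onset")
  R <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  rot <- perTrial
  for (i in seq_len(n)) rot[, , i] <- perTrial[, , i] %*% R
  vr <- conditionVarianceTrace(rot, labs, seq_len(nt) * 0.02, "onset")
  expect_equal(vr@V, v@V, tolerance = 1e-10)
  va <- conditionVarianceTrace(perTrial * 3, labs, seq_len(nt) * 0.02, "onset")
  expect_equal(va@V, 9 * v@V, tolerance = 1e-10)
})

test_that("t1/t2 summary is plain window arithmetic", {
  tm <- new("TransientModel",
            wOn = c(1, 0), wOff = c(0, 1),
            templateOn = numeric(3), templateOff = numeric(3),
            templateTimesOn = c(-0.02, 0, 0.02),
            templateTimesOff = c(-0.02, 0, 0.02),
            peakTimeOn = 0, peakTimeOff = 0,
            peakAmplitudeOn = 1, peakAmplitudeOff = 1,
            fwhmOn = 0.5, fwhmOff = 0.5, fwhmRawOn = 0.7, fwhmRawOff = 0.7,
            droppedTrials = 0)
  tt <- seq(-1, 1, by = 0.02)
  trOn <- new("VarianceTrace", times = tt,
              V = ifelse(abs(tt - 0.2) <= 0.06, 1.0, 0.5),
              alignment = "onset", nConditions = 2)
  trOff <- new("VarianceTrace", times = tt,
               V = ifelse(abs(tt + 0.2) <= 0.06, 0.35, 0.1),
               alignment = "offset", nConditions = 2)
  tm@templateOn <- exp(-tt^2 / 0.02); tm@templateTimesOn <- tt
  s <- summarizeT1T2(trOn, trOff, tm)
  expect_equal(s$Vt1, 1.0)
  expect_equal(s$Vt2, 0.35)
  expect_equal(s$ratio, 0.35)
  # constant trace gives ratio 1
  trFlat <- new("VarianceTrace", times = tt, V = rep(0.4, length(tt)),
                alignment = "offset", nConditions = 2)
  trFlatOn <- new("VarianceTrace", times = tt, V = rep(0.4, length(tt)) +
                    1e-6 * tt, alignment = "onset", nConditions = 2)
  expect_equal(summarizeT1T2(trFlatOn, trFlat, tm)$ratio, 1, tolerance = 1e-4)
})

test_that("lag estimation recovers constructed shifts exactly", {
  tt <- seq(-1.5, 2, by = 0.02)
  tmpl <- exp(-tt^2 / (2 * 0.04))
  shifted <- exp(-(tt - 0.2)^2 / (2 * 0.04))   # delayed by exactly 10 bins
  tr <- new("VarianceTrace", times = tt, V = shifted, alignment = "onset",
            nConditions = 2)
  out <- transientVarianceLag(tmpl, tt, tr)
  expect_equal(out$lag, 0.2)
  tr0 <- new("VarianceTrace", times = tt, V = tmpl, alignment = "onset",
             nConditions = 2)
  expect_identical(transientVarianceLag(tmpl, tt, tr0)$lag, 0)
  # negative shift recovered with sign
  lead <- exp(-(tt + 0.3)^2 / (2 * 0.04))
  trn <- new("VarianceTrace", times = tt, V = lead, alignment = "onset",
             nConditions = 2)
  expect_equal(transientVarianceLag(tmpl, tt, trn)$lag, -0.3)
  flat <- new("VarianceTrace", times = tt, V = rep(1, length(tt)),
              alignment = "onset", nConditions = 2)
  expect_error(transientVarianceLag(tmpl, tt, flat), "zero variance")
})

test_that("the decay ratio estimator is calibrated on noiseless planted data", {
  cfg <- simConfig("finger_click", nChannels = 48, nTrials = 12,
                   decayRatio = 0.35, seed = 14)
  sess <- simulateSession(cfg)
  gt <- groundTruth(sess)
  # the measurement operates on smoothed latents, as downstream would
  zs <- TransientGate:::.expSmoothCols(gt@latentTrue, cfg@smoothTau,
                                       cfg@binWidth)
  traj <- tgToyTrajectory(zs)
  ev <- trialEvents(sess)
  al <- alignAndAverage(traj, ev)
  trOn <- conditionVarianceTrace(al$perTrialOn, al$conditions, al$timesOn,
                                 "onset")
  trOff <- conditionVarianceTrace(al$perTrialOff, al$conditions, al$timesOff,
                                  "offset")
  # reference transient: the smoothed planted bump, peak lag from the solver
  amp <- gt@amplitudes
  tm <- new("TransientModel", wOn = c(1, rep(0, 19)), wOff = c(0, 1, rep(0, 18)),
            templateOn = as.numeric(al$avgOn %*% gt@dOn),
            templateOff = as.numeric(al$avgOff %*% gt@dOff),
            templateTimesOn = al$timesOn, templateTimesOff = al$timesOff,
            peakTimeOn = amp$peakLag, peakTimeOff = amp$peakLag,
            peakAmplitudeOn = 1, peakAmplitudeOff = 1,
            fwhmOn = 0.5, fwhmOff = 0.5, fwhmRawOn = 0.74, fwhmRawOff = 0.74,
            droppedTrials = 0)
  s <- summarizeT1T2(trOn, trOff, tm)
  expect_lt(abs(s$ratio - 0.35), 0.05)
})
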