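test_that("aligned averaging is an exact mean and drops edge trials", {
  # two trials with identical latent segments: average equals either
  k <- 4
  seg <- matrix(rnorm(50 * k), 50, k)
  z <- rbind(matrix(0, 100, k), seg, matrix(0, 150, k), seg,
             matrix(0, 100, k))
  traj <- tgToyTrajectory(z)
  events <- data.frame(onset_time = c(2.2, 6.2), offset_time = c(2.6, 6.6),
                       condition = c("a", "b"))
  win <- alignmentWindows(onset = c(-0.2, 0.78), offset = c(-0.58, 0.4))
  al <- alignAndAverage(traj, events, win)
  i0 <- which(abs(al$timesOn) < 1e-9)
  expect_equal(al$avgOn[i0:(i0 + 39), ], seg[11:50, ], tolerance = 1e-12)
  expect_identical(al$dropped, 0L)

  # an event too close to the recording edge is dropped and counted
  events2 <- rbind(events, data.frame(onset_time = 0.3, offset_time = 0.5,
                                      condition = "a"))
  al2 <- alignAndAverage(traj, events2, win)
  expect_identical(al2$dropped, 1L)
  expect_equal(dim(al2$perTrialOn)[3], 2L)
})

test_that("disjoint onset/offset activity separates into the planted axes", {
  tt <- seq(-1, 1, by = 0.02)
  k <- 6
  avgOn <- matrix(0, length(tt), k)
  avgOff <- matrix(0, length(tt), k)
  avgOn[, 1] <- exp(-tt^2 / 0.02)
  avgOff[, 2] <- exp(-tt^2 / 0.02)
  sub <- uniqueVarianceSubspaces(avgOn, avgOff)
  expect_identical(ncol(sub$sOn), 1L)
  expect_identical(ncol(sub$sOff), 1L)
  expect_gte(abs(sub$sOn[1, 1]), 0.999)
  expect_gte(abs(sub$sOff[2, 1]), 0.999)
  expect_lt(max(abs(crossprod(sub$sOn, sub$sOff))), 1e-8)
  # identical averages: everything is shared
  sub2 <- uniqueVarianceSubspaces(avgOn, avgOn)
  expect_identical(ncol(sub2$sOn), 0L)
  expect_identical(ncol(sub2$sOff), 0L)
  expect_identical(ncol(sub2$sShared), as.integer(k))
})

test_that("varimax matches a brute-force rotation search and preserves variance", {
  # two temporally disjoint unit bumps mixed at 45 degrees
  tt <- seq(0, 2, by = 0.02)
  b1 <- exp(-(tt - 0.5)^2 / (2 * 0.01))
  b2 <- exp(-(tt - 1.5)^2 / (2 * 0.01))
  mix <- cbind(b1, b2) %*% matrix(c(1, 1, -1, 1) / sqrt(2), 2, 2)
  out <- varimaxSparseComponents(mix, diag(2))
  # recovered time courses correlate with the disjoint bumps
  cors <- abs(cor(out$timecourses, cbind(b1, b2)))
  expect_true(all(apply(cors, 2, max) >= 0.99))
  # criterion value agrees with the brute-force oracle to 1e-6
  oracle <- tgVarimaxOracle2D(mix)
  expect_equal(tgVarimaxCriterion(out$timecourses), oracle$criterion,
               tolerance = 1e-6)
  # rotation is orthogonal; total variance preserved
  expect_lt(max(abs(crossprod(out$rotation) - diag(2))), 1e-8)
  expect_equal(sum(apply(out$timecourses, 2, var)), sum(apply(mix, 2, var)),
               tolerance = 1e-8)
})

test_that("varimax leaves already-sparse input unchanged up to sign/permutation", {
  tt <- seq(0, 2, by = 0.02)
  sparse <- cbind(exp(-(tt - 0.4)^2 / 0.005), exp(-(tt - 1.6)^2 / 0.005))
  out <- varimaxSparseComponents(sparse, diag(2))
  expect_gte(tgVarimaxCriterion(out$timecourses),
             tgVarimaxCriterion(sparse) - 1e-10)
  perm <- abs(crossprod(out$rotation))
  expect_equal(sort(apply(perm, 1, max)), c(1, 1), tolerance = 1e-6)
  # single-direction subspaces pass through untouched
  one <- varimaxSparseComponents(sparse, matrix(c(1, 0), 2, 1))
  expect_identical(one$rotation, matrix(1, 1, 1))
})

test_that("transient selection takes the largest modulation, flips sign, measures width", {
  tt <- seq(-1, 2, by = 0.02)
  tcs <- cbind(0.2 * exp(-(tt - 0.2)^2 / 0.02),
               -1.4 * exp(-(tt - 0.3)^2 / 0.02),    # winner, negative-going
               0.7 * exp(-(tt - 0.1)^2 / 0.02))
  dirs <- diag(3)
  sel <- selectTransient(tcs, tt, dirs, tau = 0)
  expect_identical(sel$index, 2L)
  expect_gt(sel$peakAmplitude, 0)                    # sign-flipped positive
  expect_equal(sel$w, c(0, -1, 0))
  expect_equal(sel$peakTime, 0.3, tolerance = 0.021)
  # FWHM of exp(-t^2/0.02): sigma = 0.1, width = 2.3548 sigma
  expect_equal(sel$fwhm, 0.2355, tolerance = 0.01)
  expect_error(selectTransient(tcs * 0, tt, dirs), "flat")
})

test_that("the filter-broadening correction inverts the smoothing exactly", {
  dt <- 0.02
  tt <- seq(-3, 4, by = dt)
  g <- exp(-tt^2 / (2 * (0.5 / 2.3548)^2))
  sm <- TransientGate:::.expSmoothCols(matrix(g), 0.4, dt)[, 1]
  raw <- TransientGate:::.measureFWHM(sm, tt, baseline = 0)
  expect_gt(raw, 0.7)                                 # smoothing broadens a lot
  expect_equal(TransientGate:::.correctFWHM(raw, 0.4), 0.5, tolerance = 0.002)
})

test_that("the full chain recovers the planted onset component on one session", {
  fx <- tgFittedSession()
  chOn <- as.numeric(fx$model@basis %*% fx$trans@wOn)
  chOff <- as.numeric(fx$model@basis %*% fx$trans@wOff)
  expect_gte(abs(sum(chOn * fx$truth@uOn)), 0.85)
  expect_gte(abs(sum(chOff * fx$truth@uOff)), 0.85)
  expect_lt(abs(sum(fx$trans@wOn * fx$trans@wOff)), 1e-8)
  expect_equal(sqrt(sum(fx$trans@wOn^2)), 1, tolerance = 1e-10)
  # the average response projected on the true direction peaks near onset
  al <- alignAndAverage(fx$traj, fx$events)
  bOn <- crossprod(fx$model@basis, fx$truth@uOn)
  tc <- al$avgOn %*% (bOn / sqrt(sum(bOn^2)))
  expect_lt(abs(al$timesOn[which.max(abs(tc))] - 0.2), 0.15)
})
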