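# The state machine is exercised directly with constructed posterior
# sequences; full-decoder behavior is covered on simulated sessions below.

test_that("onset debouncing requires k consecutive supra-threshold bins", {
  cfg <- gateConfig(kConsecutive = 2, classDelay = 0)
  posOn <- c(0.3, 0.95, 0.97, 0.2, rep(0.1, 16))
  posOff <- rep(0, 20)
  feat <- matrix(0.5, 20, 2, dimnames = list(NULL, c("a", "b")))
  tr <- gateStateMachine(posOn, posOff, feat, cfg)
  expect_identical(tr@state[1:2], c("idle", "idle"))
  expect_identical(tr@state[3], "deciding")    # second consecutive bin
  # a single supra-threshold bin is not enough
  tr2 <- gateStateMachine(c(0.95, 0.2, rep(0, 18)), posOff, feat, cfg)
  expect_true(all(tr2@state == "idle"))
})

test_that("class emission latches until offset detection", {
  cfg <- gateConfig(kConsecutive = 1, classDelay = 0, refractory = 0.1)
  n <- 60
  posOn <- c(rep(0, 4), 1, rep(0, n - 5))
  posOff <- c(rep(0, 39), 1, rep(0, n - 40))
  feat <- matrix(0.3, n, 3, dimnames = list(NULL, c("index", "middle", "thumb")))
  feat[10:40, 1] <- 0.92                        # "index" becomes confident at bin 10
  tr <- gateStateMachine(posOn, posOff, feat, cfg)
  expect_identical(tr@output[10], "index")
  expect_true(all(tr@output[10:39] == "index")) # held until offset detection
  expect_identical(tr@output[40], "none")
  expect_identical(tr@state[40], "idle")
  ev <- as.data.frame(tr@events)
  expect_identical(ev$event, c("onset_detected", "class_emitted",
                               "offset_detected"))
  expect_identical(latchedOutputRanges(tr), 0)
})

test_that("the class delay postpones threshold evaluation and timeouts emit argmax", {
  cfg <- gateConfig(kConsecutive = 1, classDelay = 0.2, classTimeout = 0.5)
  n <- 80
  posOn <- c(0, 1, rep(0, n - 2))
  feat <- matrix(0.2, n, 2, dimnames = list(NULL, c("a", "b")))
  feat[, 1] <- 0.95                              # confident from the start
  tr <- gateStateMachine(posOn, rep(0, n), feat, cfg)
  ev <- as.data.frame(tr@events)
  # emission waits out the 0.2 s delay (10 bins after detection at bin 2)
  expect_equal(ev$time[ev$event == "class_emitted"], tr@times[12])
  # never-confident posteriors emit the running argmax at timeout
  feat2 <- matrix(1 / 3, n, 2, dimnames = list(NULL, c("a", "b")))
  feat2[, 2] <- 0.4
  tr2 <- gateStateMachine(posOn, rep(0, n), feat2, cfg)
  ev2 <- as.data.frame(tr2@events)
  expect_identical(ev2$event[2], "class_timeout")
  expect_identical(ev2$value[2], "b")
  expect_equal(ev2$time[2] - ev2$time[1], cfg@classTimeout, tolerance = 0.021)
})

test_that("force output is clamped exactly at the decision-window end", {
  cfg <- gateConfig(kConsecutive = 1, forceWindow = 1.0, refractory = 0.2)
  n <- 150
  posOn <- c(0, 1, rep(0, n - 2))
  pred <- seq(0.2, 3, length.out = n)            # rising prediction
  tr <- gateStateMachine(posOn, rep(0, n), pred, cfg, task = "force")
  wEnd <- 2 + 50 - 1                             # detection bin + 1 s window
  expect_equal(tr@output[3:wEnd], pred[3:wEnd])  # live regression output
  latched <- tr@state == "latched"
  expect_true(any(latched))
  expect_identical(diff(range(tr@output[latched])), 0)   # range exactly 0
  expect_equal(unique(tr@output[latched]), pred[wEnd])   # clamp = window end
})

test_that("without detector confidence the output is identically null", {
  cfg <- gateConfig()
  n <- 400
  set.seed(7)
  posOn <- runif(n, 0, 0.89)                     # never reaches theta
  feat <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  tr <- gateStateMachine(posOn, runif(n), feat, cfg)
  expect_true(all(tr@output == "none"))
  expect_true(all(tr@state == "idle"))
})

test_that("decisions are causal and states follow idle->deciding->latched->idle", {
  cfg <- gateConfig(kConsecutive = 2, classDelay = 0.1)
  set.seed(17)
  n <- 600
  posOn <- pmin(1, abs(rnorm(n, 0.5, 0.35)))
  posOff <- pmin(1, abs(rnorm(n, 0.5, 0.35)))
  feat <- t(apply(matrix(rexp(n * 3), n, 3), 1, function(r) r / sum(r)))
  colnames(feat) <- c("a", "b", "c")
  tr <- gateStateMachine(posOn, posOff, feat, cfg)
  # truncation never changes earlier decisions
  half <- 300
  trH <- gateStateMachine(posOn[1:half], posOff[1:half],
                          feat[1:half, , drop = FALSE], cfg)
  expect_identical(tr@output[1:half], trH@output)
  expect_identical(tr@state[1:half], trH@state)
  # legal transitions only
  num <- c(idle = 1, deciding = 2, latched = 3)[tr@state]
  steps <- paste(num[-length(num)], num[-1])
  expect_true(all(steps %in% c("1 1", "1 2", "2 2", "2 3", "3 3", "3 1")))
})

test_that("training is deterministic and recovers noiseless linear force coding", {
  fx <- tgFittedSession()
  d1 <- trainGatedDecoder(fx$traj, fx$events, fx$trans, "classification")
  d2 <- trainGatedDecoder(fx$traj, fx$events, fx$trans, "classification")
  expect_identical(d1@classifier$means, d2@classifier$means)
  expect_identical(d1@onsetDetector$scaling, d2@onsetDetector$scaling)

  # noiseless planted linear force code: training recovery is exact.
  # Latents carry the cued force on a fixed direction during each trial,
  # plus a clean onset/offset bump so the detectors can be fit.
  k <- 20; n <- 4000; dtb <- 0.02
  tt <- (seq_len(n) - 1) * dtb
  set.seed(52)
  z <- matrix(rnorm(n * k, sd = 0.5), n, k)   # nuisance dims for the LDAs
  z[, 1] <- 0
  events <- data.frame(trial_id = 1:4, condition = rep(c("f1", "f2"), 2),
                       force = rep(c(1, 2), 2),
                       onset_time = c(5, 25, 45, 65),
                       offset_time = c(15, 35, 55, 75),
                       trial_start = c(0, 20, 40, 60),
                       trial_end = c(20, 40, 60, 80))
  for (i in 1:4) {
    hold <- tt >= events$onset_time[i] & tt <= events$offset_time[i]
    z[hold, 1] <- events$force[i]
    z[, 2] <- z[, 2] + exp(-(tt - events$onset_time[i])^2 / 0.02)
    z[, 3] <- z[, 3] + exp(-(tt - events$offset_time[i])^2 / 0.02)
  }
  traj <- tgToyTrajectory(z)
  tm <- fx$trans; tm@peakTimeOn <- 0; tm@peakTimeOff <- 0
  dec <- trainGatedDecoder(traj, events, tm, "force")
  target <- cuedForceStream(events, tt)
  pred <- as.numeric(cbind(1, z) %*% dec@forceCoef)
  sel <- target > 0
  expect_lt(max(abs(pred[sel] - target[sel])), 1e-6)  # training R^2 = 1
})

test_that("decoding a fitted session produces accurate latched clicks", {
  fx <- tgFittedSession()
  dec <- trainGatedDecoder(fx$traj, fx$events, fx$trans, "classification")
  tr <- decodeStream(fx$traj, dec)
  cm <- clickMetrics(tr@output, fx$traj@times, fx$events)
  expect_gte(mean(cm$clickClass == as.character(fx$events$condition)), 0.9)
  expect_true(all(latchedOutputRanges(tr) == 0))
  expect_gte(median(cm$durationRatio), 0.8)
})
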