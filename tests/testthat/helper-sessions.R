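# Shared fixtures, built once per test run and cached.

.tg_cache <- new.env(parent = emptyenv())

# A compact finger-click session with the full chain fitted: enough signal
# to recover the planted structure, small enough to keep tests fast.
tgFittedSession <- function(seed = 101) {
  key <- paste0("fitted", seed)
  if (!is.null(.tg_cache[[key]])) return(.tg_cache[[key]])
  cfg <- simConfig("finger_click", nChannels = 96, nTrials = 10,
                   snrScale = 2, seed = seed)
  sess <- smoothCounts(simulateSession(cfg))
  model <- fitFactorModel(sess, 20, maxIter = 200)
  traj <- projectLatents(sess, model)
  ev <- trialEvents(sess)
  trans <- findTransients(traj, ev)
  out <- list(cfg = cfg, sess = sess, model = model, traj = traj,
              events = ev, trans = trans,
              truth = groundTruth(sess))
  .tg_cache[[key]] <- out
  out
}

# Latent trajectory with hand-built content on an exact bin grid.
tgToyTrajectory <- function(z, dt = 0.02) {
  new("LatentTrajectory", z = z, binWidth = dt,
      times = (seq_len(nrow(z)) - 1) * dt)
}

# Brute-force varimax oracle for 2-column problems: scan the rotation
# angle in fine steps and return the best criterion value.
tgVarimaxOracle2D <- function(tc, stepDeg = 0.1) {
  best <- -Inf; bestA <- 0
  for (a in seq(0, 90 - stepDeg, by = stepDeg)) {
    r <- a * pi / 180
    R <- matrix(c(cos(r), -sin(r), sin(r), cos(r)), 2, 2)
    v <- sum(apply((tc %*% R)^2, 2, stats::var))
    if (v > best) { best <- v; bestA <- a }
  }
  list(criterion = best, angle = bestA)
}

tgVarimaxCriterion <- function(A) sum(apply(A^2, 2, stats::var))
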