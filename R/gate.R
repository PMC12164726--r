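#' Gated decoder configuration
#'
#' @param thetaOn,thetaOff onset/offset detector posterior thresholds.
#' @param kConsecutive consecutive supra-threshold bins required.
#' @param refractory seconds after a transition during which the opposite
#'   detector is disabled.
#' @param thetaClass classification posterior threshold.
#' @param classDelay evidence delay after detection before the
#'   classification threshold is evaluated (see [GateConfig]).
#' @param classTimeout seconds before the classifier emits its best guess.
#' @param forceWindow seconds of regression engagement after onset
#'   detection.
#' @return a [GateConfig]
#' @export
gateConfig <- function(thetaOn = 0.9, thetaOff = 0.9, kConsecutive = 2,
                       refractory = 0.5, thetaClass = 0.9,
                       classDelay = 0.3, classTimeout = 1.0,
                       forceWindow = 1.0) {
  new("GateConfig", thetaOn = thetaOn, thetaOff = thetaOff,
      kConsecutive = kConsecutive, refractory = refractory,
      thetaClass = thetaClass, classDelay = classDelay,
      classTimeout = classTimeout, forceWindow = forceWindow)
}

#' Train a gated decoder
#'
#' Trains the three components of the gated architecture on labeled
#' trials: (1) an onset detector -- a binary linear discriminant on the
#' latents with positive labels within +/-100 ms of the per-trial onset
#' transient peak and negatives elsewhere, excluding a +/-300 ms guard
#' band; (2) an analogous offset detector; and (3) the feature decoder --
#' for finger tasks a multiclass linear discriminant trained on bins in the
#' high-information window after the transient peak, for force tasks an
#' ordinary least-squares regression from latents to cued force over the
#' first second after onset. Detector discriminants use equal class priors
#' so the posterior threshold is not dominated by the label imbalance. All
#' solvers are deterministic.
#'
#' @param traj a [LatentTrajectory]
#' @param events trial event table with `onset_time`, `offset_time`,
#'   `condition`, and `force` for grasp tasks.
#' @param transients a [TransientModel] (supplies the transient peak lags).
#' @param task `"classification"` (fingers) or `"force"` (grasp).
#' @param cfg a [GateConfig]
#' @param shrinkage covariance shrinkage of the finger classifier, in
#'   \[0, 1\): the pooled within-class covariance is blended with a scaled
#'   identity. Shrinkage-regularized discriminants are standard practice
#'   in BCI decoding; here the regularization keeps the class posterior
#'   calibrated in the low-information bins right after onset detection,
#'   so the machine waits for condition evidence instead of emitting an
#'   overconfident early guess.
#' @return a [GatedDecoder]
#' @export
trainGatedDecoder <- function(traj, events, transients,
                              task = c("classification", "force"),
                              cfg = gateConfig(), shrinkage = 0.3) {
  task <- match.arg(task)
  z <- traj@z
  tt <- traj@times
  lagOn <- transients@peakTimeOn
  lagOff <- transients@peakTimeOff

  detectorFit <- function(eventTimes, lag) {
    center <- eventTimes + lag
    lab <- rep("bg", length(tt))
    guard <- rep(FALSE, length(tt))
    for (ct in center) {
      lab[abs(tt - ct) <= 0.1] <- "event"
      guard <- guard | (abs(tt - ct) <= 0.3 & abs(tt - ct) > 0.1)
    }
    sel <- !guard
    if (length(unique(lab[sel])) < 2)
      stop("degenerate detector labels")
    MASS::lda(z[sel, , drop = FALSE], grouping = factor(lab[sel]),
              prior = c(0.5, 0.5))
  }
  onDet <- detectorFit(events$onset_time, lagOn)
  offDet <- detectorFit(events$offset_time, lagOff)

  # actual detection times on the training stream, so the classifier sees
  # the same early low-information bins it will face during decoding
  posOn <- stats::predict(onDet, z)$posterior[, "event"]
  detTime <- vapply(seq_len(nrow(events)), function(i) {
    w <- which(tt >= events$onset_time[i] - 0.3 &
                 tt <= events$onset_time[i] + lagOn + 0.5)
    run <- 0L
    for (j in w) {
      run <- if (posOn[j] >= cfg@thetaOn) run + 1L else 0L
      if (run >= cfg@kConsecutive) return(tt[j])
    }
    events$onset_time[i] + lagOn      # fallback: no detection in window
  }, numeric(1))

  classes <- character(0); clsFit <- NULL; forceCoef <- NULL
  if (task == "classification") {
    lab <- rep(NA_character_, length(tt))
    for (i in seq_len(nrow(events))) {
      t0 <- detTime[i]
      lab[tt >= t0 & tt <= t0 + cfg@classTimeout] <-
        as.character(events$condition[i])
    }
    sel <- !is.na(lab)
    classes <- sort(unique(lab[sel]))
    if (length(classes) < 2) stop("degenerate classifier labels")
    clsFit <- .shrinkLDA(z[sel, , drop = FALSE], lab[sel], shrinkage)
  } else {
    sel <- rep(FALSE, length(tt)); target <- rep(0, length(tt))
    for (i in seq_len(nrow(events))) {
      w <- tt >= events$onset_time[i] &
        tt <= events$onset_time[i] + cfg@forceWindow
      sel <- sel | w
      target[w] <- events$force[i]
    }
    X <- cbind(1, z[sel, , drop = FALSE])
    forceCoef <- as.numeric(qr.coef(qr(X), target[sel]))
    forceCoef[is.na(forceCoef)] <- 0
  }
  new("GatedDecoder", onsetDetector = onDet, offsetDetector = offDet,
      task = task, classifier = clsFit, forceCoef = forceCoef,
      classes = classes, peakLagOn = lagOn, peakLagOff = lagOff,
      config = cfg)
}

#' Run the gated state machine over per-bin detector evidence
#'
#' The causal core of the decoder, exposed directly so that the state
#' logic can be driven with arbitrary posterior sequences. States progress
#' idle -> deciding -> latched -> idle only. In idle the output is the
#' null class / zero force and the onset posterior is watched; after
#' `kConsecutive` supra-threshold bins the machine enters deciding. For
#' classification, the class posterior is evaluated per bin until its
#' maximum reaches `thetaClass` (or `classTimeout` elapses, at which point
#' the running argmax is emitted), then the emitted class is latched. For
#' force, the regression prediction is output for `forceWindow` seconds and
#' then clamped at its current value. In latched the output is constant
#' and the offset posterior is watched (outside the refractory period);
#' offset detection returns the machine to idle. Every input yields a
#' valid trace; anomalies (timeout emissions) are recorded in the event
#' log.
#'
#' @param posOn,posOff per-bin onset/offset detector posteriors.
#' @param feature per-bin feature evidence: a bins x classes posterior
#'   matrix (classification) or numeric force predictions.
#' @param cfg a [GateConfig]
#' @param task `"classification"` or `"force"`.
#' @param classes class labels matching the columns of `feature`.
#' @param times bin times, seconds.
#' @param binWidth seconds.
#' @return a [DecodeTrace]
#' @export
gateStateMachine <- function(posOn, posOff, feature, cfg,
                             task = c("classification", "force"),
                             classes = colnames(feature),
                             times = (seq_along(posOn) - 1) * binWidth,
                             binWidth = 0.02) {
  task <- match.arg(task)
  n <- length(posOn)
  kReq <- cfg@kConsecutive
  refBins <- round(cfg@refractory / binWidth)
  outNull <- if (task == "force") 0 else "none"
  output <- if (task == "force") numeric(n) else rep("none", n)
  state <- rep("idle", n)
  ev <- list()
  log1 <- function(time, event, value)
    ev[[length(ev) + 1L]] <<- data.frame(time = time, event = event,
                                         value = as.character(value))
  st <- "idle"
  runOn <- 0L; runOff <- 0L
  lastTransition <- -Inf     # bin index of the most recent transition
  decideStart <- NA_integer_
  latchVal <- outNull

  for (i in seq_len(n)) {
    if (st == "idle") {
      output[i] <- outNull
      if (i - lastTransition > refBins) {
        runOn <- if (posOn[i] >= cfg@thetaOn) runOn + 1L else 0L
        if (runOn >= kReq) {
          st <- "deciding"; decideStart <- i; lastTransition <- i
          runOn <- 0L; runOff <- 0L
          log1(times[i], "onset_detected", "")
          state[i] <- "deciding"
          if (task == "force") output[i] <- feature[i]
          next
        }
      }
    } else if (st == "deciding") {
      if (task == "classification") {
        output[i] <- "none"
        pmax_i <- max(feature[i, ])
        timeout <- (i - decideStart) * binWidth >= cfg@classTimeout
        ready <- (i - decideStart) * binWidth >= cfg@classDelay
        if ((ready && pmax_i >= cfg@thetaClass) || timeout) {
          latchVal <- classes[which.max(feature[i, ])]
          output[i] <- latchVal
          st <- "latched"
          log1(times[i],
               if (timeout && pmax_i < cfg@thetaClass) "class_timeout"
               else "class_emitted", latchVal)
        }
      } else {
        output[i] <- feature[i]
        if ((i - decideStart + 1L) * binWidth >= cfg@forceWindow) {
          latchVal <- feature[i]
          st <- "latched"
          log1(times[i], "force_clamped", format(latchVal))
        }
      }
    } else { # latched
      output[i] <- latchVal
      if (i - lastTransition > refBins) {
        runOff <- if (posOff[i] >= cfg@thetaOff) runOff + 1L else 0L
        if (runOff >= kReq) {
          st <- "idle"; lastTransition <- i
          runOff <- 0L; runOn <- 0L
          output[i] <- outNull
          latchVal <- outNull
          log1(times[i], "offset_detected", "")
        }
      }
    }
    state[i] <- st
  }
  evDF <- if (length(ev)) DataFrame(do.call(rbind, ev)) else
    DataFrame(time = numeric(0), event = character(0), value = character(0))
  new("DecodeTrace", times = times, output = output, state = state,
      events = evDF, task = task, binWidth = binWidth)
}

#' Decode a latent stream with a gated decoder
#'
#' Computes the per-bin detector and feature evidence (each bin uses only
#' its own latent state, which is itself a causal function of past counts)
#' and runs the gated state machine over the stream.
#'
#' @param traj a [LatentTrajectory]
#' @param decoder a [GatedDecoder]
#' @return a [DecodeTrace]
#' @export
decodeStream <- function(traj, decoder) {
  z <- traj@z
  posOn <- stats::predict(decoder@onsetDetector, z)$posterior[, "event"]
  posOff <- stats::predict(decoder@offsetDetector, z)$posterior[, "event"]
  feature <- if (decoder@task == "classification") {
    p <- .shrinkLDAPosterior(decoder@classifier, z)
    p[, decoder@classes, drop = FALSE]
  } else {
    as.numeric(cbind(1, z) %*% decoder@forceCoef)
  }
  gateStateMachine(posOn, posOff, feature, decoder@config, decoder@task,
                   classes = decoder@classes, times = traj@times,
                   binWidth = traj@binWidth)
}

#' Output range within each latched segment
#'
#' Returns the output range of every contiguous latched segment of a
#' decode trace (for classification, the number of distinct labels minus
#' one). The gated architecture guarantees these are exactly zero; the
#' function exists so that the guarantee can be asserted on decoded data.
#'
#' @param trace a [DecodeTrace]
#' @return numeric vector, one entry per latched segment
#' @export
latchedOutputRanges <- function(trace) {
  r <- rle(trace@state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values == "latched")
  vapply(idx, function(j) {
    v <- trace@output[starts[j]:ends[j]]
    if (is.numeric(v)) diff(range(v)) else as.numeric(length(unique(v)) - 1L)
  }, numeric(1))
}


# Shrinkage-regularized linear discriminant: class means with pooled
# covariance blended toward a scaled identity. Deterministic.
.shrinkLDA <- function(x, labels, shrinkage) {
  labels <- factor(labels)
  mu <- t(vapply(levels(labels), function(l)
    colMeans(x[labels == l, , drop = FALSE]), numeric(ncol(x))))
  xc <- x - mu[as.integer(labels), , drop = FALSE]
  S <- crossprod(xc) / (nrow(x) - nlevels(labels))
  S <- (1 - shrinkage) * S + shrinkage * diag(mean(diag(S)), ncol(x))
  list(means = mu, cov = S, covInv = solve(S), classes = levels(labels),
       prior = as.numeric(table(labels)) / nrow(x))
}

.shrinkLDAPosterior <- function(fit, z) {
  # linear discriminant scores g_c = z' Sigma^-1 mu_c - mu_c' Sigma^-1 mu_c/2
  A <- fit$covInv %*% t(fit$means)              # p x C
  g <- z %*% A - rep(colSums(t(fit$means) * A) / 2, each = nrow(z))
  g <- g + rep(log(fit$prior), each = nrow(z))
  g <- g - apply(g, 1, max)
  p <- exp(g)
  p <- p / rowSums(p)
  colnames(p) <- fit$classes
  p
}
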