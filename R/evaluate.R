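#' Trial epoch segmentation
#'
#' Splits a trial into pre-grasp, middle-of-grasp, and after-grasp epochs:
#' the 25th--75th percentile spans of, respectively, trial start to onset,
#' onset to offset, and offset to trial end. Windows are half-open on the
#' bin grid; a degenerate phase yields a single bin at its midpoint.
#'
#' @param trial one row of the trial event table (list-like with
#'   `trial_start`, `onset_time`, `offset_time`, `trial_end`).
#' @param times bin times of the stream being evaluated, seconds.
#' @return list of integer bin-index vectors `pre`, `mid`, `post`.
#' @export
epochSegments <- function(trial, times) {
  if (!(trial$trial_start < trial$onset_time &&
        trial$onset_time < trial$offset_time &&
        trial$offset_time < trial$trial_end))
    stop("trial events must satisfy start < onset < offset < end")
  seg <- function(a, b) {
    lo <- a + 0.25 * (b - a); hi <- a + 0.75 * (b - a)
    idx <- which(times >= lo & times < hi)
    if (!length(idx)) idx <- which.min(abs(times - (lo + hi) / 2))
    idx
  }
  list(pre = seg(trial$trial_start, trial$onset_time),
       mid = seg(trial$onset_time, trial$offset_time),
       post = seg(trial$offset_time, trial$trial_end))
}

#' Force metrics for one decoded trial
#'
#' Epoch means of the decoded force over the pre/mid/post windows and the
#' normalized range over the middle-of-grasp epoch, `(max - min) / mean`,
#' the prediction-stability measure. A non-positive middle-epoch mean makes
#' the normalized range undefined; the record is flagged and excluded from
#' range aggregates.
#'
#' @param output per-bin decoded force.
#' @param times bin times.
#' @param trial one trial event row.
#' @return list with `epochMeans` (length 3), `normRange`, `flagged`.
#' @export
forceMetrics <- function(output, times, trial) {
  ep <- epochSegments(trial, times)
  m <- vapply(ep, function(idx) mean(output[idx]), numeric(1))
  mid <- output[ep$mid]
  flagged <- mean(mid) <= 0
  normRange <- if (flagged) NA_real_ else (max(mid) - min(mid)) / mean(mid)
  list(epochMeans = m, normRange = normRange, flagged = flagged)
}

#' Click metrics for a decoded classification stream
#'
#' Timepoint accuracy is the fraction of all bins (inter-trial null bins
#' included) whose prediction equals the cued label. Per click, the
#' decoded duration is the length of the contiguous non-null run with
#' maximal overlap with the cued click window (ties toward the earliest
#' run), divided by the cued duration; a click with no overlapping run
#' scores 0.
#'
#' @param output per-bin predicted labels (`"none"` = null).
#' @param times bin times.
#' @param events trial event table.
#' @return list with `accuracy`, per-trial `durationRatio`, and the
#'   per-trial emitted class `clickClass` (label of the overlapping run,
#'   `"none"` if absent).
#' @export
clickMetrics <- function(output, times, events) {
  cued <- cuedLabelStream(events, times)
  accuracy <- mean(output == cued)
  r <- rle(output)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values != "none")
  dt <- diff(times[1:2])
  n <- nrow(events)
  ratio <- numeric(n); cls <- character(n)
  for (i in seq_len(n)) {
    w <- c(events$onset_time[i], events$offset_time[i])
    ov <- vapply(runs, function(j) {
      a <- times[starts[j]]; b <- times[ends[j]] + dt
      max(0, min(b, w[2]) - max(a, w[1]))
    }, numeric(1))
    if (!length(ov) || max(ov) <= 0) { ratio[i] <- 0; cls[i] <- "none"; next }
    j <- runs[which.max(ov)]          # which.max ties -> earliest run
    ratio[i] <- (r$lengths[j] * dt) / (w[2] - w[1])
    cls[i] <- r$values[j]
  }
  list(accuracy = accuracy, durationRatio = ratio, clickClass = cls)
}

#' Leave-one-out cross-validated decoder comparison
#'
#' For each trial: refit the entire chain on the remaining trials -- latent
#' model, transient components, gated decoder, and the continuous baseline
#' (Wiener cascade for force tasks, per-bin discriminant for finger tasks)
#' -- with no access to the held-out trial, then decode the held-out
#' trial's continuous stream segment and score it. Trials for which any
#' compared decoder produces an all-null prediction are flagged and
#' excluded from the aggregates. Smoothing is a fixed causal filter (no
#' fitted parameters) and is applied once to the whole session.
#'
#' @param session a [SpikeSession] (counts; rates are computed if absent).
#' @param task `"classification"` or `"force"`.
#' @param nFactors latent dimensionality.
#' @param gateCfg a [GateConfig]
#' @param windows an [AlignmentWindows]
#' @param nTaps Wiener history taps.
#' @param tau smoothing decay constant, seconds.
#' @return an [EvalReport]
#' @export
looCrossValidate <- function(session, task = c("classification", "force"),
                             nFactors = 20, gateCfg = gateConfig(),
                             windows = alignmentWindows(), nTaps = 10,
                             tau = 0.4) {
  task <- match.arg(task)
  ev <- trialEvents(session)
  n <- nrow(ev)
  if (n < 3) stop("need at least 3 trials for leave-one-out evaluation")
  if (!"rates" %in% assayNames(session))
    session <- smoothCounts(session, tau = tau)
  rates <- firingRates(session)
  dt <- binWidth(session)
  tt <- binTimes(session)

  rows <- list()
  for (i in seq_len(n)) {
    testBins <- which(tt >= ev$trial_start[i] & tt < ev$trial_end[i])
    trainBins <- setdiff(seq_along(tt), testBins)
    # event times of trials after the excised block refer to the spliced
    # training timeline
    trainEv <- ev[-i, , drop = FALSE]
    gap <- length(testBins) * dt
    for (cc in c("cue_time", "onset_time", "offset_time",
                 "trial_start", "trial_end")) {
      late <- trainEv[[cc]] >= ev$trial_end[i] - 1e-9
      trainEv[[cc]][late] <- trainEv[[cc]][late] - gap
    }

    model <- fitFactorModel(rates[, trainBins, drop = FALSE], nFactors)
    zAll <- crossprod(model@basis, rates - model@channelMeans)
    trajTrain <- new("LatentTrajectory", z = t(zAll[, trainBins, drop = FALSE]),
                     binWidth = dt,
                     times = (seq_along(trainBins) - 1) * dt)
    trajTest <- new("LatentTrajectory", z = t(zAll[, testBins, drop = FALSE]),
                    binWidth = dt, times = tt[testBins])
    trans <- findTransients(trajTrain, trainEv, windows, tau = tau)
    gated <- trainGatedDecoder(trajTrain, trainEv, trans, task, gateCfg)
    traceG <- decodeStream(trajTest, gated)

    if (task == "force") {
      wc <- fitWienerCascade(trajTrain, cuedForceStream(trainEv, trajTrain@times),
                             nTaps = nTaps)
      predW <- predictWienerCascade(wc, trajTest)
      fmG <- forceMetrics(traceG@output, trajTest@times, ev[i, ])
      fmW <- forceMetrics(predW, trajTest@times, ev[i, ])
      latchOK <- all(latchedOutputRanges(traceG) == 0)
      rows[[i]] <- data.frame(
        trial_id = ev$trial_id[i], condition = as.character(ev$condition)[i],
        target = ev$force[i],
        gated_pre = fmG$epochMeans[1], gated_mid = fmG$epochMeans[2],
        gated_post = fmG$epochMeans[3], gated_range = fmG$normRange,
        wiener_pre = fmW$epochMeans[1], wiener_mid = fmW$epochMeans[2],
        wiener_post = fmW$epochMeans[3], wiener_range = fmW$normRange,
        gated_flagged = fmG$flagged, wiener_flagged = fmW$flagged,
        latch_ok = latchOK)
    } else {
      cc <- fitContinuousClassifier(trajTrain,
                                    cuedLabelStream(trainEv, trajTrain@times))
      predC <- predictContinuousClassifier(cc, trajTest)
      cmG <- clickMetrics(traceG@output, trajTest@times, ev[i, ])
      cmC <- clickMetrics(predC, trajTest@times, ev[i, ])
      rows[[i]] <- data.frame(
        trial_id = ev$trial_id[i], condition = as.character(ev$condition)[i],
        gated_class = cmG$clickClass, gated_accuracy = cmG$accuracy,
        gated_duration_ratio = cmG$durationRatio,
        cont_class = cmC$clickClass, cont_accuracy = cmC$accuracy,
        cont_duration_ratio = cmC$durationRatio,
        gated_null = all(traceG@output == "none"),
        cont_null = all(predC == "none"))
    }
  }
  perTrial <- DataFrame(do.call(rbind, rows))
  if (task == "force") {
    included <- which(perTrial$gated_mid > 0 & perTrial$wiener_mid > 0)
    excluded <- setdiff(seq_len(n), included)
    pt <- perTrial[included, , drop = FALSE]
    epochTargets <- function(pre, mid, post)
      .rsq(c(rep(0, nrow(pt)), pt$target, rep(0, nrow(pt))),
           c(pre, mid, post))
    agg <- list(
      gated_r2 = epochTargets(pt$gated_pre, pt$gated_mid, pt$gated_post),
      wiener_r2 = epochTargets(pt$wiener_pre, pt$wiener_mid, pt$wiener_post),
      gated_range_median = stats::median(pt$gated_range[!pt$gated_flagged]),
      wiener_range_median = stats::median(pt$wiener_range[!pt$wiener_flagged]),
      latch_ok = all(perTrial$latch_ok))
  } else {
    included <- which(perTrial$gated_class != "none" &
                        perTrial$cont_class != "none")
    excluded <- setdiff(seq_len(n), included)
    pt <- perTrial[included, , drop = FALSE]
    agg <- list(
      gated_trial_accuracy = mean(pt$gated_class == pt$condition),
      cont_trial_accuracy = mean(pt$cont_class == pt$condition),
      gated_timepoint_accuracy = mean(perTrial$gated_accuracy),
      cont_timepoint_accuracy = mean(perTrial$cont_accuracy),
      gated_duration_ratio_median = stats::median(pt$gated_duration_ratio),
      cont_duration_ratio_median = stats::median(pt$cont_duration_ratio))
  }
  new("EvalReport", perTrial = perTrial, aggregates = agg, task = task,
      nFolds = n, excludedTrials = as.numeric(ev$trial_id[excluded]))
}
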