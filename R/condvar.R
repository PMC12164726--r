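#' Condition-dependent variance over time
#'
#' For each aligned bin, computes the mean latent state of every condition
#' and returns the variance across those condition means: `V(t) = (1/C) *
#' sum_c ||m_c(t) - mbar(t)||^2`, the trace of the across-condition
#' covariance with denominator C (population form; `denom = "sample"`
#' switches to C - 1). V is zero when all condition means coincide and is
#' invariant to orthonormal rotations of the latent space.
#'
#' @param perTrial time x factors x trials array of aligned latent
#'   segments (from [alignAndAverage()]).
#' @param conditions per-trial condition labels.
#' @param times aligned sample times, seconds.
#' @param alignment `"onset"` or `"offset"`.
#' @param denom `"population"` (C) or `"sample"` (C - 1).
#' @return a [VarianceTrace]
#' @export
conditionVarianceTrace <- function(perTrial, conditions, times,
                                   alignment = c("onset", "offset"),
                                   denom = c("population", "sample")) {
  alignment <- match.arg(alignment)
  denom <- match.arg(denom)
  conditions <- as.character(conditions)
  tab <- table(conditions)
  if (length(tab) < 2) stop("need at least 2 conditions")
  if (any(tab < 1)) stop("condition with zero trials: ",
                         paste(names(tab)[tab < 1], collapse = ", "))
  C <- length(tab)
  nt <- dim(perTrial)[1]
  k <- dim(perTrial)[2]
  means <- array(0, c(nt, k, C))
  for (j in seq_len(C))
    means[, , j] <- apply(perTrial[, , conditions == names(tab)[j],
                                   drop = FALSE], c(1, 2), mean)
  grand <- apply(means, c(1, 2), mean)
  dev <- sweep(means, c(1, 2), grand)
  V <- apply(dev^2, 1, sum) / if (denom == "population") C else C - 1
  new("VarianceTrace", times = times, V = V, alignment = alignment,
      nConditions = C)
}

#' Summarize information decay between t1 and t2
#'
#' Averages the condition-dependent variance in two 100 ms windows: t1
#' centered 200 ms after the onset-transient peak (onset-aligned trace) and
#' t2 centered 200 ms before the offset-transient peak (offset-aligned
#' trace), and reports their ratio together with the transient-to-variance
#' lag.
#'
#' @param traceOn,traceOff onset- and offset-aligned [VarianceTrace]s.
#' @param transients a [TransientModel] providing the peak times and the
#'   onset template for the lag estimate.
#' @param maxLag maximum lag scanned by [transientVarianceLag()], seconds.
#' @return list with `Vt1`, `Vt2`, `ratio`, `t1Center`, `t2Center`,
#'   `lag` (seconds).
#' @export
summarizeT1T2 <- function(traceOn, traceOff, transients, maxLag = 1.0) {
  t1c <- transients@peakTimeOn + 0.2
  t2c <- transients@peakTimeOff - 0.2
  w1 <- traceOn@times >= t1c - 0.05 & traceOn@times <= t1c + 0.05
  w2 <- traceOff@times >= t2c - 0.05 & traceOff@times <= t2c + 0.05
  if (!any(w1) || !any(w2))
    stop("t1/t2 windows fall outside the variance traces")
  Vt1 <- mean(traceOn@V[w1])
  Vt2 <- mean(traceOff@V[w2])
  lag <- transientVarianceLag(transients@templateOn,
                              transients@templateTimesOn, traceOn, maxLag)
  list(Vt1 = Vt1, Vt2 = Vt2, ratio = Vt2 / Vt1,
       t1Center = t1c, t2Center = t2c, lag = lag$lag,
       lagCorrelations = lag$correlations)
}

#' Lag between the onset transient and the condition-variance trace
#'
#' Scans every integer-bin lag in `[-maxLag, maxLag]`, computing the
#' Pearson correlation between the onset-transient template and the
#' variance trace over their overlapping support only (no zero padding,
#' which would bias the lag toward 0), and returns the lag maximizing the
#' correlation. Ties are broken toward the smallest absolute lag.
#'
#' @param template transient template time course.
#' @param templateTimes its sample times.
#' @param trace a [VarianceTrace] on the same bin grid.
#' @param maxLag scan range, seconds (default 1).
#' @return list with `lag` (seconds, positive when the variance trails the
#'   transient) and the per-lag `correlations`.
#' @export
transientVarianceLag <- function(template, templateTimes, trace,
                                 maxLag = 1.0) {
  if (stats::sd(trace@V) == 0) stop("variance trace has zero variance")
  if (stats::sd(template) == 0) stop("template has zero variance")
  dt <- diff(templateTimes[1:2])
  # align the two series on a common index grid
  off <- round((trace@times[1] - templateTimes[1]) / dt)
  nT <- length(template); nV <- length(trace@V)
  maxL <- round(maxLag / dt)
  lags <- -maxL:maxL
  cors <- vapply(lags, function(L) {
    # trace delayed by L bins: template index i pairs with trace index
    # i - off + L
    i1 <- max(1, 1 + off - L); i2 <- min(nT, nV + off - L)
    if (i2 - i1 < 10) return(NA_real_)
    idx <- i1:i2
    suppressWarnings(stats::cor(template[idx], trace@V[idx - off + L]))
  }, numeric(1))
  best <- which(cors >= max(cors, na.rm = TRUE) - 1e-12)
  best <- best[which.min(abs(lags[best]))]
  list(lag = lags[best] * dt, correlations = stats::setNames(cors, lags * dt))
}
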