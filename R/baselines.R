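#' Fit a Wiener cascade force decoder
#'
#' The standard continuous baseline for force decoding: an ordinary
#' least-squares linear stage from the tapped latent history (current bin
#' plus `nTaps - 1` preceding bins) to the target force, followed by a
#' static 3rd-order polynomial stage fit by least squares from the linear
#' stage's output to the target. Rank deficiency in either stage falls back
#' to a small ridge (lambda = 1e-6 x trace of the Gram matrix) and is
#' flagged.
#'
#' @param traj a [LatentTrajectory]
#' @param target per-bin target force (0 outside grasp, cued force inside).
#' @param nTaps number of history bins (default 10, i.e. 200 ms).
#' @return a [WienerCascade]
#' @export
fitWienerCascade <- function(traj, target, nTaps = 10) {
  z <- traj@z
  if (length(target) != nrow(z)) stop("target must be defined for every bin")
  X <- .tappedDesign(z, nTaps)
  Xi <- cbind(1, X)
  qrX <- qr(Xi)
  ridged <- FALSE
  if (qrX$rank < ncol(Xi)) {
    ridged <- TRUE
    G <- crossprod(Xi)
    beta <- solve(G + diag(1e-6 * sum(diag(G)), ncol(Xi)), crossprod(Xi, target))
    beta <- as.numeric(beta)
  } else beta <- as.numeric(qr.coef(qrX, target))
  yhat <- as.numeric(Xi %*% beta)
  r2lin <- .rsq(target, yhat)
  P <- cbind(1, yhat, yhat^2, yhat^3)
  qrP <- qr(P)
  if (qrP$rank < 4) {
    # degenerate linear stage (e.g. constant target): constant polynomial
    pc <- c(mean(target), 0, 0, 0)
  } else pc <- as.numeric(qr.coef(qrP, target))
  comp <- as.numeric(P %*% pc)
  new("WienerCascade", linearWeights = beta, nTaps = nTaps, polyCoeffs = pc,
      r2Linear = r2lin, r2Composite = .rsq(target, comp), ridged = ridged)
}

.tappedDesign <- function(z, nTaps) {
  n <- nrow(z)
  do.call(cbind, lapply(0:(nTaps - 1), function(l) {
    if (l == 0) z else rbind(matrix(0, l, ncol(z)), z[1:(n - l), , drop = FALSE])
  }))
}

#' Predict force from a Wiener cascade
#'
#' @param cascade a [WienerCascade]
#' @param traj a [LatentTrajectory]
#' @return per-bin force predictions
#' @export
predictWienerCascade <- function(cascade, traj) {
  Xi <- cbind(1, .tappedDesign(traj@z, cascade@nTaps))
  y <- as.numeric(Xi %*% cascade@linearWeights)
  as.numeric(cbind(1, y, y^2, y^3) %*% cascade@polyCoeffs)
}

#' Fit the continuous per-bin classifier baseline
#'
#' Multiclass linear discriminant over latents with an explicit null
#' class, the standard continuous baseline for finger classification.
#' Prediction is the stateless per-bin maximum-posterior label.
#'
#' @param traj a [LatentTrajectory]
#' @param labels per-bin labels including the null class `"none"`.
#' @return a [ContinuousClassifier]
#' @export
fitContinuousClassifier <- function(traj, labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two classes")
  if (any(tab < 2)) stop("class with fewer than 2 bins: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  fit <- MASS::lda(traj@z, grouping = factor(labels))
  new("ContinuousClassifier", fit = fit, classes = names(tab))
}

#' Per-bin predictions of the continuous classifier
#'
#' @param clf a [ContinuousClassifier]
#' @param traj a [LatentTrajectory]
#' @return character vector of per-bin labels
#' @export
predictContinuousClassifier <- function(clf, traj) {
  as.character(stats::predict(clf@fit, traj@z)$class)
}

#' Per-bin cued label stream from trial events
#'
#' The cued condition during `[onset, offset)` of each trial and `"none"`
#' elsewhere; the supervision signal for the continuous classifier and the
#' reference for timepoint accuracy.
#'
#' @param events trial event table.
#' @param times bin times, seconds.
#' @return character vector of per-bin labels
#' @export
cuedLabelStream <- function(events, times) {
  lab <- rep("none", length(times))
  for (i in seq_len(nrow(events)))
    lab[times >= events$onset_time[i] & times < events$offset_time[i]] <-
      as.character(events$condition[i])
  lab
}

#' Per-bin cued force stream from trial events
#'
#' Piecewise-constant target: the cued force during `[onset, offset)` and 0
#' elsewhere.
#'
#' @param events trial event table with a `force` column.
#' @param times bin times, seconds.
#' @return numeric vector
#' @export
cuedForceStream <- function(events, times) {
  f <- rep(0, length(times))
  for (i in seq_len(nrow(events)))
    f[times >= events$onset_time[i] & times < events$offset_time[i]] <-
      events$force[i]
  f
}
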