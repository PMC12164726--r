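#' Alignment windows
#'
#' @param onset window in seconds relative to action onset.
#' @param offset window in seconds relative to action offset.
#' @return an [AlignmentWindows]
#' @export
alignmentWindows <- function(onset = c(-1.5, 2.0), offset = c(-2.0, 1.5)) {
  new("AlignmentWindows", onsetWindow = onset, offsetWindow = offset)
}

#' Align latent trajectories to trial events and average
#'
#' Snaps each trial's onset and offset times to the nearest bin, extracts
#' the latent segments over the alignment windows, and averages across all
#' retained trials with conditions pooled (the transients are
#' condition-invariant by hypothesis). Trials whose windows do not fit
#' inside the recording are dropped and counted.
#'
#' @param traj a [LatentTrajectory]
#' @param events trial event table (`DataFrame` or data.frame with
#'   `onset_time`, `offset_time`)
#' @param windows an [AlignmentWindows]
#' @return list with `avgOn`, `avgOff` (time x factors matrices carrying a
#'   `times` attribute), `perTrialOn`, `perTrialOff` (time x factors x
#'   trial arrays), `conditions` (labels of retained trials), and
#'   `dropped` (count).
#' @export
alignAndAverage <- function(traj, events, windows = alignmentWindows()) {
  z <- traj@z
  dt <- traj@binWidth
  nb <- nrow(z)
  one <- function(eventTimes, win) {
    rel <- seq(round(win[1] / dt), round(win[2] / dt))
    evBin <- round(eventTimes / dt) + 1L
    ok <- evBin + rel[1] >= 1L & evBin + rel[length(rel)] <= nb
    idx <- which(ok)
    if (!length(idx)) stop("no trial fits inside the recording")
    arr <- vapply(idx, function(i) z[evBin[i] + rel, , drop = FALSE],
                  matrix(0, length(rel), ncol(z)))
    avg <- apply(arr, c(1, 2), mean)
    attr(avg, "times") <- rel * dt
    list(avg = avg, arr = arr, ok = ok)
  }
  on <- one(events$onset_time, windows@onsetWindow)
  off <- one(events$offset_time, windows@offsetWindow)
  keep <- on$ok & off$ok
  list(avgOn = on$avg, avgOff = off$avg,
       perTrialOn = on$arr[, , keep[on$ok], drop = FALSE],
       perTrialOff = off$arr[, , keep[off$ok], drop = FALSE],
       timesOn = attr(on$avg, "times"), timesOff = attr(off$avg, "times"),
       conditions = as.character(events$condition)[keep],
       dropped = sum(!keep))
}

#' Onset-/offset-unique variance subspaces
#'
#' Splits the latent space into subspaces carrying onset-unique,
#' offset-unique, and shared variance of the trial-averaged responses.
#' Directions are the eigenvectors of the difference matrix
#' `C_on - C_off`, where `C_on`, `C_off` are the temporal covariances of
#' the (time-centered) averages; being eigenvectors of a symmetric matrix
#' they are orthonormal and the onset/offset bases are mutually orthogonal
#' by construction. A direction is onset-unique when its onset-excess
#' variance (its difference-matrix eigenvalue) is at least `varThreshold`
#' of the largest onset excess, offset-unique symmetrically for negative
#' eigenvalues, and shared otherwise. The relative-excess criterion is
#' robust to the unavoidable bleed of the opposite event into each
#' alignment window (with variable hold durations the opposite event is
#' smeared in the average but not absent). Directions carrying (almost) no
#' response variance -- less than `varFloor` of the largest total -- are
#' always shared, as is everything when the two averages coincide.
#'
#' @param avgOn,avgOff time x factors average responses.
#' @param varThreshold relative excess-variance threshold (default 0.1).
#' @param ridge ridge size; default `1e-6 * trace / k`.
#' @param varFloor relative variance floor below which a direction cannot
#'   be classified as unique.
#' @return list with orthonormal bases `sOn`, `sOff`, `sShared` (factors x
#'   dims matrices, possibly zero-column), the per-direction onset share
#'   `ratios`, and the difference eigenvalues `excess`.
#' @export
uniqueVarianceSubspaces <- function(avgOn, avgOff, varThreshold = 0.1,
                                    ridge = NULL, varFloor = 1e-3) {
  stopifnot(all(is.finite(avgOn)), all(is.finite(avgOff)))
  k <- ncol(avgOn)
  con <- scale(avgOn, center = TRUE, scale = FALSE)
  cof <- scale(avgOff, center = TRUE, scale = FALSE)
  Con <- crossprod(con) / nrow(con)
  Cof <- crossprod(cof) / nrow(cof)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(Con + Cof)) / k
  e <- eigen(Con - Cof, symmetric = TRUE)
  V <- e$vectors
  lam <- e$values
  vOn <- colSums(V * (Con %*% V))
  vOff <- colSums(V * (Cof %*% V))
  tot <- vOn + vOff
  ratio <- vOn / (tot + ridge)
  keep <- tot >= varFloor * max(tot, ridge)
  # identical averages (or pure noise): no unique variance anywhere
  unique_ok <- abs(lam) >= varFloor * max(tot, ridge)
  ion <- which(keep & unique_ok & lam > 0 & lam >= varThreshold * max(lam, 0))
  ioff <- which(keep & unique_ok & lam < 0 & -lam >= varThreshold * max(-lam, 0))
  ish <- setdiff(seq_len(k), c(ion, ioff))
  list(sOn = V[, ion, drop = FALSE],
       sOff = V[, rev(ioff), drop = FALSE],
       sShared = V[, ish, drop = FALSE],
       ratios = ratio, excess = lam)
}

#' Varimax rotation for temporally sparse components
#'
#' Rotates the within-subspace time courses of an average latent response
#' with an orthogonal varimax rotation (no column normalization, since the
#' columns are latent time courses with meaningful scale), identifying
#' projections with temporally sparse, bump-like responses. Total variance
#' of the time courses is preserved.
#'
#' @param avgResponse time x factors average latent response.
#' @param subspace factors x k orthonormal basis to rotate within.
#' @param maxSweeps maximum varimax iterations.
#' @return list with `directions` (factors x k, the rotated basis),
#'   `timecourses` (time x k), `rotation` (k x k orthogonal), and
#'   `converged`.
#' @export
varimaxSparseComponents <- function(avgResponse, subspace, maxSweeps = 1000) {
  k <- ncol(subspace)
  if (k < 1) stop("subspace must contain at least one direction")
  tc <- avgResponse %*% subspace
  if (k == 1)
    return(list(directions = subspace, timecourses = tc,
                rotation = matrix(1, 1, 1), converged = TRUE))
  # the identity start can be a stationary point of the criterion (e.g. an
  # exact 45-degree mixture); restart from a fixed set of rotations and
  # keep the best, so the solution is deterministic and start-independent
  starts <- c(list(diag(k)), lapply(1:4, function(i)
    qr.Q(qr(matrix(sin(seq_len(k * k) * 997 * i + i), k, k)))))
  best <- NULL; bestCrit <- -Inf
  for (R0 in starts) {
    vr <- stats::varimax(tc %*% R0, normalize = FALSE, eps = 1e-10)
    R <- R0 %*% vr$rotmat
    crit <- sum(apply((tc %*% R)^2, 2, stats::var))
    if (crit > bestCrit) { bestCrit <- crit; best <- R }
  }
  R <- best
  converged <- max(abs(crossprod(R) - diag(k))) < 1e-8
  list(directions = subspace %*% R, timecourses = tc %*% R,
       rotation = R, converged = converged)
}

# Varimax criterion: sum over columns of the variance of squared entries.
.varimaxCriterion <- function(A) sum(apply(A^2, 2, stats::var))

#' Select the transient component with the largest modulation
#'
#' Scores each candidate component by its peak absolute deviation from the
#' baseline mean within the modulation window, returns the winner
#' sign-flipped so its peak is positive, and records peak time, amplitude,
#' and FWHM. Two widths are reported: the raw FWHM measured on the (already
#' smoothed) time course by linear interpolation at half maximum, and a
#' corrected FWHM that inverts the broadening of the causal exponential
#' smoothing filter (decay constant `tau`), recovering the intrinsic width
#' of the underlying transient.
#'
#' @param timecourses time x k candidate time courses.
#' @param times sample times, seconds relative to the aligning event.
#' @param directions factors x k unit directions matching the columns.
#' @param window modulation window, seconds (default: whole time course).
#' @param baselineWindow baseline window, seconds (default: first 0.5 s of
#'   the time course).
#' @param tau smoothing decay constant used for the width correction;
#'   `0` disables the correction.
#' @return list with `w` (unit direction), `template`
#'   (baseline-subtracted, sign-corrected time course), `times`,
#'   `peakTime`, `peakAmplitude`, `fwhm` (corrected), `fwhmRaw`, `index`.
#' @export
selectTransient <- function(timecourses, times, directions,
                            window = range(times),
                            baselineWindow = c(times[1], times[1] + 0.5),
                            tau = 0.4) {
  timecourses <- as.matrix(timecourses)
  k <- ncol(timecourses)
  inWin <- times >= window[1] & times <= window[2]
  inBase <- times >= baselineWindow[1] & times <= baselineWindow[2]
  if (!any(inBase)) stop("empty baseline window")
  base <- colMeans(timecourses[inBase, , drop = FALSE])
  dev <- abs(sweep(timecourses[inWin, , drop = FALSE], 2, base))
  modulation <- apply(dev, 2, max)
  if (max(modulation) < 1e-10)
    stop("all candidate components are flat: no transient to select")
  peakAt <- times[inWin][apply(dev, 2, which.max)]
  best <- order(-modulation, peakAt)[1]     # ties -> earlier peak
  tc <- timecourses[, best] - base[best]
  sgn <- sign(tc[which(inWin)[which.max(dev[, best])]])
  if (sgn == 0) sgn <- 1
  tc <- sgn * tc
  pk <- which.max(tc)
  fwhmRaw <- .measureFWHM(tc, times, baseline = 0)
  list(w = .unit(sgn * directions[, best]), template = tc, times = times,
       peakTime = times[pk], peakAmplitude = tc[pk],
       fwhm = .correctFWHM(fwhmRaw, tau), fwhmRaw = fwhmRaw, index = best)
}

#' Identify onset and offset transient components
#'
#' Full transient-identification chain: align latent responses to action
#' onset and offset and average across trials (conditions pooled), split
#' the latent space into onset-/offset-unique subspaces, varimax-rotate the
#' average response within each unique subspace to expose temporally sparse
#' components, and select the single component with the largest modulation
#' on each side. The onset and offset components are orthogonal by
#' construction of the subspace decomposition.
#'
#' @param traj a [LatentTrajectory]
#' @param events trial event table
#' @param windows an [AlignmentWindows]
#' @param varThreshold subspace uniqueness threshold.
#' @param tau smoothing decay constant used for FWHM correction (taken from
#'   preprocessing provenance when available).
#' @return a [TransientModel]
#' @export
findTransients <- function(traj, events, windows = alignmentWindows(),
                           varThreshold = 0.1, tau = 0.4) {
  al <- alignAndAverage(traj, events, windows)
  sub <- uniqueVarianceSubspaces(al$avgOn, al$avgOff, varThreshold)
  if (ncol(sub$sOn) == 0 || ncol(sub$sOff) == 0)
    stop("subspace decomposition found no onset- or offset-unique directions")
  von <- varimaxSparseComponents(al$avgOn, sub$sOn)
  voff <- varimaxSparseComponents(al$avgOff, sub$sOff)
  selOn <- selectTransient(von$timecourses, al$timesOn, von$directions,
                           tau = tau)
  selOff <- selectTransient(voff$timecourses, al$timesOff, voff$directions,
                            tau = tau)
  new("TransientModel",
      wOn = selOn$w, wOff = selOff$w,
      templateOn = selOn$template, templateOff = selOff$template,
      templateTimesOn = al$timesOn, templateTimesOff = al$timesOff,
      peakTimeOn = selOn$peakTime, peakTimeOff = selOff$peakTime,
      peakAmplitudeOn = selOn$peakAmplitude,
      peakAmplitudeOff = selOff$peakAmplitude,
      fwhmOn = selOn$fwhm, fwhmOff = selOff$fwhm,
      fwhmRawOn = selOn$fwhmRaw, fwhmRawOff = selOff$fwhmRaw,
      droppedTrials = al$dropped)
}
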