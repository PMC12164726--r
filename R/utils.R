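# Internal numerical helpers shared across modules.

# Truncated, unit-sum causal exponential kernel h[k] = exp(-k*dt/tau),
# k = 0 .. truncation*tau/dt.
.expKernel <- function(tau, dt, truncation = 5) {
  stopifnot(tau > 0, dt > 0, truncation > 0)
  k <- 0:ceiling(truncation * tau / dt)
  h <- exp(-k * dt / tau)
  h / sum(h)
}

# Causal convolution of the columns of `x` (bins in rows) with the
# truncated exponential kernel, computed recursively in O(n):
# S_t = a S_{t-1} + x_t - a^(K+1) x_{t-K-1}, then divided by the kernel sum.
.expSmoothCols <- function(x, tau, dt, truncation = 5) {
  x <- as.matrix(x)
  a <- exp(-dt / tau)
  K <- ceiling(truncation * tau / dt)
  n <- nrow(x)
  y <- x
  if (n > K + 1)
    y[(K + 2):n, ] <- y[(K + 2):n, , drop = FALSE] -
      a^(K + 1) * x[1:(n - K - 1), , drop = FALSE]
  s <- stats::filter(y, a, method = "recursive")
  s <- matrix(as.numeric(s), nrow = n)
  s / sum(a^(0:K))
}

# FWHM of a unimodal curve by linear interpolation at half maximum,
# measured above the curve minimum unless a baseline is supplied.
.measureFWHM <- function(y, x, baseline = NULL) {
  if (is.null(baseline)) baseline <- min(y)
  y <- y - baseline
  i <- which.max(y)
  hm <- y[i] / 2
  left <- which(y[seq_len(i)] <= hm)
  right <- which(y[i:length(y)] <= hm)
  if (!length(left) || !length(right)) return(NA_real_)
  li <- max(left)
  ri <- i - 1L + min(right)
  xl <- x[li] + (x[li + 1] - x[li]) * (hm - y[li]) / (y[li + 1] - y[li])
  xr <- x[ri - 1] + (x[ri] - x[ri - 1]) * (hm - y[ri - 1]) / (y[ri] - y[ri - 1])
  xr - xl
}

# FWHM of a Gaussian of width sigma after causal exponential smoothing
# (decay constant tau), evaluated numerically on a fine grid.
.smoothedGaussianFWHM <- function(sigma, tau, dt = 0.004) {
  tt <- seq(-6 * sigma - tau, 6 * sigma + 8 * tau, by = dt)
  g <- exp(-tt^2 / (2 * sigma^2))
  sm <- .expSmoothCols(matrix(g, ncol = 1), tau, dt)[, 1]
  .measureFWHM(sm, tt, baseline = 0)
}

# Invert the smoothing-broadening relation: given a FWHM measured on the
# exponentially smoothed time course, return the intrinsic FWHM of the
# underlying Gaussian transient. Monotone in sigma, solved by uniroot.
.correctFWHM <- function(fwhmMeasured, tau, dt = 0.004) {
  if (is.na(fwhmMeasured)) return(NA_real_)
  if (tau <= 0) return(fwhmMeasured)
  floorWidth <- .smoothedGaussianFWHM(1e-3, tau, dt)
  if (fwhmMeasured <= floorWidth) return(0)
  f <- function(s) .smoothedGaussianFWHM(s, tau, dt) - fwhmMeasured
  sig <- stats::uniroot(f, lower = 1e-3, upper = max(2, fwhmMeasured),
                        tol = 1e-5)$root
  2 * sqrt(2 * log(2)) * sig
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# random-number state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Orthonormalize the columns of V by symmetric (Loewdin) orthogonalization,
# which perturbs each column minimally and keeps block identities.
.loewdin <- function(V) {
  if (ncol(V) == 0L) return(V)
  e <- eigen(crossprod(V), symmetric = TRUE)
  if (min(e$values) < 1e-12) stop("rank-deficient basis in orthogonalization")
  V %*% (e$vectors %*% (t(e$vectors) / sqrt(e$values)))
}

.unit <- function(v) v / sqrt(sum(v^2))

# R-squared of predictions against observations.
.rsq <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}
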