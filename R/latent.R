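#' Fit the latent factor model
#'
#' Maximum-likelihood factor analysis of smoothed firing rates by
#' expectation--maximization, operating on the sample covariance of all
#' within-session bins. Initialization is deterministic (principal
#' components), the log-likelihood is asserted non-decreasing at every
#' iteration, and non-convergence within `maxIter` is reported through the
#' `converged` flag rather than an error. The orthonormal latent basis is
#' the set of left singular vectors of the fitted loading matrix.
#'
#' Constant channels carry no information for the shared-variance model and
#' are dropped with a warning; their loadings and basis rows are zero.
#'
#' @param x a [SpikeSession] with a `"rates"` assay, or a channels x bins
#'   rate matrix.
#' @param nFactors number of factors (default 20).
#' @param maxIter maximum EM iterations.
#' @param tol relative log-likelihood change declaring convergence.
#' @return a [LatentModel]
#' @export
setGeneric("fitFactorModel", function(x, nFactors = 20, maxIter = 500,
                                      tol = 1e-8) standardGeneric("fitFactorModel"))

#' @rdname fitFactorModel
#' @export
setMethod("fitFactorModel", "SpikeSession", function(x, nFactors, maxIter, tol) {
  fitFactorModel(firingRates(x), nFactors, maxIter, tol)
})

#' @rdname fitFactorModel
#' @export
setMethod("fitFactorModel", "matrix", function(x, nFactors, maxIter, tol) {
  p <- nrow(x); nb <- ncol(x)
  if (nb <= nFactors)
    stop("need more time bins than factors")
  mu <- rowMeans(x)
  xc <- x - mu
  vars <- rowSums(xc^2) / nb
  keep <- which(vars > 1e-12)
  if (length(keep) < p)
    warning(sprintf("dropping %d constant channel(s) from the factor fit",
                    p - length(keep)))
  if (length(keep) <= nFactors)
    stop("fewer varying channels than factors")
  S <- tcrossprod(xc[keep, , drop = FALSE]) / nb

  fit <- .faEM(S, nFactors, maxIter, tol)

  loadings <- matrix(0, p, nFactors)
  loadings[keep, ] <- fit$W
  psi <- rep(1e-12, p)
  psi[keep] <- fit$psi
  sv <- svd(loadings, nu = nFactors, nv = 0)
  new("LatentModel", loadings = loadings, channelMeans = mu,
      noiseVariances = psi, basis = sv$u, nFactors = nFactors,
      converged = fit$converged, logLik = fit$logLik,
      keptChannels = as.integer(keep), scoring = "projection")
})

# EM for the factor model x ~ N(0, W W' + Psi) from the sample covariance.
# All expectations reduce to functions of S, so iterations are O(p^2 k).
.faEM <- function(S, k, maxIter, tol) {
  p <- nrow(S)
  dS <- diag(S)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 1e-12)
  tailVar <- mean(ev[(k + 1):p])
  psiFloor <- pmax(1e-6 * dS, 1e-12)   # uniqueness floor, relative per channel
  W <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev[seq_len(k)] - tailVar, 1e-8)), k)
  psi <- pmax(dS - rowSums(W^2), psiFloor)

  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    Wp <- W / psi                       # Psi^-1 W
    G <- solve(diag(k) + crossprod(W, Wp))     # (I + W'Psi^-1 W)^-1
    beta <- tcrossprod(G, Wp)           # k x p, = G W' Psi^-1
    SB <- S %*% t(beta)                 # p x k
    Ezz <- G + beta %*% SB              # k x k
    Wnew <- SB %*% solve(Ezz)
    psiNew <- pmax(dS - rowSums(Wnew * SB), psiFloor)

    # log-likelihood per observation of the *current* (pre-update) model:
    # log|Sigma| and tr(Sigma^-1 S) via the Woodbury identity
    logdet <- sum(log(psi)) - determinant(G, logarithm = TRUE)$modulus[1]
    Sinv_S_tr <- sum(dS / psi) - sum(beta * t(S %*% Wp))
    llNow <- -0.5 * (p * log(2 * pi) + logdet + Sinv_S_tr)
    if (it > 1 && llNow < ll[it - 1]) {
      # EM is monotone in exact arithmetic; a drop here is finite-precision
      # stall near the optimum (fail loudly if it is anything bigger)
      if (ll[it - 1] - llNow > 1e-4 * (abs(ll[it - 1]) + 1))
        stop("EM log-likelihood decreased; numerical failure")
      W <- Wprev; psi <- psiPrev
      converged <- TRUE
      break
    }
    ll <- c(ll, llNow)
    Wprev <- W; psiPrev <- psi
    W <- Wnew; psi <- psiNew
    if (it > 1 && abs(ll[it] - ll[it - 1]) <
        tol * (abs(ll[it - 1]) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  list(W = W, psi = psi, logLik = ll, converged = converged)
}

#' Project rates into the orthonormal latent space
#'
#' Latent trajectories are `z(t) = B' (r(t) - mu)` with `B` the orthonormal
#' basis of the model; `B z` reconstructs the rank-`nFactors` component of
#' the centered rates, so projection followed by reconstruction is
#' idempotent. Posterior-mean factor scoring (expressed in the same
#' orthonormal coordinates) is available via `scoring = "posterior"`.
#'
#' @param x a [SpikeSession] with rates, or a channels x bins rate matrix.
#' @param model a [LatentModel]; channel count must match.
#' @param scoring `"projection"` (default) or `"posterior"`.
#' @return a [LatentTrajectory]
#' @export
setGeneric("projectLatents", function(x, model, scoring = c("projection", "posterior"))
  standardGeneric("projectLatents"))

#' @rdname projectLatents
#' @export
setMethod("projectLatents", "SpikeSession", function(x, model, scoring) {
  tr <- projectLatents(firingRates(x), model, scoring)
  tr@binWidth <- binWidth(x)
  tr@times <- binTimes(x)
  tr
})

#' @rdname projectLatents
#' @export
setMethod("projectLatents", "matrix", function(x, model, scoring) {
  scoring <- match.arg(scoring)
  if (nrow(x) != nrow(model@basis))
    stop(sprintf("channel mismatch: data has %d channels, model %d",
                 nrow(x), nrow(model@basis)))
  xc <- x - model@channelMeans
  z <- if (scoring == "projection") {
    crossprod(model@basis, xc)
  } else {
    W <- model@loadings; psi <- model@noiseVariances
    Wp <- W / psi
    G <- solve(diag(model@nFactors) + crossprod(W, Wp))
    zf <- tcrossprod(G, Wp) %*% xc          # posterior factor means
    sv <- svd(W, nu = 0)
    (diag(sv$d, model@nFactors) %*% t(sv$v)) %*% zf  # to basis coordinates
  }
  new("LatentTrajectory", z = t(z), binWidth = 0.02,
      times = (seq_len(ncol(x)) - 1) * 0.02)
})

#' Reconstruct rates from a latent trajectory
#'
#' Returns `mu + B z`, the rank-limited reconstruction of the centered
#' rates.
#'
#' @param traj a [LatentTrajectory]
#' @param model the [LatentModel] used to produce it
#' @return channels x bins matrix
#' @export
reconstructRates <- function(traj, model) {
  model@channelMeans + model@basis %*% t(traj@z)
}
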