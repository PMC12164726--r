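#' Smoothed firing-rate estimates from binned counts
#'
#' Converts binned threshold-crossing counts into smoothed firing-rate
#' estimates: counts are square-root transformed and convolved with a
#' causal decaying-exponential filter (decay constant `tau`, default
#' 400 ms), truncated at `truncation * tau` and renormalized to unit sum.
#' The output at bin t depends only on bins <= t, and a constant count c
#' converges to sqrt(c) (unit DC gain).
#'
#' @param x a [SpikeSession] (the `"rates"` assay is added and the
#'   parameters recorded in `metadata(x)$preprocess`), or a channels x bins
#'   count matrix.
#' @param tau exponential decay constant, seconds.
#' @param sqrtTransform apply the square-root variance-stabilizing
#'   transform before smoothing (default TRUE).
#' @param truncation kernel truncation, in multiples of `tau`.
#' @return the same class as `x`, with smoothed rates.
#' @examples
#' cts <- matrix(rpois(200, 2), nrow = 4)
#' r <- smoothCounts(cts, tau = 0.4)
#' @export
setGeneric("smoothCounts", function(x, tau = 0.4, sqrtTransform = TRUE,
                                    truncation = 5) standardGeneric("smoothCounts"))

#' @rdname smoothCounts
#' @export
setMethod("smoothCounts", "matrix", function(x, tau, sqrtTransform, truncation) {
  .smoothCountMatrix(x, binWidth = attr(x, "binWidth") %||% 0.02,
                     tau = tau, sqrtTransform = sqrtTransform,
                     truncation = truncation)
})

#' @rdname smoothCounts
#' @export
setMethod("smoothCounts", "SpikeSession", function(x, tau, sqrtTransform,
                                                   truncation) {
  r <- .smoothCountMatrix(assay(x, "counts"), binWidth = binWidth(x),
                          tau = tau, sqrtTransform = sqrtTransform,
                          truncation = truncation)
  assay(x, "rates", withDimnames = FALSE) <- r
  metadata(x)$preprocess <- list(tau = tau, sqrtTransform = sqrtTransform,
                                 truncation = truncation)
  x
})

`%||%` <- function(a, b) if (is.null(a)) b else a

.smoothCountMatrix <- function(counts, binWidth, tau, sqrtTransform,
                               truncation) {
  if (any(counts < 0)) stop("counts must be nonnegative integers")
  if (tau <= 0) stop("tau must be > 0")
  v <- if (sqrtTransform) sqrt(counts) else counts
  out <- t(.expSmoothCols(t(v), tau = tau, dt = binWidth,
                          truncation = truncation))
  dimnames(out) <- dimnames(counts)
  out
}
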