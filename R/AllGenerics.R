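#' @rdname SpikeSession-class
#' @param object,x a `SpikeSession`
#' @export
setGeneric("trialEvents", function(x) standardGeneric("trialEvents"))

#' @rdname SpikeSession-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname SpikeSession-class
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname SpikeSession-class
#' @export
setGeneric("firingRates", function(x) standardGeneric("firingRates"))

#' @rdname SpikeSession-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SpikeSession-class
#' @export
setGeneric("binTimes", function(x) standardGeneric("binTimes"))

setMethod("trialEvents", "SpikeSession", function(x) x@trialEvents)
setMethod("binWidth", "SpikeSession", function(x) x@binWidth)
setMethod("binWidth", "LatentTrajectory", function(x) x@binWidth)
setMethod("spikeCounts", "SpikeSession", function(x) assay(x, "counts"))
setMethod("firingRates", "SpikeSession", function(x) {
  if (!"rates" %in% assayNames(x))
    stop("no 'rates' assay: run smoothCounts() first")
  assay(x, "rates")
})
setMethod("groundTruth", "SpikeSession", function(x) metadata(x)$groundTruth)
setMethod("binTimes", "SpikeSession",
          function(x) (seq_len(ncol(x)) - 1L) * x@binWidth)

#' Latent state matrix of a trajectory
#' @param x a `LatentTrajectory`
#' @return bins x factors numeric matrix
#' @export
setGeneric("latentState", function(x) standardGeneric("latentState"))
setMethod("latentState", "LatentTrajectory", function(x) x@z)

setMethod("show", "SpikeSession", function(object) {
  cat("SpikeSession:", nrow(object), "channels x", ncol(object), "bins",
      sprintf("(%.0f Hz, %.1f s)\n", 1 / object@binWidth,
              ncol(object) * object@binWidth))
  ev <- object@trialEvents
  if (nrow(ev)) {
    cat(" ", nrow(ev), "trials |", ev$task[1], "|",
        length(unique(ev$condition)), "conditions\n")
  }
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (!is.null(metadata(object)$groundTruth))
    cat("  ground truth available (simulated session)\n")
})

setMethod("show", "LatentModel", function(object) {
  cat("LatentModel:", nrow(object@loadings), "channels,", object@nFactors,
      "factors\n  EM", if (object@converged) "converged" else "NOT converged",
      "after", length(object@logLik), "iterations; logLik",
      sprintf("%.2f", utils::tail(object@logLik, 1)), "\n")
})

setMethod("show", "TransientModel", function(object) {
  cat("TransientModel\n")
  cat(sprintf("  onset : peak %+.3f s, amplitude %.3f, FWHM %.0f ms (raw %.0f ms)\n",
              object@peakTimeOn, object@peakAmplitudeOn,
              1000 * object@fwhmOn, 1000 * object@fwhmRawOn))
  cat(sprintf("  offset: peak %+.3f s, amplitude %.3f, FWHM %.0f ms (raw %.0f ms)\n",
              object@peakTimeOff, object@peakAmplitudeOff,
              1000 * object@fwhmOff, 1000 * object@fwhmRawOff))
})

setMethod("show", "DecodeTrace", function(object) {
  cat("DecodeTrace (", object@task, "): ", length(object@times), " bins, ",
      nrow(object@events), " state transitions\n", sep = "")
  print(table(factor(object@state, levels = c("idle", "deciding", "latched"))))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (", object@task, "): ", object@nFolds, " LOO folds, ",
      length(object@excludedTrials), " trials excluded\n", sep = "")
  agg <- object@aggregates
  for (nm in names(agg))
    if (is.numeric(agg[[nm]]) && length(agg[[nm]]) == 1L)
      cat(sprintf("  %-28s %.4f\n", nm, agg[[nm]]))
})
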