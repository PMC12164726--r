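#' Run the full analysis pipeline on one simulated session
#'
#' End-to-end orchestration: simulate -> preprocess -> fit the latent model
#' -> identify transients -> condition-variance summary -> leave-one-out
#' decoder comparison -> report. Fully reproducible: the report is a pure
#' function of the configuration (which carries the seed), and the
#' configuration is embedded in the report.
#'
#' @param cfg a [SimConfig] describing the session.
#' @param nFactors latent dimensionality.
#' @param gateCfg a [GateConfig]
#' @param tau smoothing decay constant, seconds.
#' @param outFile optional path; when given, the report is written there
#'   as JSON.
#' @param runCV run the leave-one-out decoder comparison (the slow stage).
#' @return the report as a named list, invisibly when `outFile` is given.
#' @export
runPipeline <- function(cfg, nFactors = 20, gateCfg = gateConfig(),
                        tau = 0.4, outFile = NULL, runCV = TRUE) {
  session <- simulateSession(cfg)
  session <- smoothCounts(session, tau = tau)
  model <- fitFactorModel(session, nFactors)
  traj <- projectLatents(session, model)
  ev <- trialEvents(session)
  trans <- findTransients(traj, ev, tau = tau)
  al <- alignAndAverage(traj, ev)
  trOn <- conditionVarianceTrace(al$perTrialOn, al$conditions, al$timesOn,
                                 "onset")
  trOff <- conditionVarianceTrace(al$perTrialOff, al$conditions, al$timesOff,
                                  "offset")
  cv <- summarizeT1T2(trOn, trOff, trans)
  task <- if (grepl("grasp", cfg@task)) "force" else "classification"
  report <- list(
    config = .configToList(cfg),
    latent = list(converged = model@converged,
                  logLik = unname(utils::tail(model@logLik, 1))),
    transients = list(
      peak_time_on = trans@peakTimeOn, peak_time_off = trans@peakTimeOff,
      peak_amplitude_on = trans@peakAmplitudeOn,
      peak_amplitude_off = trans@peakAmplitudeOff,
      fwhm_on = trans@fwhmOn, fwhm_off = trans@fwhmOff,
      fwhm_raw_on = trans@fwhmRawOn, fwhm_raw_off = trans@fwhmRawOff,
      dropped_trials = trans@droppedTrials),
    condition_variance = list(V_t1 = cv$Vt1, V_t2 = cv$Vt2,
                              ratio = cv$ratio, lag = cv$lag))
  if (runCV) {
    rep2 <- looCrossValidate(session, task, nFactors, gateCfg, tau = tau)
    report$evaluation <- c(list(task = task, n_folds = rep2@nFolds,
                                excluded_trials = rep2@excludedTrials),
                           rep2@aggregates)
  }
  if (!is.null(outFile)) {
    jsonlite::write_json(report, outFile, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}
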