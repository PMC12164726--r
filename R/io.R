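#' Session bundle persistence
#'
#' A session bundle is stored as a plain-text directory: `counts.csv`
#' (bins x channels integer table), `events.csv` (trial event table), and
#' `meta.json` (schema version, bin width, seed, and the simulation
#' config when the session was generated). `rates.csv` is written when a
#' `"rates"` assay is present. Writing then reading restores the session
#' exactly: counts bit-exact, real-valued fields to 1e-12.
#'
#' @param session a [SpikeSession]
#' @param path bundle directory (created if needed).
#' @return `writeSessionBundle` returns `path` invisibly;
#'   `readSessionBundle` returns a [SpikeSession].
#' @export
writeSessionBundle <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cts <- assay(session, "counts")
  data.table::fwrite(data.table::as.data.table(t(cts)),
                     file.path(path, "counts.csv"))
  data.table::fwrite(as.data.frame(trialEvents(session)),
                     file.path(path, "events.csv"))
  if ("rates" %in% assayNames(session))
    data.table::fwrite(data.table::as.data.table(t(assay(session, "rates"))),
                       file.path(path, "rates.csv"))
  cfg <- metadata(session)$config
  meta <- list(schema_version = 1L,
               bin_width = binWidth(session),
               n_channels = nrow(session), n_bins = ncol(session),
               seed = metadata(session)$seed,
               config = if (!is.null(cfg)) .configToList(cfg) else NULL,
               preprocess = metadata(session)$preprocess)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeSessionBundle
#' @param path bundle directory.
#' @export
readSessionBundle <- function(path) {
  need <- c("counts.csv", "events.csv", "meta.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("not a session bundle: missing ", f)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop("unsupported bundle schema version: ",
         meta$schema_version %||% "<absent>")
  cts <- t(as.matrix(data.table::fread(file.path(path, "counts.csv"))))
  storage.mode(cts) <- "integer"
  rownames(cts) <- sprintf("ch%03d", seq_len(nrow(cts)))
  evDF <- data.table::fread(file.path(path, "events.csv"))
  if ("force" %in% names(evDF)) evDF$force <- as.numeric(evDF$force)
  assays <- list(counts = cts)
  rp <- file.path(path, "rates.csv")
  if (file.exists(rp)) {
    r <- t(as.matrix(data.table::fread(rp)))
    dimnames(r) <- dimnames(cts)
    assays$rates <- r
  }
  se <- SummarizedExperiment(assays = assays)
  sess <- new("SpikeSession", se,
              trialEvents = DataFrame(as.data.frame(evDF)),
              binWidth = meta$bin_width)
  metadata(sess)$seed <- meta$seed
  if (!is.null(meta$config))
    metadata(sess)$config <- .configFromList(meta$config)
  if (!is.null(meta$preprocess)) metadata(sess)$preprocess <- meta$preprocess
  sess
}

.configToList <- function(cfg) {
  nm <- slotNames("SimConfig")
  stats::setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}

.configFromList <- function(lst) {
  known <- slotNames("SimConfig")
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  lst$nConditions <- as.integer(lst$nConditions)
  do.call(new, c(list("SimConfig"), lst))
}
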