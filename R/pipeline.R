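#' @include synth.R
NULL

#' Read a pipeline configuration file
#'
#' YAML or JSON key-value file; see \code{\link{runPipeline}} for the
#' schema.
#'
#' @param path config file path
#' @return the configuration as a named list
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  yaml::read_yaml(path)
}

.cfgFail <- function(key, why) {
  stop(sprintf("config validation failed at '%s': %s", key, why),
       call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks the schema, the preprocessing-step ordering contract
#' (crop -> background -> baseline/dff -> filter -> resample) and that
#' every referenced ROI label is defined. Errors name the offending key.
#'
#' @param config a configuration list (see \code{\link{runPipeline}})
#' @return the config, invisibly, when valid
#' @export
validatePipelineConfig <- function(config) {
  if (is.null(config$input)) .cfgFail("input", "missing")
  if (is.null(config$input$tiff)) .cfgFail("input.tiff", "missing movie path")
  if (is.null(config$input$rate) || config$input$rate <= 0)
    .cfgFail("input.rate", "must be a positive frame rate in Hz")
  if (is.null(config$rois) || length(config$rois) == 0)
    .cfgFail("rois", "at least one ROI required")
  labels <- vapply(config$rois, function(r) {
    if (is.null(r$label) || !nzchar(r$label)) .cfgFail("rois.label", "missing")
    r$label
  }, character(1))
  if (anyDuplicated(labels))
    .cfgFail("rois.label", "labels must be unique")
  for (r in config$rois) {
    if (is.null(r$kind) || !r$kind %in% c("rectangle", "ellipse", "polygon"))
      .cfgFail(sprintf("rois[%s].kind", r$label),
               "must be rectangle, ellipse or polygon")
  }
  steps <- config$steps
  if (is.null(steps) || length(steps) == 0) .cfgFail("steps", "missing")
  ops <- vapply(steps, function(s) {
    if (is.null(s$op)) .cfgFail("steps.op", "missing")
    s$op
  }, character(1))
  known <- c("crop", "baseline", "dff", "filter", "resample")
  bad <- setdiff(ops, known)
  if (length(bad))
    .cfgFail(sprintf("steps.op '%s'", bad[1]),
             paste("unknown; allowed:", paste(known, collapse = ", ")))
  ranks <- .STAGE_RANK[ops]
  if (any(diff(ranks) < 0)) {
    k <- which(diff(ranks) < 0)[1]
    .cfgFail(sprintf("steps[%d] '%s'", k + 1, ops[k + 1]),
             sprintf(paste0("ordering rule violated: '%s' must not follow ",
                            "'%s' (required order: crop -> background -> ",
                            "baseline/dff -> filter -> resample)"),
                     ops[k + 1], ops[k]))
  }
  if ("dff" %in% ops && !"baseline" %in% ops[seq_len(match("dff", ops))])
    .cfgFail("steps.dff", "requires a preceding baseline step")
  if (!is.null(config$detection) &&
      !config$detection$mode %in% c("spikes", "bursts"))
    .cfgFail("detection.mode", "must be 'spikes' or 'bursts'")
  if (!is.null(config$analyses$xcorr)) {
    kind <- config$analyses$xcorr$kind
    if (is.null(kind) || !kind %in% c("amplitude", "spike", "instantaneous"))
      .cfgFail("analyses.xcorr.kind",
               "must be amplitude, spike or instantaneous")
    if (length(labels) < 2)
      .cfgFail("analyses.xcorr", "needs at least two ROIs")
  }
  if (is.null(config$output)) .cfgFail("output", "missing output directory")
  invisible(config)
}

.roiFromConfig <- function(r) {
  switch(r$kind,
    rectangle = Roi("rectangle", label = r$label,
                    rows = unlist(r$rows), cols = unlist(r$cols)),
    ellipse = Roi("ellipse", label = r$label, center = unlist(r$center),
                  semiAxes = unlist(r$semiAxes)),
    polygon = Roi("polygon", label = r$label,
                  vertices = do.call(rbind, r$vertices)))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: movie import, optional rigid movement correction
#' (\code{movement: {reference, maxShift}}), ROI trace extraction,
#' optional perisomatic background subtraction
#' (\code{background: {width, scale}}), the configured preprocessing
#' steps, event detection, and the requested analyses; writes every
#' result as CSV plus a machine-readable run manifest
#' (\code{manifest.json}). Identical config and inputs give byte-identical
#' outputs.
#'
#' Config schema (YAML/JSON): \code{seed}; \code{input: {tiff, rate}};
#' \code{rois}: list of \code{{label, kind, ...geometry}};
#' \code{movement}, \code{background} (optional); \code{steps}: ordered
#' list of \code{{op: crop|baseline|dff|filter|resample, ...params}};
#' \code{detection: {mode: spikes|bursts, threshold: {mode, level,
#' window, k}, ...}}; \code{analyses: {spectrum: {...}, xcorr: {kind,
#' maxLag, ...}}}; \code{output}: directory.
#'
#' @param config a configuration list or the path of a YAML/JSON file
#' @param quiet suppress per-stage log messages
#' @return the manifest (named list), invisibly
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  log <- function(fmt, ...) {
    if (!quiet) message(sprintf("[optovolt %s] %s", format(Sys.time(), "%H:%M:%OS1"),
                                sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log("%s done (%.2f s)", name, proc.time()[["elapsed"]] - t0)
    out
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  outDir <- config$output
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  stack <- stage("import", readStack(config$input$tiff, config$input$rate))
  if (!is.null(config$movement)) {
    stack <- stage("movement-correction", {
      ref <- config$movement$reference %||% "first"
      ms <- config$movement$maxShift %||% 5
      applyShifts(stack, estimateShifts(stack, reference = ref, maxShift = ms))
    })
  }
  rois <- lapply(config$rois, .roiFromConfig)
  labels <- vapply(rois, function(r) r@label, character(1))
  masks <- lapply(rois, makeMask, shape = frameDim(stack))

  raws <- stage("extract-traces", {
    tr <- lapply(seq_along(rois), function(i) extractTrace(stack, rois[[i]]))
    if (!is.null(config$background)) {
      w <- config$background$width %||% 2
      sc <- config$background$scale %||% 1
      tr <- lapply(seq_along(tr), function(i) {
        ann <- perisomaticAnnulus(masks[[i]], w, frameDim(stack),
                                  exclude = masks[-i])
        bg <- extractTrace(stack, ann)
        bg@label <- paste0(labels[i], ".annulus")
        subtractBackground(tr[[i]], bg, scale = sc)
      })
    }
    tr
  })

  processed <- stage("preprocess", lapply(raws, function(tr) {
    baseline <- NULL
    cur <- tr
    for (s in config$steps) {
      cur <- switch(s$op,
        crop = cropTime(cur, s$start, s$end),
        baseline = { baseline <- fitBaseline(cur, kind = s$kind %||% "polynomial",
                                             degree = s$degree %||% 1,
                                             markers = unlist(s$markers))
                     cur },
        dff = computeDFF(cur, baseline, invert = isTRUE(s$invert)),
        filter = do.call(applyFilter,
                         c(list(cur), s[setdiff(names(s), "op")])),
        resample = resampleTrace(cur, s$rate, method = s$method %||% "linear"))
    }
    cur
  }))

  results <- stats::setNames(processed, paste0("trace_", labels))
  events <- NULL
  if (!is.null(config$detection)) {
    events <- stage("detection", lapply(processed, function(p) {
      th <- config$detection$threshold
      curve <- makeThreshold(p, mode = th$mode %||% "dynamic",
                             level = th$level, window = th$window %||% 1,
                             k = th$k %||% 3)
      if (config$detection$mode == "spikes")
        detectSpikes(p, curve, refractory = config$detection$refractory %||% 0)
      else
        detectBursts(p, curve,
                     minDuration = config$detection$minDuration %||% 0,
                     endFraction = config$detection$endFraction %||% 0.5)
    }))
    results <- c(results, stats::setNames(
      events, paste0(config$detection$mode, "_", labels)))
  }
  if (!is.null(config$analyses$spectrum)) {
    sp <- config$analyses$spectrum
    specs <- stage("spectrum", lapply(processed, function(p)
      powerSpectrum(p, method = sp$method %||% "averaged_segment",
                    segmentLength = sp$segmentLength %||% 10)))
    results <- c(results, stats::setNames(specs, paste0("spectrum_", labels)))
  }
  if (!is.null(config$analyses$xcorr)) {
    xc <- config$analyses$xcorr
    pairs <- utils::combn(seq_along(labels), 2)
    xcs <- stage("xcorr", apply(pairs, 2, function(pr) {
      i <- pr[1]; j <- pr[2]
      switch(xc$kind,
        amplitude = amplitudeXcorr(processed[[i]], processed[[j]],
                                   maxLag = xc$maxLag %||% 1,
                                   band = unlist(xc$band)),
        instantaneous = instantaneousXcorr(processed[[i]], processed[[j]],
                                           maxLag = xc$maxLag %||% 1,
                                           band = unlist(xc$band)),
        spike = spikeXcorr(events[[i]], events[[j]],
                           maxLag = xc$maxLag %||% 1,
                           binWidth = xc$binWidth))
    }, simplify = FALSE))
    names(xcs) <- apply(pairs, 2, function(pr)
      paste0("xcorr_", labels[pr[1]], "_", labels[pr[2]]))
    results <- c(results, xcs)
  }

  files <- stage("export", exportTables(results, outDir))
  provenance <- stats::setNames(lapply(processed, traceSteps), labels)
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfgJson, tf)
  manifest <- list(
    package = "optovolt",
    version = as.character(utils::packageVersion("optovolt")),
    rVersion = R.version.string,
    configHash = unname(tools::md5sum(tf)),
    config = config,
    rois = as.list(labels),
    files = as.list(files),
    provenance = provenance)
  unlink(tf)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("pipeline complete: %d result files in %s", length(files), outDir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
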