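#' Detect and track foci in every burst of a stack
#'
#' Detection runs per frame; linking runs within each burst (tracks must be
#' consecutive frames of one burst — the minutes-long gaps between bursts
#' are never bridged) and short tracks are discarded per the strict
#' track-length rule.
#'
#' @param stack an [ImageStack-class].
#' @param channel channel name.
#' @param params a [DetectionParams-class].
#' @param framesPerBurstUsed optional cap on frames analysed per burst
#'   (the first so many); `NULL` analyses all frames.
#' @return list with `spotsByFrame` (per-frame data.frames over analysed
#'   frames, `NULL` for skipped ones), `tracksByBurst` (filtered
#'   [TrackSet-class] per burst, frames 0-based within the burst) and
#'   `burstTimesMin`.
#' @export
analyzeStack <- function(stack, channel, params = detectionParams(),
                         framesPerBurstUsed = NULL) {
  arr <- stack@frames[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  acq <- stack@acquisition
  bursts <- sort(unique(stack@burstIndex))
  nF <- dim(arr)[3]
  spotsByFrame <- vector("list", nF)
  tracksByBurst <- vector("list", length(bursts))
  burstTimes <- numeric(length(bursts))
  for (bi in seq_along(bursts)) {
    idx <- which(stack@burstIndex == bursts[bi])
    burstTimes[bi] <- min(stack@timestampsMin[idx])
    if (!is.null(framesPerBurstUsed))
      idx <- idx[seq_len(min(framesPerBurstUsed, length(idx)))]
    perFrame <- lapply(idx, function(f) detectSpots(arr[, , f], params))
    spotsByFrame[idx] <- perFrame
    ts <- linkSpots(perFrame, params,
                    pixelSizeUm = acq@pixelSizeUm,
                    frameIntervalS = acq@frameIntervalS)
    tracksByBurst[[bi]] <- filterTracks(ts, params)
  }
  list(spotsByFrame = spotsByFrame, tracksByBurst = tracksByBurst,
       burstTimesMin = burstTimes)
}

#' Analyse one cell: tracks, intensity trace, and focus-loss calls
#'
#' Runs [analyzeStack()] on the requested channel, derives per-burst focus
#' presence from the filtered tracks, builds the burst-level intensity
#' trace at the tracked positions (carried forward after loss), and calls
#' focus loss by both methods. The detection-absence call is the primary
#' loss time: focus extinction is gradual, so an intensity threshold fires
#' while the focus is still fading, whereas the first trackless burst
#' pins the extinction itself (quantized to the burst clock).
#'
#' @param stack an [ImageStack-class].
#' @param channel channel name.
#' @param params a [DetectionParams-class].
#' @param framesPerBurstUsed see [analyzeStack()].
#' @param thresholdFraction,persistencePoints,minDropPercent passed to
#'   [callFocusLoss()].
#' @return list with `analysis` (from [analyzeStack()]), `trace`
#'   (burst-level [IntensityTrace-class] or NULL), `lossAbsence`,
#'   `lossIntensity` ([FocusLossEvent-class]).
#' @export
analyzeCell <- function(stack, channel, params = detectionParams(),
                        framesPerBurstUsed = NULL,
                        thresholdFraction = 0.5, persistencePoints = 3L,
                        minDropPercent = 25) {
  an <- analyzeStack(stack, channel, params, framesPerBurstUsed)
  present <- vapply(an$tracksByBurst, function(ts) nTracks(ts) > 0,
                    logical(1))
  lossAbsence <- callFocusLoss(presentByBurst = present,
                               burstTimesMin = an$burstTimesMin,
                               persistencePoints = persistencePoints,
                               channel = channel)

  # per-frame focus positions from spots of the filtered tracks
  nF <- length(stack@timestampsMin)
  xy <- matrix(NA_real_, nF, 2)
  bursts <- sort(unique(stack@burstIndex))
  for (bi in seq_along(bursts)) {
    ts <- an$tracksByBurst[[bi]]
    if (!nrow(ts@spots)) next
    idx <- which(stack@burstIndex == bursts[bi])
    # keep the longest track of the burst
    lens <- table(ts@spots$track_id)
    main <- ts@spots[ts@spots$track_id ==
                       names(lens)[which.max(lens)], , drop = FALSE]
    xy[idx[main$frame + 1L], ] <- cbind(main$x_px, main$y_px)
  }
  trace <- NULL
  lossIntensity <- new("FocusLossEvent", channel = channel, lost = FALSE,
                       tLossMin = NA_real_, method = "intensity")
  if (any(!is.na(xy[, 1]))) {
    # keep the measurement line inside the field when a focus sits at the
    # border (intensityRatioTrace itself treats that as an error)
    half <- params@radiusPx
    h <- dim(stack@frames[[channel]])[1]
    w <- dim(stack@frames[[channel]])[2]
    xy[, 1] <- pmin(pmax(xy[, 1], half + 0.6), w - half - 0.6)
    xy[, 2] <- pmin(pmax(xy[, 2], 0.6), h - 0.6)
    avoid <- lapply(an$spotsByFrame, function(sp) {
      if (is.null(sp) || !nrow(sp)) NULL else cbind(sp$x_px, sp$y_px)
    })
    full <- intensityRatioTrace(stack, channel, xy,
                                lineLengthPx = 2L * params@radiusPx + 1L,
                                avoidXyPx = avoid)
    analysed <- which(!vapply(an$spotsByFrame, is.null, logical(1)))
    sub <- new("IntensityTrace",
               timesMin = full@timesMin[analysed],
               ratioPercent = 100 * full@ratioPercent[analysed] /
                 full@ratioPercent[analysed][1],
               channel = channel)
    trace <- collapseTraceByBurst(sub, stack@burstIndex[analysed])
    lossIntensity <- callFocusLoss(trace,
                                   thresholdFraction = thresholdFraction,
                                   persistencePoints = persistencePoints,
                                   minDropPercent = minDropPercent,
                                   channel = channel)
  }
  list(analysis = an, trace = trace,
       lossAbsence = lossAbsence, lossIntensity = lossIntensity)
}

#' Analyse a simulated cohort end-to-end
#'
#' Runs [analyzeCell()] on both channels of every movie and assembles the
#' per-cell events table used by [buildReport()], plus per-burst track sets
#' of the requested mobility channel for [windowedD()].
#'
#' @param cohort a [MovieCohort-class].
#' @param params a [DetectionParams-class].
#' @param framesPerBurstUsed see [analyzeStack()].
#' @param method `"detection-absence"` (default) or `"intensity"` loss
#'   calls for the events table.
#' @param mobilityChannel channel whose tracks are returned for MSD
#'   analysis (default INT2, the focus that persists in wild type).
#' @return list with `events` (data.frame: cell_id, lost_int1,
#'   t_loss_int1_min, lost_int2, t_loss_int2_min, method), `traces`
#'   (per cell, per channel), `tracksByBurst` and `burstTimesMin` of the
#'   mobility channel (tracks pooled over cells per burst).
#' @export
analyzeCohort <- function(cohort, params = detectionParams(),
                          framesPerBurstUsed = NULL,
                          method = c("detection-absence", "intensity"),
                          mobilityChannel = "INT2") {
  method <- match.arg(method)
  nCells <- length(cohort@movies)
  rows <- vector("list", nCells)
  traces <- vector("list", nCells)
  mobility <- NULL
  burstTimes <- NULL
  for (i in seq_len(nCells)) {
    mv <- cohort@movies[[i]]
    res <- lapply(c("INT1", "INT2"), function(ch) {
      analyzeCell(mv@stack, ch, params, framesPerBurstUsed)
    })
    names(res) <- c("INT1", "INT2")
    pick <- function(r) {
      if (method == "intensity") r$lossIntensity else r$lossAbsence
    }
    e1 <- pick(res$INT1); e2 <- pick(res$INT2)
    rows[[i]] <- data.frame(cell_id = mv@cellId,
                            lost_int1 = e1@lost,
                            t_loss_int1_min = e1@tLossMin,
                            lost_int2 = e2@lost,
                            t_loss_int2_min = e2@tLossMin,
                            method = method)
    traces[[i]] <- lapply(res, `[[`, "trace")
    mb <- res[[mobilityChannel]]$analysis
    if (is.null(mobility)) {
      mobility <- mb$tracksByBurst
      burstTimes <- mb$burstTimesMin
    } else {
      for (b in seq_along(mobility)) {
        mobility[[b]] <- mergeTrackSets(list(mobility[[b]],
                                             mb$tracksByBurst[[b]]))
      }
    }
  }
  list(events = do.call(rbind, rows), traces = traces,
       tracksByBurst = mobility, burstTimesMin = burstTimes)
}

#' Run the full simulate-analyse-report pipeline
#'
#' Simulates one cohort per scenario preset, analyses every movie
#' (detect, track, quantify), computes the mobility time series of the
#' persistent channel, assembles the kinetics report, and (optionally)
#' writes all intermediate artifacts (TIFF stacks, sidecars, CSV tables,
#' report JSON) under `outDir`. Deterministic for a fixed seed.
#'
#' @param presets character vector of scenario presets (see
#'   [scenarioPreset()]), analysed in the given order; the commitment delay
#'   is first minus second.
#' @param nCells cells per scenario.
#' @param seed root integer seed.
#' @param outDir output directory, or `NULL` to skip writing.
#' @param acqOverrides named list of [acquisitionParams()] overrides
#'   applied to every preset (e.g. smaller images for quick runs).
#' @param render a [RenderParams-class].
#' @param params a [DetectionParams-class].
#' @param framesPerBurstUsed frames analysed per burst (default 20: enough
#'   to exceed the strict 15-frame track rule and estimate D).
#' @param constants from [kineticsConstants()].
#' @param writeStacks also write the TIFF stacks (large); default FALSE.
#' @return list with `report` ([ResectionReport-class]), `events` per
#'   scenario, `mobility` (windowed D series per scenario), `cohorts`.
#' @export
runPipeline <- function(presets = c("wt", "yku70"), nCells = 10L, seed = 1L,
                        outDir = NULL,
                        acqOverrides = list(),
                        render = renderParams(),
                        params = detectionParams(),
                        framesPerBurstUsed = 20L,
                        constants = kineticsConstants(),
                        writeStacks = FALSE) {
  eventsByScenario <- list()
  mobility <- list()
  cohorts <- list()
  for (k in seq_along(presets)) {
    p <- presets[k]
    acq <- do.call(acquisitionPreset, c(list(preset = p), acqOverrides))
    coh <- generateMovie(scenarioPreset(p), render = render, acq = acq,
                         nCells = nCells, seed = childSeed(seed, k))
    an <- analyzeCohort(coh, params, framesPerBurstUsed)
    eventsByScenario[[p]] <- an$events
    mobility[[p]] <- windowedD(an$tracksByBurst, an$burstTimesMin,
                               DRef = 0.019)
    cohorts[[p]] <- coh
    if (!is.null(outDir)) {
      dir.create(file.path(outDir, p), recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(an$events,
                       file.path(outDir, p, "events.csv"), row.names = FALSE)
      utils::write.csv(coh@events,
                       file.path(outDir, p, "true_events.csv"),
                       row.names = FALSE)
      utils::write.csv(mobility[[p]],
                       file.path(outDir, p, "diffusion_series.csv"),
                       row.names = FALSE)
      writeTracksCSV(an$tracksByBurst, an$burstTimesMin,
                     file.path(outDir, p, "tracks.csv"))
      if (writeStacks) {
        for (mv in coh@movies) {
          writeImageStack(mv@stack,
                          file.path(outDir, p,
                                    sprintf("cell%03d", mv@cellId)))
        }
      }
    }
  }
  report <- buildReport(eventsByScenario, constants)
  if (!is.null(outDir)) {
    jsonlite::write_json(
      c(reportAsList(report), list(seed = seed, presets = presets)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(report = report, events = eventsByScenario, mobility = mobility,
       cohorts = cohorts)
}

#' Write per-burst track sets to one long-format CSV
#' @keywords internal
#' @noRd
writeTracksCSV <- function(tracksByBurst, burstTimesMin, path) {
  rows <- list()
  for (b in seq_along(tracksByBurst)) {
    ts <- tracksByBurst[[b]]
    if (is.null(ts) || !nrow(ts@spots)) next
    d <- ts@spots
    d$burst <- b
    d$burst_time_min <- burstTimesMin[b]
    rows[[length(rows) + 1L]] <- d
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame = integer(0),
               x_px = numeric(0), y_px = numeric(0),
               intensity = numeric(0), score = numeric(0),
               burst = integer(0), burst_time_min = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
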