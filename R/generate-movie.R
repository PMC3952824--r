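#' Build the per-cell mobility schedule implied by its event times
#'
#' Uncut cells diffuse freely throughout. Cut cells switch to the confined
#' model `confinementOnsetLagMin` minutes after cleavage and back to the
#' free model `recoveryTimeMin` minutes after cleavage (step transitions).
#'
#' @param scenario a [ResectionScenario-class].
#' @param cellEvents one row of the event table from [sampleEventTimes()].
#' @param freeModel free-diffusion [MotionModel-class].
#' @param confinedModel confined [MotionModel-class].
#' @return A [MobilitySchedule-class].
#' @export
mobilityScheduleFor <- function(scenario, cellEvents,
                                freeModel = motionModel("free", 0.019),
                                confinedModel = motionModel("confined", 0.003,
                                                            tauCS = 20)) {
  if (!isTRUE(cellEvents$cut))
    return(mobilitySchedule(0, list(freeModel)))
  tConf <- cellEvents$t_cleave_min + scenario@confinementOnsetLagMin
  tRec <- cellEvents$t_cleave_min + scenario@recoveryTimeMin
  starts <- c(0, tConf)
  models <- list(freeModel, confinedModel)
  if (tRec > tConf) {
    starts <- c(starts, tRec)
    models <- c(models, list(freeModel))
  }
  mobilitySchedule(starts, models)
}

#' Focus amplitude while the resection front traverses a cassette
#'
#' Amplitude is full until the front reaches the proximal end, declines
#' linearly in front position across the cassette (ParB binds dsDNA
#' uniformly along it), and is exactly zero when the front reaches the
#' distal end, i.e. at the cassette's loss time.
#'
#' @keywords internal
#' @noRd
focusAmplitudeFraction <- function(tMin, scenario, cellEvents,
                                   proximalNt, distalNt) {
  if (!isTRUE(cellEvents$cut)) return(rep(1, length(tMin)))
  tOn <- cellEvents$t_onset_min
  el <- pmax(tMin - tOn, 0)  # minutes of resection
  sw <- scenario@phaseSwitchNt
  front <- el * scenario@vSlow
  if (scenario@fastPhaseEnabled) {
    tSw <- sw / scenario@vSlow
    fast <- el > tSw
    front[fast] <- sw + (el[fast] - tSw) * scenario@vFast
  } else {
    front <- pmin(front, sw)  # resection halts at the switch point
  }
  pmin(pmax((distalNt - front) / (distalNt - proximalNt), 0), 1)
}

#' Generate a cohort of dual-channel movies with ground truth
#'
#' For each cell, event times are drawn with [sampleEventTimes()], a
#' mobility schedule is built with [mobilityScheduleFor()], and bursts of
#' `framesPerBurst` frames are rendered every `burstIntervalMin` minutes
#' starting at `burstOriginMin`. The INT1 (mCherry) and INT2 (GFP) foci sit
#' at the same chromatin locus and share a trajectory. Each burst starts
#' from the cell's home position plus a small jitter: between bursts
#' (minutes apart) the locus decorrelates within its nuclear territory, and
#' within-burst dynamics follow the scheduled motion model exactly.
#'
#' @param scenario a [ResectionScenario-class].
#' @param render a [RenderParams-class].
#' @param acq an [AcquisitionParams-class].
#' @param nCells number of cells.
#' @param seed root integer seed; per-cell, per-burst and per-frame streams
#'   are derived by fixed splitting so movies are reproducible cell by cell.
#' @param freeModel,confinedModel motion models passed to
#'   [mobilityScheduleFor()].
#' @param homeJitterUm sd of the per-burst start-position jitter (um).
#' @param noiseFree render the noise-free expectation instead of
#'   Poisson + read noise (used by detector accuracy tests).
#' @return A [MovieCohort-class].
#' @examples
#' coh <- generateMovie(scenarioPreset("uncut"),
#'                      acq = acquisitionParams(totalDurationMin = 14,
#'                                              framesPerBurst = 5L),
#'                      nCells = 1, seed = 7)
#' coh@events
#' @export
generateMovie <- function(scenario,
                          render = renderParams(),
                          acq = acquisitionParams(),
                          nCells = 1L,
                          seed = 1L,
                          freeModel = motionModel("free", 0.019),
                          confinedModel = motionModel("confined", 0.003,
                                                      tauCS = 20),
                          homeJitterUm = 0.15,
                          noiseFree = FALSE) {
  validObject(scenario); validObject(render); validObject(acq)
  events <- sampleEventTimes(scenario, nCells, seed = childSeed(seed, 0L))
  ts <- frameTimestamps(acq)
  nFrames <- length(ts$timesMin)
  home <- c(acq@imageShape[2], acq@imageShape[1]) / 2 * acq@pixelSizeUm

  movies <- vector("list", nCells)
  for (cell in seq_len(nCells)) {
    ev <- events[cell, ]
    sched <- mobilityScheduleFor(scenario, ev, freeModel, confinedModel)
    pos <- matrix(NA_real_, nFrames, 2)
    for (b in unique(ts$burstIndex)) {
      idx <- which(ts$burstIndex == b)
      start <- withSeed(childSeed(seed, cell, 2L, b), {
        home + stats::rnorm(2, 0, homeJitterUm)
      })
      pos[idx, ] <- simulateTrajectory(sched, ts$timesMin[idx], start,
                                       seed = childSeed(seed, cell, 3L, b))
    }
    amp1 <- render@focusPhotons *
      focusAmplitudeFraction(ts$timesMin, scenario, ev,
                             scenario@int1ProximalNt, scenario@int1DistalNt)
    amp2 <- render@focusPhotons *
      focusAmplitudeFraction(ts$timesMin, scenario, ev,
                             scenario@int2ProximalNt, scenario@int2DistalNt)

    h <- acq@imageShape[1]; w <- acq@imageShape[2]
    arr1 <- array(0, c(h, w, nFrames))
    arr2 <- array(0, c(h, w, nFrames))
    for (f in seq_len(nFrames)) {
      foci <- list(
        INT1 = data.frame(x_um = pos[f, 1], y_um = pos[f, 2],
                          amplitude = amp1[f]),
        INT2 = data.frame(x_um = pos[f, 1], y_um = pos[f, 2],
                          amplitude = amp2[f]))
      img <- renderFrame(foci, ts$timesMin[f], render, acq,
                         seed = if (noiseFree) NULL
                                else childSeed(seed, cell, 4L, f))
      arr1[, , f] <- img$INT1
      arr2[, , f] <- img$INT2
    }
    stack <- new("ImageStack",
                 frames = list(INT1 = arr1, INT2 = arr2),
                 timestampsMin = ts$timesMin,
                 burstIndex = as.integer(ts$burstIndex),
                 acquisition = acq)
    mode <- vapply(findInterval(ts$timesMin, sched@startMin), function(s) {
      sched@models[[max(s, 1L)]]@mode
    }, character(1))
    truth <- list(
      cut = ev$cut,
      t_cleave_min = ev$t_cleave_min,
      t_onset_min = ev$t_onset_min,
      t_loss_int1_min = ev$t_loss_int1_min,
      t_loss_int2_min = ev$t_loss_int2_min,
      frames = data.frame(frame = seq_len(nFrames) - 1L,
                          time_min = ts$timesMin,
                          burst = ts$burstIndex,
                          x_um = pos[, 1], y_um = pos[, 2],
                          amp_int1 = amp1, amp_int2 = amp2,
                          mode = mode))
    movies[[cell]] <- new("SimulatedMovie", stack = stack, truth = truth,
                          cellId = as.integer(cell))
  }
  new("MovieCohort", movies = movies, events = events, scenario = scenario,
      acquisition = acq, seed = as.integer(seed))
}
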