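#' @import methods
NULL

#' Acquisition parameters for burst time-lapse imaging
#'
#' Physical calibration and timing of the burst acquisition scheme: stacks of
#' `framesPerBurst` consecutive short exposures (fast lags for MSD analysis)
#' repeated every `burstIntervalMin` minutes (the slow clock for focus-loss
#' timing), starting `burstOriginMin` minutes after induction.
#'
#' @slot pixelSizeUm length of one pixel side in micrometres.
#' @slot frameIntervalS within-burst frame spacing in seconds.
#' @slot framesPerBurst number of frames per burst.
#' @slot burstIntervalMin spacing between burst starts in minutes.
#' @slot imageShape integer (height, width) in pixels.
#' @slot bitDepth unsigned-integer camera depth.
#' @slot totalDurationMin movie span in minutes on the induction axis.
#' @slot burstOriginMin time of the first burst, minutes post-induction.
#' @export
setClass("AcquisitionParams", representation(
  pixelSizeUm = "numeric",
  frameIntervalS = "numeric",
  framesPerBurst = "integer",
  burstIntervalMin = "numeric",
  imageShape = "integer",
  bitDepth = "integer",
  totalDurationMin = "numeric",
  burstOriginMin = "numeric"
))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  num <- c(object@pixelSizeUm, object@frameIntervalS, object@burstIntervalMin,
           object@totalDurationMin)
  if (any(!is.finite(num)) || any(num <= 0))
    msg <- c(msg, "pixel size, frame interval, burst interval and duration must be positive")
  if (object@framesPerBurst < 2L)
    msg <- c(msg, "framesPerBurst must be at least 2")
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be two positive integers")
  if (object@bitDepth < 1L || object@bitDepth > 32L)
    msg <- c(msg, "bitDepth must be in [1, 32]")
  if (object@burstIntervalMin * 60 < object@framesPerBurst * object@frameIntervalS)
    msg <- c(msg, "bursts must fit inside the burst interval")
  if (object@burstOriginMin < 0)
    msg <- c(msg, "burstOriginMin must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Single-mode motion model for a chromatin locus
#'
#' Either free Brownian diffusion (`mode = "free"`) with coefficient
#' `D` (um^2/s), or confined diffusion (`mode = "confined"`) modelled as an
#' Ornstein-Uhlenbeck process with short-time coefficient `D` and
#' relaxation time `tauCS` seconds; the stationary per-axis variance is
#' `D * tauCS` and the MSD plateaus at `4 * D * tauCS`.
#'
#' @slot mode `"free"` or `"confined"`.
#' @slot D diffusion coefficient in um^2/s.
#' @slot tauCS confinement relaxation time in seconds (`NA` for free mode).
#' @export
setClass("MotionModel", representation(
  mode = "character",
  D = "numeric",
  tauCS = "numeric"
))

setValidity("MotionModel", function(object) {
  msg <- character()
  if (!object@mode %in% c("free", "confined"))
    msg <- c(msg, "mode must be 'free' or 'confined'")
  if (!is.finite(object@D) || object@D < 0)
    msg <- c(msg, "D must be finite and nonnegative")
  if (object@mode == "confined" && (!is.finite(object@tauCS) || object@tauCS <= 0))
    msg <- c(msg, "confined mode requires tauCS > 0")
  if (length(msg)) msg else TRUE
})

#' Time-ordered schedule of motion models
#'
#' @slot startMin segment start times in minutes, strictly increasing,
#'   first equal to 0.
#' @slot models list of [MotionModel-class], one per segment.
#' @export
setClass("MobilitySchedule", representation(
  startMin = "numeric",
  models = "list"
))

setValidity("MobilitySchedule", function(object) {
  msg <- character()
  if (length(object@startMin) != length(object@models))
    msg <- c(msg, "startMin and models must have equal length")
  if (length(object@startMin) == 0L)
    msg <- c(msg, "schedule must have at least one segment")
  else {
    if (object@startMin[1] != 0)
      msg <- c(msg, "first segment must start at 0")
    if (any(diff(object@startMin) <= 0))
      msg <- c(msg, "segment start times must be strictly increasing")
  }
  if (!all(vapply(object@models, is, logical(1), "MotionModel")))
    msg <- c(msg, "models must all be MotionModel objects")
  if (length(msg)) msg else TRUE
})

#' Biological scenario of cleavage and resection
#'
#' Parameters of the per-cell event model: a fraction `pCut` of cells is
#' cleaved at a truncated-Gaussian time, resection starts after a commitment
#' lag, and the resection front advances at `vSlow` nt/min until
#' `phaseSwitchNt` then (if `fastPhaseEnabled`) at `vFast` nt/min. Focus k is
#' extinguished when the front reaches the distal end of cassette k.
#'
#' @slot name preset label.
#' @slot pCut fraction of cells cleaved.
#' @slot cleavageMeanMin,cleavageSdMin Gaussian cleavage-time parameters (min).
#' @slot cleavageMinMin truncation floor (min).
#' @slot commitmentLagMin delay from cleavage to resection onset (min).
#' @slot vSlow,vFast slow/fast-phase resection speeds (nt/min).
#' @slot phaseSwitchNt slow-to-fast transition position (nt from cut).
#' @slot fastPhaseEnabled whether resection proceeds past the first cassette.
#' @slot int1ProximalNt,int1DistalNt INT1 cassette span (nt from cut).
#' @slot int2ProximalNt,int2DistalNt INT2 cassette span (nt from cut).
#' @slot confinementOnsetLagMin cleavage-to-confinement delay (min).
#' @slot recoveryTimeMin confinement end, minutes after cleavage.
#' @export
setClass("ResectionScenario", representation(
  name = "character",
  pCut = "numeric",
  cleavageMeanMin = "numeric",
  cleavageSdMin = "numeric",
  cleavageMinMin = "numeric",
  commitmentLagMin = "numeric",
  vSlow = "numeric",
  vFast = "numeric",
  phaseSwitchNt = "numeric",
  fastPhaseEnabled = "logical",
  int1ProximalNt = "numeric",
  int1DistalNt = "numeric",
  int2ProximalNt = "numeric",
  int2DistalNt = "numeric",
  confinementOnsetLagMin = "numeric",
  recoveryTimeMin = "numeric"
))

setValidity("ResectionScenario", function(object) {
  msg <- character()
  if (object@pCut < 0 || object@pCut > 1)
    msg <- c(msg, "pCut must lie in [0, 1]")
  if (object@cleavageMinMin < 0)
    msg <- c(msg, "cleavageMinMin must be nonnegative")
  if (object@cleavageSdMin < 0)
    msg <- c(msg, "cleavageSdMin must be nonnegative")
  if (object@int1ProximalNt >= object@int1DistalNt)
    msg <- c(msg, "INT1 proximal end must precede its distal end")
  if (object@int2ProximalNt >= object@int2DistalNt)
    msg <- c(msg, "INT2 proximal end must precede its distal end")
  if (object@vSlow <= 0)
    msg <- c(msg, "vSlow must be positive")
  if (object@fastPhaseEnabled && object@vFast <= 0)
    msg <- c(msg, "vFast must be positive when the fast phase is enabled")
  if (object@commitmentLagMin < 0)
    msg <- c(msg, "commitmentLagMin must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Rendering parameters for synthetic fluorescence frames
#'
#' @slot psfSigmaPx Gaussian point-spread sd in pixels.
#' @slot focusPhotons expected photon count of an intact focus.
#' @slot backgroundPhotons0 initial background photon level per pixel.
#' @slot bleachTauMin background photobleaching time constant (min);
#'   `Inf` disables bleaching.
#' @slot readNoiseSd Gaussian read noise sd (photons).
#' @slot cameraGain photons-to-counts conversion factor.
#' @export
setClass("RenderParams", representation(
  psfSigmaPx = "numeric",
  focusPhotons = "numeric",
  backgroundPhotons0 = "numeric",
  bleachTauMin = "numeric",
  readNoiseSd = "numeric",
  cameraGain = "numeric"
))

setValidity("RenderParams", function(object) {
  msg <- character()
  if (!is.finite(object@psfSigmaPx) || object@psfSigmaPx <= 0)
    msg <- c(msg, "psfSigmaPx must be positive")
  other <- c(object@focusPhotons, object@backgroundPhotons0,
             object@readNoiseSd, object@cameraGain)
  if (any(other < 0) || any(is.na(other)))
    msg <- c(msg, "photon counts, noise and gain must be nonnegative")
  if (object@bleachTauMin <= 0)
    msg <- c(msg, "bleachTauMin must be positive (Inf disables bleaching)")
  if (length(msg)) msg else TRUE
})

#' Detection and tracking parameters
#'
#' Defaults follow the classical particle detector/tracker settings for this
#' assay: radius 4 px, no score cutoff, top 0.1 percent of filtered
#' intensities retained, 10 px link radius, and only tracks longer than 15
#' consecutive frames scored.
#'
#' @slot radiusPx integer spot radius in pixels.
#' @slot cutoff non-particle discrimination score floor.
#' @slot percentile top percentage of filtered intensities retained (0.1
#'   means the top 0.1 percent).
#' @slot maxDisplacementPx frame-to-frame link radius in pixels.
#' @slot minTrackFrames minimum scored track length, strict (tracks must
#'   exceed it).
#' @export
setClass("DetectionParams", representation(
  radiusPx = "integer",
  cutoff = "numeric",
  percentile = "numeric",
  maxDisplacementPx = "numeric",
  minTrackFrames = "integer"
))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@radiusPx < 1L)
    msg <- c(msg, "radiusPx must be at least 1")
  if (!is.finite(object@percentile) || object@percentile <= 0 ||
      object@percentile > 100)
    msg <- c(msg, "percentile must lie in (0, 100]")
  if (object@maxDisplacementPx < 1)
    msg <- c(msg, "maxDisplacementPx must be at least 1")
  if (object@minTrackFrames < 0L)
    msg <- c(msg, "minTrackFrames must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' A dual-channel burst time-lapse image stack for one cell
#'
#' Frames are stored per channel as height x width x time integer arrays.
#' Timestamps are minutes on the induction axis; all frames within a burst
#' map to the burst start time for kinetic analyses (the 10 s within-burst
#' span is negligible against the minutes axis).
#'
#' @slot frames named list per channel of H x W x T arrays.
#' @slot timestampsMin acquisition time of each frame in minutes.
#' @slot burstIndex 1-based burst index of each frame.
#' @slot acquisition [AcquisitionParams-class].
#' @export
setClass("ImageStack", representation(
  frames = "list",
  timestampsMin = "numeric",
  burstIndex = "integer",
  acquisition = "AcquisitionParams"
))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(object@frames) == 0L)
    msg <- c(msg, "at least one channel required")
  nt <- length(object@timestampsMin)
  for (ch in names(object@frames)) {
    a <- object@frames[[ch]]
    if (length(dim(a)) != 3L)
      msg <- c(msg, sprintf("channel '%s' must be a 3D array", ch))
    else if (dim(a)[3] != nt)
      msg <- c(msg, sprintf("channel '%s' frame count != timestamps", ch))
    else if (min(a) < 0 || max(a) >= 2^object@acquisition@bitDepth)
      msg <- c(msg, sprintf("channel '%s' pixel values outside bit depth", ch))
  }
  if (nt > 1 && any(diff(object@timestampsMin) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(object@burstIndex) != nt)
    msg <- c(msg, "burstIndex length != timestamps")
  if (length(msg)) msg else TRUE
})

#' A set of single-focus tracks
#'
#' Tracks are stored long-format: one row per (track, frame) with sub-pixel
#' positions in pixels. Frame indices within a track are consecutive
#' (no gap closing).
#'
#' @slot spots data.frame with columns track_id, frame, x_px, y_px,
#'   intensity, score.
#' @slot pixelSizeUm pixel size carried from acquisition.
#' @slot frameIntervalS frame interval carried from acquisition.
#' @export
setClass("TrackSet", representation(
  spots = "data.frame",
  pixelSizeUm = "numeric",
  frameIntervalS = "numeric"
))

setValidity("TrackSet", function(object) {
  need <- c("track_id", "frame", "x_px", "y_px")
  if (!all(need %in% names(object@spots)))
    return("spots must have columns track_id, frame, x_px, y_px")
  sp <- object@spots
  if (nrow(sp)) {
    bad <- vapply(split(sp$frame, sp$track_id), function(f) {
      any(diff(sort(f)) != 1L) || anyDuplicated(f) > 0L
    }, logical(1))
    if (any(bad))
      return("each track must occupy strictly consecutive frames, one spot per frame")
  }
  TRUE
})

#' Background-normalized focus-intensity trace
#'
#' @slot timesMin timestamps (minutes, induction axis).
#' @slot ratioPercent intensity ratio normalized to 100 at the first point.
#' @slot channel channel label.
#' @export
setClass("IntensityTrace", representation(
  timesMin = "numeric",
  ratioPercent = "numeric",
  channel = "character"
))

setValidity("IntensityTrace", function(object) {
  msg <- character()
  if (length(object@timesMin) != length(object@ratioPercent))
    msg <- c(msg, "times and ratios must have equal length")
  if (length(object@ratioPercent) &&
      abs(object@ratioPercent[1] - 100) > 1e-9)
    msg <- c(msg, "trace must be normalized to 100 at the first timepoint")
  if (length(msg)) msg else TRUE
})

#' A focus-loss call for one cell and channel
#'
#' @slot channel channel label.
#' @slot lost whether the focus was lost.
#' @slot tLossMin loss time in minutes (`NA` when not lost).
#' @slot method `"intensity"` or `"detection-absence"`.
#' @export
setClass("FocusLossEvent", representation(
  channel = "character",
  lost = "logical",
  tLossMin = "numeric",
  method = "character"
))

setValidity("FocusLossEvent", function(object) {
  if (object@lost != !is.na(object@tLossMin))
    return("tLossMin must be present exactly when lost")
  if (!object@method %in% c("intensity", "detection-absence"))
    return("method must be 'intensity' or 'detection-absence'")
  TRUE
})

#' Mean-square displacement curve
#'
#' @slot lagsS lag times in seconds.
#' @slot msdUm2 ensemble MSD per lag in um^2.
#' @slot nPairs displacement-pair count per lag.
#' @slot nTracks number of tracks contributing.
#' @export
setClass("MSDResult", representation(
  lagsS = "numeric",
  msdUm2 = "numeric",
  nPairs = "numeric",
  nTracks = "integer"
))

setValidity("MSDResult", function(object) {
  msg <- character()
  n <- length(object@lagsS)
  if (length(object@msdUm2) != n || length(object@nPairs) != n)
    msg <- c(msg, "lags, msd and nPairs must have equal length")
  if (any(object@msdUm2 < 0, na.rm = TRUE))
    msg <- c(msg, "MSD values must be nonnegative")
  if (n > 1 && any(diff(object@nPairs) > 0))
    msg <- c(msg, "nPairs must be nonincreasing in lag")
  if (length(msg)) msg else TRUE
})

#' Diffusion coefficient fitted from the short-lag MSD slope
#'
#' Ordinary least squares of MSD on lag over lags at or below
#' `fitMaxLagS`, with an intercept absorbing localization noise;
#' `D = slope / 4` for 2D tracking.
#'
#' @slot D fitted diffusion coefficient (um^2/s).
#' @slot interceptUm2 fitted offset (um^2).
#' @slot fitMaxLagS fit window (s).
#' @slot normalizedPercent `100 * D / DRef` when a reference was supplied.
#' @slot DRef reference (uncut-locus) coefficient (um^2/s), `NA` if none.
#' @slot nLags number of lags used in the fit.
#' @export
setClass("DiffusionEstimate", representation(
  D = "numeric",
  interceptUm2 = "numeric",
  fitMaxLagS = "numeric",
  normalizedPercent = "numeric",
  DRef = "numeric",
  nLags = "integer"
))

setValidity("DiffusionEstimate", function(object) {
  if (is.na(object@DRef) != is.na(object@normalizedPercent))
    return("normalizedPercent must be present exactly when DRef is supplied")
  TRUE
})

#' Summary of focus-loss times as a Gaussian-by-moments distribution
#'
#' @slot n number of loss events.
#' @slot meanMin sample mean (min).
#' @slot sdMin sample sd, n - 1 denominator (min; 0 when n = 1).
#' @slot minMin earliest loss (min).
#' @slot maxMin latest loss (min).
#' @export
setClass("LossTimeDistribution", representation(
  n = "integer",
  meanMin = "numeric",
  sdMin = "numeric",
  minMin = "numeric",
  maxMin = "numeric"
))

setValidity("LossTimeDistribution", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be at least 1")
  if (!is.na(object@meanMin) &&
      (object@meanMin < object@minMin - 1e-9 ||
       object@meanMin > object@maxMin + 1e-9))
    msg <- c(msg, "mean must lie within [min, max]")
  if (object@sdMin < 0) msg <- c(msg, "sd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Resection kinetics report across genotype scenarios
#'
#' @slot scenarios named list; per scenario a list with loss-time
#'   distributions, durations, speeds and the fraction of cells losing
#'   each focus.
#' @slot commitmentDelayMin wild-type-minus-mutant delay (min), `NA` when
#'   fewer than two scenarios carry INT1 losses.
#' @slot constants list with int1_distal_nt, int2_distal_nt,
#'   earliest_cleavage_min.
#' @export
setClass("ResectionReport", representation(
  scenarios = "list",
  commitmentDelayMin = "numeric",
  constants = "list"
))

#' A cohort of simulated movies
#'
#' @slot movies list of [SimulatedMovie-class].
#' @slot events data.frame of true event times, one row per cell.
#' @slot scenario the [ResectionScenario-class] used.
#' @slot acquisition the [AcquisitionParams-class] used.
#' @slot seed root seed of the simulation.
#' @export
setClass("MovieCohort", representation(
  movies = "list",
  events = "data.frame",
  scenario = "ResectionScenario",
  acquisition = "AcquisitionParams",
  seed = "integer"
))

#' A simulated movie with its ground truth
#'
#' @slot stack [ImageStack-class] for the cell.
#' @slot truth list: cut flag, event times, and a per-frame data.frame of
#'   true positions (um), per-channel amplitudes and the active motion mode.
#' @slot cellId integer cell identifier.
#' @export
setClass("SimulatedMovie", representation(
  stack = "ImageStack",
  truth = "list",
  cellId = "integer"
))
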