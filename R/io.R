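#' Write an image stack as multi-page TIFF files plus a JSON sidecar
#'
#' One 16-bit little-endian multi-page TIFF per channel (page order =
#' time), named `<prefix>_<channel>.tif`, with timestamps and acquisition
#' parameters in `<prefix>_meta.json`. Pixel values round-trip exactly.
#'
#' @param stack an [ImageStack-class].
#' @param prefix output path prefix (directories are created).
#' @return Invisibly, the written file paths.
#' @export
writeImageStack <- function(stack, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^stack@acquisition@bitDepth - 1
  paths <- character(0)
  for (ch in names(stack@frames)) {
    arr <- stack@frames[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(f) arr[, , f] / maxval)
    p <- sprintf("%s_%s.tif", prefix, ch)
    tiff::writeTIFF(pages, p, bits.per.sample = 16L, compression = "none")
    paths <- c(paths, p)
  }
  acq <- stack@acquisition
  meta <- list(
    channels = names(stack@frames),
    timestamps_min = stack@timestampsMin,
    burst_index = stack@burstIndex,
    acquisition = list(pixel_size_um = acq@pixelSizeUm,
                       frame_interval_s = acq@frameIntervalS,
                       frames_per_burst = acq@framesPerBurst,
                       burst_interval_min = acq@burstIntervalMin,
                       image_shape = acq@imageShape,
                       bit_depth = acq@bitDepth,
                       total_duration_min = acq@totalDurationMin,
                       burst_origin_min = acq@burstOriginMin))
  mp <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read an image stack written by [writeImageStack()]
#'
#' @param prefix path prefix used when writing.
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(prefix) {
  meta <- jsonlite::read_json(sprintf("%s_meta.json", prefix),
                              simplifyVector = TRUE)
  a <- meta$acquisition
  acq <- acquisitionParams(pixelSizeUm = a$pixel_size_um,
                           frameIntervalS = a$frame_interval_s,
                           framesPerBurst = a$frames_per_burst,
                           burstIntervalMin = a$burst_interval_min,
                           imageShape = a$image_shape,
                           bitDepth = a$bit_depth,
                           totalDurationMin = a$total_duration_min,
                           burstOriginMin = a$burst_origin_min)
  maxval <- 2^acq@bitDepth - 1
  frames <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) arr[, , f] <- round(pages[[f]] * maxval)
    frames[[ch]] <- arr
  }
  new("ImageStack", frames = frames,
      timestampsMin = as.numeric(meta$timestamps_min),
      burstIndex = as.integer(meta$burst_index),
      acquisition = acq)
}

#' Write the ground truth of a simulated movie as a JSON sidecar
#'
#' @param movie a [SimulatedMovie-class].
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
writeGroundTruth <- function(movie, path) {
  tr <- movie@truth
  jsonlite::write_json(
    list(cell_id = movie@cellId, cut = tr$cut,
         t_cleave_min = tr$t_cleave_min, t_onset_min = tr$t_onset_min,
         t_loss_int1_min = tr$t_loss_int1_min,
         t_loss_int2_min = tr$t_loss_int2_min,
         frames = tr$frames),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("ImageStack: %d channel(s) [%s], %dx%d px, %d frames, %d bursts\n",
              length(object@frames),
              paste(names(object@frames), collapse = ", "),
              d[1], d[2], d[3], length(unique(object@burstIndex))))
})

setMethod("show", "MovieCohort", function(object) {
  cat(sprintf("MovieCohort: %d cells, scenario '%s', seed %d\n",
              length(object@movies), object@scenario@name, object@seed))
  print(object@events)
})

setMethod("show", "MSDResult", function(object) {
  cat(sprintf("MSDResult: %d lags (max %.2f s), %d tracks\n",
              length(object@lagsS), max(object@lagsS), object@nTracks))
})

setMethod("show", "DiffusionEstimate", function(object) {
  cat(sprintf("D = %.4g um^2/s (intercept %.4g um^2, %d lags <= %.1f s)",
              object@D, object@interceptUm2, object@nLags,
              object@fitMaxLagS))
  if (!is.na(object@normalizedPercent))
    cat(sprintf(", %.1f%% of reference %.3g", object@normalizedPercent,
                object@DRef))
  cat("\n")
})

setMethod("show", "FocusLossEvent", function(object) {
  if (object@lost)
    cat(sprintf("FocusLossEvent[%s]: lost at %.1f min (%s)\n",
                object@channel, object@tLossMin, object@method))
  else
    cat(sprintf("FocusLossEvent[%s]: not lost (%s)\n",
                object@channel, object@method))
})

setMethod("show", "LossTimeDistribution", function(object) {
  cat(sprintf("LossTimeDistribution: n=%d, %.1f +/- %.1f min, range [%.1f, %.1f]\n",
              object@n, object@meanMin, object@sdMin,
              object@minMin, object@maxMin))
})
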