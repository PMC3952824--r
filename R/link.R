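#' Link per-frame spots into single-focus tracks
#'
#' Greedy globally-nearest-neighbour linking between consecutive frames:
#' all candidate pairs within `maxDisplacementPx` are sorted by distance
#' (ties broken by the lower frame-local spot index) and accepted when both
#' endpoints are still unassigned. Unmatched spots start new tracks; a
#' track ends at the first frame with no match — there is no gap closing,
#' so every track occupies strictly consecutive frames.
#'
#' @param spotsByFrame list of per-frame spot data.frames (columns `x_px`,
#'   `y_px`, optionally `intensity`, `score`), indexed by consecutive
#'   frames; empty frames may be `NULL` or zero-row.
#' @param params a [DetectionParams-class].
#' @param pixelSizeUm,frameIntervalS calibration carried into the
#'   [TrackSet-class] for downstream MSD analysis.
#' @return A [TrackSet-class]; `frame` is the 0-based index into
#'   `spotsByFrame`.
#' @examples
#' fr <- lapply(0:19, function(f) data.frame(x_px = 10 + 0.1 * f, y_px = 8))
#' tracks(linkSpots(fr, detectionParams()))
#' @export
linkSpots <- function(spotsByFrame, params = detectionParams(),
                      pixelSizeUm = 0.065, frameIntervalS = 0.2) {
  validObject(params)
  nF <- length(spotsByFrame)
  norm <- function(df) {
    if (is.null(df) || !nrow(df))
      return(data.frame(x_px = numeric(0), y_px = numeric(0),
                        intensity = numeric(0), score = numeric(0)))
    if (is.null(df$intensity)) df$intensity <- NA_real_
    if (is.null(df$score)) df$score <- NA_real_
    df[, c("x_px", "y_px", "intensity", "score")]
  }
  frames <- lapply(spotsByFrame, norm)

  rows <- list()       # accumulated spot rows
  nextId <- 1L
  active <- list()     # open tracks: list(id, x, y)
  for (f in seq_len(nF)) {
    cur <- frames[[f]]
    nCur <- nrow(cur)
    assignedPrev <- logical(length(active))
    assignedCur <- logical(nCur)
    trackOf <- integer(nCur)

    if (length(active) && nCur) {
      px <- vapply(active, `[[`, numeric(1), "x")
      py <- vapply(active, `[[`, numeric(1), "y")
      d <- sqrt(outer(px, cur$x_px, "-")^2 + outer(py, cur$y_px, "-")^2)
      cand <- which(d <= params@maxDisplacementPx, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], cand[, 1], cand[, 2])
        for (k in ord) {
          a <- cand[k, 1]; b <- cand[k, 2]
          if (!assignedPrev[a] && !assignedCur[b]) {
            assignedPrev[a] <- TRUE
            assignedCur[b] <- TRUE
            trackOf[b] <- active[[a]]$id
          }
        }
      }
    }

    newActive <- list()
    for (b in seq_len(nCur)) {
      if (!assignedCur[b]) {
        trackOf[b] <- nextId
        nextId <- nextId + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = trackOf[b], frame = f - 1L,
        x_px = cur$x_px[b], y_px = cur$y_px[b],
        intensity = cur$intensity[b], score = cur$score[b])
      newActive[[length(newActive) + 1L]] <-
        list(id = trackOf[b], x = cur$x_px[b], y = cur$y_px[b])
    }
    active <- newActive  # tracks unmatched at this frame are closed
  }

  spots <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame = integer(0),
               x_px = numeric(0), y_px = numeric(0),
               intensity = numeric(0), score = numeric(0))
  new("TrackSet", spots = spots, pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS)
}

#' Keep only tracks longer than the scoring minimum
#'
#' Retention is strict: a track of exactly `minTrackFrames` frames is
#' dropped; only tracks of more than `minTrackFrames` consecutive frames
#' are scored.
#'
#' @param trackSet a [TrackSet-class].
#' @param params a [DetectionParams-class].
#' @return A filtered [TrackSet-class].
#' @export
filterTracks <- function(trackSet, params = detectionParams()) {
  validObject(params)
  sp <- trackSet@spots
  if (!nrow(sp)) return(trackSet)
  len <- table(sp$track_id)
  keep <- names(len)[len > params@minTrackFrames]
  out <- sp[as.character(sp$track_id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  initialize(trackSet, spots = out)
}

#' Number of tracks in a track set
#' @param x a [TrackSet-class].
#' @return integer count.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname nTracks
#' @export
setMethod("nTracks", "TrackSet", function(x) {
  length(unique(x@spots$track_id))
})

#' Split a track set into per-track data.frames
#' @param x a [TrackSet-class].
#' @return named list of data.frames, one per track.
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname tracks
#' @export
setMethod("tracks", "TrackSet", function(x) {
  split(x@spots, x@spots$track_id)
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d tracks, %d spots (px %.3f um, dt %.3f s)\n",
              nTracks(object), nrow(object@spots),
              object@pixelSizeUm, object@frameIntervalS))
})
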