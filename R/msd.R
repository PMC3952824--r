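#' Compute the ensemble mean-square displacement of a track set
#'
#' Per track, the time-averaged MSD at lag \eqn{k\Delta t} is
#' \deqn{MSD(k\Delta t) = \frac{1}{N-k}\sum_{i=1}^{N-k}
#'   |r_{i+k} - r_i|^2}
#' in um^2. The ensemble curve is by default the unweighted mean over all
#' tracks that reach a given lag (each cell contributes equally regardless
#' of track length); `weighting = "pairs"` instead weights tracks by their
#' displacement-pair counts.
#'
#' @param trackSet a [TrackSet-class] (positions in pixels; calibration is
#'   taken from the object).
#' @param maxLagS largest lag in seconds.
#' @param weighting `"tracks"` (unweighted mean over tracks, default) or
#'   `"pairs"` (pair-count weighted).
#' @return An [MSDResult-class].
#' @examples
#' tt <- (0:49) * 0.2 / 60
#' xy <- simulateTrajectory(motionModel("free", 0.019), tt, c(2, 2), seed = 1)
#' sp <- data.frame(track_id = 1L, frame = 0:49,
#'                  x_px = xy[, 1] / 0.065, y_px = xy[, 2] / 0.065)
#' ts <- new("TrackSet", spots = sp, pixelSizeUm = 0.065, frameIntervalS = 0.2)
#' computeMSD(ts, maxLagS = 2)
#' @export
computeMSD <- function(trackSet, maxLagS = 2,
                       weighting = c("tracks", "pairs")) {
  weighting <- match.arg(weighting)
  sp <- trackSet@spots
  if (!nrow(sp)) stop("empty track set")
  dt <- trackSet@frameIntervalS
  if (maxLagS < dt) stop("maxLagS shorter than one frame interval")
  px <- trackSet@pixelSizeUm
  kMax <- floor(maxLagS / dt + 1e-9)

  perTrack <- lapply(tracks(trackSet), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    x <- tr$x_px * px; y <- tr$y_px * px
    ks <- seq_len(min(kMax, n - 1L))
    if (!length(ks)) return(NULL)
    msd <- vapply(ks, function(k) {
      mean((x[(1 + k):n] - x[1:(n - k)])^2 +
           (y[(1 + k):n] - y[1:(n - k)])^2)
    }, numeric(1))
    list(k = ks, msd = msd, npair = n - ks)
  })
  perTrack <- Filter(Negate(is.null), perTrack)
  if (!length(perTrack)) stop("no track reaches the first lag")

  lags <- seq_len(max(vapply(perTrack, function(p) max(p$k), integer(1))))
  msd <- nPairs <- numeric(length(lags))
  for (k in lags) {
    vals <- wts <- numeric(0)
    for (p in perTrack) {
      j <- match(k, p$k)
      if (!is.na(j)) {
        vals <- c(vals, p$msd[j])
        wts <- c(wts, p$npair[j])
      }
    }
    nPairs[k] <- sum(wts)
    msd[k] <- if (weighting == "tracks") mean(vals)
              else sum(vals * wts) / sum(wts)
  }
  new("MSDResult", lagsS = lags * dt, msdUm2 = msd, nPairs = nPairs,
      nTracks = length(perTrack))
}

#' Estimate the diffusion coefficient from the short-lag MSD slope
#'
#' Ordinary least squares of the ensemble MSD on lag time over lags at or
#' below `fitMaxLagS` (default the first 2 seconds), with an intercept:
#' localization noise adds a lag-independent offset \eqn{4\sigma_{loc}^2}
#' which would otherwise bias the slope. For 2D tracking
#' \eqn{D = slope / 4}. When a reference coefficient is supplied the
#' estimate is also expressed as a percentage of it (the uncut-locus
#' reference, 1.9e-2 um^2/s, set at 100 percent).
#'
#' @param msd an [MSDResult-class].
#' @param fitMaxLagS fit window in seconds (default 2).
#' @param DRef optional reference coefficient (um^2/s).
#' @return A [DiffusionEstimate-class].
#' @examples
#' m <- new("MSDResult", lagsS = (1:10) * 0.2, msdUm2 = 4 * 0.019 * (1:10) * 0.2,
#'          nPairs = rep(100, 10), nTracks = 10L)
#' estimateD(m)
#' @export
estimateD <- function(msd, fitMaxLagS = 2, DRef = NA_real_) {
  use <- which(msd@lagsS <= fitMaxLagS + 1e-9 & is.finite(msd@msdUm2))
  if (length(use) < 2L) stop("fewer than 2 usable lags in the fit window")
  fit <- stats::lm.fit(cbind(1, msd@lagsS[use]), msd@msdUm2[use])
  slope <- fit$coefficients[2]
  D <- unname(slope) / 4
  new("DiffusionEstimate",
      D = D, interceptUm2 = unname(fit$coefficients[1]),
      fitMaxLagS = fitMaxLagS,
      normalizedPercent = if (is.na(DRef)) NA_real_ else 100 * D / DRef,
      DRef = DRef, nLags = length(use))
}

#' Diffusion-coefficient time series over burst windows
#'
#' Applies [computeMSD()] + [estimateD()] to each burst (or sliding window
#' of `windowBursts` bursts) of a time-stamped stream of tracks, producing
#' the mobility time course on the minutes axis. Windows with no usable
#' tracks are emitted as missing (`NA`), not zero.
#'
#' @param trackSetsByBurst named or unnamed list of [TrackSet-class], one
#'   per burst, in time order.
#' @param burstTimesMin burst start times (minutes).
#' @param windowBursts number of consecutive bursts pooled per estimate.
#' @param fitMaxLagS fit window passed to [estimateD()].
#' @param DRef optional reference coefficient for normalization.
#' @return data.frame with `time_min`, `D_um2_s`, `intercept_um2`,
#'   `normalized_percent`, `n_tracks`.
#' @export
windowedD <- function(trackSetsByBurst, burstTimesMin, windowBursts = 1L,
                      fitMaxLagS = 2, DRef = NA_real_) {
  nB <- length(trackSetsByBurst)
  stopifnot(length(burstTimesMin) == nB, windowBursts >= 1L)
  out <- data.frame(time_min = burstTimesMin,
                    D_um2_s = NA_real_, intercept_um2 = NA_real_,
                    normalized_percent = NA_real_, n_tracks = 0L)
  for (b in seq_len(nB)) {
    lo <- max(1L, b - windowBursts + 1L)
    sets <- trackSetsByBurst[lo:b]
    sets <- Filter(function(s) !is.null(s) && nrow(s@spots) > 0, sets)
    if (!length(sets)) next
    merged <- mergeTrackSets(sets)
    msd <- tryCatch(computeMSD(merged, maxLagS = fitMaxLagS),
                    error = function(e) NULL)
    if (is.null(msd)) next
    est <- tryCatch(estimateD(msd, fitMaxLagS = fitMaxLagS, DRef = DRef),
                    error = function(e) NULL)
    if (is.null(est)) next
    out$D_um2_s[b] <- est@D
    out$intercept_um2[b] <- est@interceptUm2
    out$normalized_percent[b] <- est@normalizedPercent
    out$n_tracks[b] <- msd@nTracks
  }
  out
}

#' Merge track sets, renumbering track ids to stay distinct
#' @keywords internal
#' @noRd
mergeTrackSets <- function(sets) {
  offset <- 0L
  sp <- lapply(sets, function(s) {
    d <- s@spots
    if (nrow(d)) {
      ids <- match(d$track_id, unique(d$track_id))
      d$track_id <- ids + offset
      offset <<- offset + max(ids)
    }
    d
  })
  new("TrackSet", spots = do.call(rbind, sp),
      pixelSizeUm = sets[[1]]@pixelSizeUm,
      frameIntervalS = sets[[1]]@frameIntervalS)
}
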