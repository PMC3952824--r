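#' Background-normalized focus-intensity trace
#'
#' Per frame, the intensities of a horizontal line of `lineLengthPx` pixels
#' centred on the focus are summed and divided by the sum over a same-length
#' line displaced into a background region; the ratio trace is rescaled to
#' 100 percent at the first timepoint. When the default background offset
#' lands on a detected spot (or outside the image), seven further compass
#' offsets are tried; failure to find a clear line is an error. After focus
#' loss the line stays at the last available position, so positions may be
#' carried forward by the caller.
#'
#' Because foci resist photobleaching while the background bleaches rapidly
#' during initial acquisition, the raw ratio of an intact focus rises over
#' early frames.
#'
#' @param stack an [ImageStack-class].
#' @param channel channel name within the stack.
#' @param focusXyPx two-column matrix of per-frame focus positions
#'   (continuous pixel coordinates); rows with `NA` reuse the last
#'   available position.
#' @param lineLengthPx line length in pixels (default `2*4 + 1 = 9`,
#'   matching the detection radius).
#' @param backgroundOffsetPx integer (dx, dy) displacement of the
#'   background line in pixels.
#' @param avoidXyPx optional matrix of detected spot positions per frame
#'   (list indexed by frame) that the background line must not cross.
#' @return An [IntensityTrace-class].
#' @export
intensityRatioTrace <- function(stack, channel, focusXyPx,
                                lineLengthPx = 9L,
                                backgroundOffsetPx = c(15L, 0L),
                                avoidXyPx = NULL) {
  arr <- stack@frames[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  nF <- dim(arr)[3]
  h <- dim(arr)[1]; w <- dim(arr)[2]
  half <- lineLengthPx %/% 2L
  stopifnot(nrow(focusXyPx) == nF)

  # carry last known position forward
  xy <- focusXyPx
  for (f in seq_len(nF)) {
    if (anyNA(xy[f, ])) {
      if (f == 1L) {
        ok <- which(!is.na(focusXyPx[, 1]))
        if (!length(ok)) stop("no focus position available")
        xy[f, ] <- focusXyPx[ok[1], ]
      } else xy[f, ] <- xy[f - 1L, ]
    }
  }

  offsets <- rbind(backgroundOffsetPx,
                   c(-backgroundOffsetPx[1], backgroundOffsetPx[2]),
                   c(0, 15), c(0, -15), c(15, 15), c(-15, 15),
                   c(15, -15), c(-15, -15))
  d <- max(abs(backgroundOffsetPx), 15)
  offsets[3:8, ] <- cbind(c(0, 0, d, -d, d, -d), c(d, -d, d, d, -d, -d))

  lineSum <- function(frame, cx, cy) {
    i <- round(cy + 0.5)            # row containing the centre
    j0 <- round(cx + 0.5)
    jj <- (j0 - half):(j0 + half)
    if (i < 1 || i > h || any(jj < 1) || any(jj > w)) return(NA_real_)
    sum(arr[i, jj, frame])
  }
  clearOf <- function(f, cx, cy) {
    if (is.null(avoidXyPx) || is.null(avoidXyPx[[f]])) return(TRUE)
    sp <- avoidXyPx[[f]]
    if (!nrow(sp)) return(TRUE)
    # the line must not come within the line half-length of any spot
    all(abs(sp[, 2] - cy) > 2 | abs(sp[, 1] - cx) > half + 2)
  }

  ratio <- numeric(nF)
  for (f in seq_len(nF)) {
    fg <- lineSum(f, xy[f, 1], xy[f, 2])
    if (is.na(fg)) stop("focus line falls outside the image at frame ", f)
    bg <- NA_real_
    for (k in seq_len(nrow(offsets))) {
      cx <- xy[f, 1] + offsets[k, 1]
      cy <- xy[f, 2] + offsets[k, 2]
      if (!clearOf(f, cx, cy)) next
      bg <- lineSum(f, cx, cy)
      if (!is.na(bg) && bg > 0) break
    }
    if (is.na(bg) || bg <= 0)
      stop("no spot-free background line found at frame ", f)
    ratio[f] <- fg / bg
  }
  new("IntensityTrace",
      timesMin = stack@timestampsMin,
      ratioPercent = 100 * ratio / ratio[1],
      channel = channel)
}

#' Collapse a per-frame trace to one point per burst
#'
#' Kinetic analyses run on the minutes axis; the within-burst spread
#' (seconds) is negligible, so the per-burst median ratio is timestamped at
#' the burst start.
#'
#' @param trace an [IntensityTrace-class].
#' @param burstIndex per-frame burst index (from the [ImageStack-class]).
#' @return An [IntensityTrace-class] with one point per burst.
#' @export
collapseTraceByBurst <- function(trace, burstIndex) {
  stopifnot(length(burstIndex) == length(trace@timesMin))
  t <- tapply(trace@timesMin, burstIndex, min)
  r <- tapply(trace@ratioPercent, burstIndex, stats::median)
  ord <- order(t)
  r <- as.numeric(r)[ord]; t <- as.numeric(t)[ord]
  new("IntensityTrace", timesMin = t, ratioPercent = 100 * r / r[1],
      channel = trace@channel)
}

#' Call focus loss from an intensity trace or burst presence
#'
#' Intensity method: the trace is smoothed (rolling mean, window 3); the
#' background plateau is taken as the smoothed minimum and the pre-onset
#' level as the median of the first five smoothed points. Loss is called at
#' the first timepoint where the excess ratio (smoothed minus plateau)
#' falls below `thresholdFraction` of the pre-onset excess and stays below
#' for `persistencePoints` consecutive timepoints. Detection-absence
#' method: loss is called at the start of the first run of at least
#' `persistencePoints` spot-free bursts.
#'
#' @param trace an [IntensityTrace-class] (intensity method), or `NULL`.
#' @param presentByBurst logical vector of per-burst spot presence
#'   (detection-absence method), with `burstTimesMin` giving burst times.
#' @param burstTimesMin burst start times for the detection-absence method.
#' @param thresholdFraction fraction of the pre-onset excess below which
#'   the focus counts as lost (default 0.5).
#' @param persistencePoints consecutive qualifying points required
#'   (default 3).
#' @param minDropPercent minimum pre-onset-to-plateau contrast (percentage
#'   points of the normalized ratio) for a trace to be eligible for an
#'   intensity-based loss call; traces that merely fluctuate (uncut cells)
#'   never cross this gate.
#' @param channel channel label for the returned event.
#' @return A [FocusLossEvent-class].
#' @examples
#' tr <- new("IntensityTrace", timesMin = seq(8, 58, by = 5),
#'           ratioPercent = c(100, 104, 98, 101, 30, 28, 30, 29, 31, 30, 29),
#'           channel = "INT1")
#' callFocusLoss(tr)
#' @export
callFocusLoss <- function(trace = NULL, presentByBurst = NULL,
                          burstTimesMin = NULL,
                          thresholdFraction = 0.5, persistencePoints = 3L,
                          minDropPercent = 25,
                          channel = if (!is.null(trace)) trace@channel
                                    else "focus") {
  if (!is.null(trace)) {
    n <- length(trace@ratioPercent)
    if (n < 3L) stop("trace must have at least 3 timepoints")
    if (n < persistencePoints)
      stop("trace shorter than the persistence window")
    sm <- rollMean(trace@ratioPercent, 3L)
    plateau <- min(sm)
    pre <- stats::median(sm[seq_len(min(5L, n))])
    excess <- sm - plateau
    preExcess <- pre - plateau
    idx <- NA_integer_
    if (preExcess >= minDropPercent) {
      below <- excess < thresholdFraction * preExcess
      idx <- firstPersistentRun(below, persistencePoints)
    }
    if (is.na(idx))
      return(new("FocusLossEvent", channel = channel, lost = FALSE,
                 tLossMin = NA_real_, method = "intensity"))
    return(new("FocusLossEvent", channel = channel, lost = TRUE,
               tLossMin = trace@timesMin[idx], method = "intensity"))
  }
  if (is.null(presentByBurst) || is.null(burstTimesMin))
    stop("supply either a trace or presentByBurst with burstTimesMin")
  stopifnot(length(presentByBurst) == length(burstTimesMin))
  idx <- firstPersistentRun(!presentByBurst, persistencePoints)
  if (is.na(idx))
    return(new("FocusLossEvent", channel = channel, lost = FALSE,
               tLossMin = NA_real_, method = "detection-absence"))
  new("FocusLossEvent", channel = channel, lost = TRUE,
      tLossMin = burstTimesMin[idx], method = "detection-absence")
}

#' First index starting a run of at least `k` TRUEs that persists
#' @keywords internal
#' @noRd
firstPersistentRun <- function(flag, k) {
  n <- length(flag)
  if (k < 1L) k <- 1L
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (flag[i]) run + 1L else 0L
    if (run >= k) return(i - k + 1L)
  }
  NA_integer_
}
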