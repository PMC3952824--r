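#' Simulate a 2D chromatin-locus trajectory
#'
#' Generates one sub-pixel position per timestamp under either a single
#' [MotionModel-class] or a [MobilitySchedule-class] of piecewise models.
#' Free mode draws exact Brownian increments (per-axis variance
#' \eqn{2 D \Delta t}); confined mode uses the exact discrete
#' Ornstein-Uhlenbeck update per axis,
#' \deqn{x' = \mu + (x - \mu) e^{-\Delta t/\tau_c} +
#'   \sqrt{D \tau_c (1 - e^{-2\Delta t/\tau_c})}\,\xi,}
#' with \eqn{\xi} standard normal, so arbitrary (strictly increasing)
#' timestamp grids are integrated without discretization error. The OU
#' centre \eqn{\mu} is the position at which the confined segment is
#' entered, so mode switches are continuous.
#'
#' @param model a [MotionModel-class] or [MobilitySchedule-class].
#' @param timestampsMin strictly increasing timestamps in minutes.
#' @param startXyUm numeric length-2 starting position in um.
#' @param seed integer seed; trajectories are reproducible per seed.
#' @return A matrix with columns `x_um`, `y_um`, one row per timestamp.
#' @examples
#' tt <- (0:49) * 0.2 / 60
#' xy <- simulateTrajectory(motionModel("free", 0.019), tt, c(2, 2), seed = 1)
#' head(xy)
#' @export
simulateTrajectory <- function(model, timestampsMin, startXyUm, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible trajectories")
  nt <- length(timestampsMin)
  if (nt < 1L) stop("at least one timestamp required")
  if (nt > 1L && any(diff(timestampsMin) <= 0))
    stop("timestamps must be strictly increasing")
  stopifnot(length(startXyUm) == 2L)

  if (is(model, "MotionModel")) {
    model <- mobilitySchedule(0, list(model))
  } else if (!is(model, "MobilitySchedule")) {
    stop("model must be a MotionModel or MobilitySchedule")
  }
  validObject(model)
  for (m in model@models) validObject(m)

  # active segment per timestamp: last segment started at or before t
  seg <- findInterval(timestampsMin, model@startMin)
  seg[seg == 0L] <- 1L  # timestamps before 0 fall back to the first segment

  out <- matrix(NA_real_, nt, 2, dimnames = list(NULL, c("x_um", "y_um")))
  out[1, ] <- startXyUm
  if (nt == 1L) return(out)

  withSeed(seed, {
    dts <- diff(timestampsMin) * 60  # seconds
    m1 <- model@models[[seg[1]]]
    oneSegment <- length(unique(seg)) == 1L
    if (oneSegment && (m1@mode == "free" || m1@D == 0)) {
      sds <- sqrt(2 * m1@D * dts)
      out[-1, 1] <- startXyUm[1] + cumsum(stats::rnorm(nt - 1, 0, sds))
      out[-1, 2] <- startXyUm[2] + cumsum(stats::rnorm(nt - 1, 0, sds))
    } else if (oneSegment && length(unique(dts)) == 1L) {
      # constant-step OU: vectorized AR(1) recursion per axis,
      # centre = start position
      a <- exp(-dts[1] / m1@tauCS)
      sd <- sqrt(m1@D * m1@tauCS * (1 - exp(-2 * dts[1] / m1@tauCS)))
      for (ax in 1:2) {
        eps <- stats::rnorm(nt - 1, 0, sd)
        dev <- stats::filter(eps, a, method = "recursive", init = 0)
        out[-1, ax] <- startXyUm[ax] + as.numeric(dev)
      }
    } else {
      mu <- startXyUm                # OU anchor, reset on entering confinement
      prevSeg <- seg[1]
      for (i in 2:nt) {
        m <- model@models[[seg[i]]]
        if (seg[i] != prevSeg && m@mode == "confined") mu <- out[i - 1, ]
        prevSeg <- seg[i]
        dt <- dts[i - 1]
        if (m@mode == "free" || m@D == 0) {
          sd <- sqrt(2 * m@D * dt)
          out[i, ] <- out[i - 1, ] + stats::rnorm(2, 0, sd)
        } else {
          a <- exp(-dt / m@tauCS)
          sd <- sqrt(m@D * m@tauCS * (1 - exp(-2 * dt / m@tauCS)))
          out[i, ] <- mu + (out[i - 1, ] - mu) * a + stats::rnorm(2, 0, sd)
        }
      }
    }
  })
  out
}
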