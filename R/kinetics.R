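#' Summarise focus-loss times by Gaussian moments
#'
#' Loss times scatter cell-to-cell (cleavage by the endonuclease is poorly
#' synchronized) and follow an approximately Gaussian distribution; the
#' summary reports the sample mean, sample sd (n - 1 denominator), and the
#' observed range.
#'
#' @param tLossMin numeric vector of loss times in minutes (at least one).
#' @return A [LossTimeDistribution-class].
#' @examples
#' fitLossTimeDistribution(c(25, 27, 26, 31, 28))
#' @export
fitLossTimeDistribution <- function(tLossMin) {
  tLossMin <- tLossMin[!is.na(tLossMin)]
  if (!length(tLossMin)) stop("no loss times supplied")
  new("LossTimeDistribution",
      n = length(tLossMin),
      meanMin = mean(tLossMin),
      sdMin = if (length(tLossMin) > 1L) stats::sd(tLossMin) else 0,
      minMin = min(tLossMin),
      maxMin = max(tLossMin))
}

#' Resection duration from a loss time
#'
#' Duration from the earliest possible cleavage (10 min post-induction) to
#' the loss of the focus, the calculation behind the headline durations:
#' loss at 25 min gives 15 min of resection over INT1 in wild type; loss
#' at 12 min gives 2 min in the Ku-less mutant.
#'
#' @param tLossMin loss time in minutes (may be a vector).
#' @param constants from [kineticsConstants()].
#' @return Duration(s) in minutes.
#' @examples
#' resectionDuration(25)  # 15
#' resectionDuration(12)  # 2
#' @export
resectionDuration <- function(tLossMin, constants = kineticsConstants()) {
  if (any(tLossMin < constants$earliest_cleavage_min, na.rm = TRUE))
    stop("loss earlier than the earliest cleavage time; mis-called loss?")
  tLossMin - constants$earliest_cleavage_min
}

#' Resection speed over a known distance
#'
#' @param distanceNt resected distance in nucleotides.
#' @param durationMin resection duration in minutes (> 0).
#' @return Speed in nt/min.
#' @examples
#' resectionSpeed(1231, 15)  # ~82 nt/min, the wild-type slow phase
#' @export
resectionSpeed <- function(distanceNt, durationMin) {
  if (any(durationMin <= 0, na.rm = TRUE))
    stop("duration must be positive")
  distanceNt / durationMin
}

#' Fast-phase resection speed from the INT1-to-INT2 loss interval
#'
#' Speed of extensive resection over the INT1-distal to INT2-distal span:
#' \deqn{v_{fast} = (d_2 - d_1) / (t_{loss,2} - t_{loss,1}).}
#' With the printed distances a 4-min interval gives
#' (7612 - 1231)/4 = 1595 nt/min, consistent with the > 1200 nt/min bound.
#'
#' @param tLossInt1Min,tLossInt2Min loss times in minutes;
#'   `tLossInt2Min` must be later.
#' @param constants from [kineticsConstants()].
#' @return Speed in nt/min.
#' @examples
#' twoPhaseSpeed(21, 25)  # 4-min interval
#' @export
twoPhaseSpeed <- function(tLossInt1Min, tLossInt2Min,
                          constants = kineticsConstants()) {
  dt <- tLossInt2Min - tLossInt1Min
  if (any(dt <= 0, na.rm = TRUE))
    stop("INT2 loss must be later than INT1 loss")
  (constants$int2_distal_nt - constants$int1_distal_nt) / dt
}

#' Commitment delay between two genotypes
#'
#' Difference of mean loss times over the same cassette, wild type minus
#' mutant: with no commitment lag in the mutant, the difference estimates
#' the time from cleavage to onset of resection (commitment to the
#' homology-directed repair pathway), ~10 min.
#'
#' @param distA wild-type [LossTimeDistribution-class] (or a mean in min).
#' @param distB mutant [LossTimeDistribution-class] (or a mean in min).
#' @return Delay in minutes.
#' @examples
#' commitmentDelay(25, 15)  # 10
#' @export
commitmentDelay <- function(distA, distB) {
  ma <- if (is(distA, "LossTimeDistribution")) distA@meanMin else distA
  mb <- if (is(distB, "LossTimeDistribution")) distB@meanMin else distB
  ma - mb
}

#' Assemble a resection kinetics report across scenarios
#'
#' Per scenario, builds loss-time distributions for INT1 and INT2,
#' earliest-based durations and speeds (anchored at the earliest-cleavage
#' constant, as the headline calculation prescribes) alongside mean-based
#' variants, per-cell fast-phase speeds over cells losing both foci, and
#' the fraction of cells losing each focus. With two or more scenarios the
#' INT1 commitment delay (first scenario minus second) is included.
#'
#' @param eventsByScenario named list; per scenario a data.frame with one
#'   row per cell and columns `lost_int1`, `t_loss_int1_min`, `lost_int2`,
#'   `t_loss_int2_min` (the events table written by [analyzeCohort()], or
#'   truth tables from [sampleEventTimes()] renamed accordingly).
#' @param constants from [kineticsConstants()].
#' @return A [ResectionReport-class].
#' @export
buildReport <- function(eventsByScenario, constants = kineticsConstants()) {
  if (!length(eventsByScenario)) stop("no scenarios supplied")
  scen <- lapply(eventsByScenario, function(ev) {
    out <- list()
    for (ch in c("int1", "int2")) {
      lost <- ev[[paste0("lost_", ch)]]
      tl <- ev[[paste0("t_loss_", ch, "_min")]]
      if (is.null(lost)) lost <- !is.na(tl)
      tl <- tl[which(lost)]
      tl <- tl[!is.na(tl)]
      out[[paste0("fraction_lost_", ch)]] <-
        if (nrow(ev)) sum(lost, na.rm = TRUE) / nrow(ev) else NA_real_
      if (length(tl)) {
        d <- fitLossTimeDistribution(tl)
        dn <- constants[[paste0(ch, "_distal_nt")]]
        durEarliest <- max(d@minMin - constants$earliest_cleavage_min, 0)
        durMean <- max(d@meanMin - constants$earliest_cleavage_min, 0)
        out[[paste0("loss_", ch)]] <- d
        out[[paste0("duration_earliest_", ch, "_min")]] <- durEarliest
        out[[paste0("duration_mean_", ch, "_min")]] <- durMean
        if (ch == "int1") {
          out$speed_earliest_nt_min <-
            if (durEarliest > 0) resectionSpeed(dn, durEarliest) else NA_real_
          out$speed_mean_nt_min <-
            if (durMean > 0) resectionSpeed(dn, durMean) else NA_real_
        }
      }
    }
    both <- which((!is.na(ev$t_loss_int1_min)) & (!is.na(ev$t_loss_int2_min)) &
                  ev$t_loss_int2_min > ev$t_loss_int1_min)
    if (length(both)) {
      v <- twoPhaseSpeed(ev$t_loss_int1_min[both], ev$t_loss_int2_min[both],
                         constants)
      out$fast_speed_nt_min <- mean(v)
      out$fast_speed_n <- length(both)
      out$int1_int2_interval_min <-
        mean(ev$t_loss_int2_min[both] - ev$t_loss_int1_min[both])
    }
    out
  })
  delay <- NA_real_
  haveInt1 <- vapply(scen, function(s) !is.null(s$loss_int1), logical(1))
  if (sum(haveInt1) >= 2L) {
    ij <- which(haveInt1)[1:2]
    delay <- commitmentDelay(scen[[ij[1]]]$loss_int1, scen[[ij[2]]]$loss_int1)
  }
  new("ResectionReport", scenarios = scen, commitmentDelayMin = delay,
      constants = constants)
}

#' Convert a report to a plain list (for JSON serialization)
#'
#' @param report a [ResectionReport-class].
#' @return A nested named list of plain values.
#' @export
reportAsList <- function(report) {
  lossAsList <- function(d) {
    list(n = d@n, mean_min = d@meanMin, sd_min = d@sdMin,
         min_min = d@minMin, max_min = d@maxMin)
  }
  scen <- lapply(report@scenarios, function(s) {
    lapply(s, function(v) {
      if (is(v, "LossTimeDistribution")) lossAsList(v) else v
    })
  })
  list(scenarios = scen,
       commitment_delay_min = report@commitmentDelayMin,
       constants = report@constants)
}

setMethod("show", "ResectionReport", function(object) {
  cat("ResectionReport over", length(object@scenarios), "scenario(s)\n")
  for (nm in names(object@scenarios)) {
    s <- object@scenarios[[nm]]
    cat(sprintf("  %s:\n", nm))
    for (ch in c("int1", "int2")) {
      d <- s[[paste0("loss_", ch)]]
      fl <- s[[paste0("fraction_lost_", ch)]]
      if (!is.null(d)) {
        cat(sprintf("    %s: lost %.0f%%, t_loss %.1f +/- %.1f min [%.1f, %.1f] (n=%d)\n",
                    toupper(ch), 100 * fl, d@meanMin, d@sdMin,
                    d@minMin, d@maxMin, d@n))
      } else {
        cat(sprintf("    %s: lost %.0f%%\n", toupper(ch),
                    100 * (fl %||% 0)))
      }
    }
    if (!is.null(s$speed_earliest_nt_min))
      cat(sprintf("    slow-phase speed: %.1f nt/min (earliest-based), %.1f (mean-based)\n",
                  s$speed_earliest_nt_min, s$speed_mean_nt_min))
    if (!is.null(s$fast_speed_nt_min))
      cat(sprintf("    fast-phase speed: %.0f nt/min (n=%d, interval %.1f min)\n",
                  s$fast_speed_nt_min, s$fast_speed_n,
                  s$int1_int2_interval_min))
  }
  if (!is.na(object@commitmentDelayMin))
    cat(sprintf("  commitment delay (INT1): %.1f min\n",
                object@commitmentDelayMin))
})

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
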