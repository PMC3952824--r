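#' Sample per-cell cleavage and focus-loss times
#'
#' Each cell is cleaved with probability `pCut`. Cleavage times follow a
#' Gaussian truncated at the floor by redrawing. Resection starts after the
#' commitment lag; the focus over cassette k is lost when the resection
#' front reaches its distal end:
#' \deqn{t_{loss,1} = t_{onset} + d_1 / v_{slow}}
#' and, when the fast phase is enabled,
#' \deqn{t_{loss,2} = t_{onset} + s / v_{slow} + (d_2 - s) / v_{fast}}
#' with \eqn{d_k} the distal ends and \eqn{s} the phase-switch position.
#' Without a fast phase the INT2 focus is never lost.
#'
#' @param scenario a [ResectionScenario-class].
#' @param nCells number of cells.
#' @param seed integer seed.
#' @return A data.frame with one row per cell: `cell_id`, `cut`,
#'   `t_cleave_min`, `t_onset_min`, `t_loss_int1_min`, `t_loss_int2_min`
#'   (`NA` where an event does not occur).
#' @examples
#' sampleEventTimes(scenarioPreset("yku70"), nCells = 5, seed = 1)
#' @export
sampleEventTimes <- function(scenario, nCells, seed) {
  validObject(scenario)
  if (nCells < 1L) stop("nCells must be at least 1")
  withSeed(seed, {
    cut <- stats::runif(nCells) < scenario@pCut
    tCleave <- rep(NA_real_, nCells)
    ncut <- sum(cut)
    if (ncut > 0L) {
      draws <- numeric(0)
      while (length(draws) < ncut) {
        d <- stats::rnorm(ncut, scenario@cleavageMeanMin,
                          scenario@cleavageSdMin)
        draws <- c(draws, d[d >= scenario@cleavageMinMin])
      }
      tCleave[cut] <- draws[seq_len(ncut)]
    }
  })
  tOnset <- tCleave + scenario@commitmentLagMin
  tLoss1 <- tOnset + scenario@int1DistalNt / scenario@vSlow
  tLoss2 <- if (scenario@fastPhaseEnabled) {
    tOnset + scenario@phaseSwitchNt / scenario@vSlow +
      (scenario@int2DistalNt - scenario@phaseSwitchNt) / scenario@vFast
  } else {
    rep(NA_real_, nCells)
  }
  data.frame(cell_id = seq_len(nCells), cut = cut,
             t_cleave_min = tCleave, t_onset_min = tOnset,
             t_loss_int1_min = tLoss1, t_loss_int2_min = tLoss2)
}
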