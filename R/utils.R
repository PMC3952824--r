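#' Derive a child seed from a root seed by fixed splitting
#'
#' Deterministic integer stream splitting so that each cell and frame of a
#' simulation has its own reproducible RNG stream. Stays within the 32-bit
#' signed integer range.
#'
#' @param root root seed (integer).
#' @param ... one or more nonnegative integer stream indices.
#' @return An integer seed.
#' @keywords internal
#' @noRd
childSeed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483647
  for (i in idx) {
    # LCG-style mix; 48271 is the MINSTD multiplier
    s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(s)
}

#' Burst start times of an acquisition
#' @param acq AcquisitionParams.
#' @return numeric vector of burst start times in minutes.
#' @keywords internal
#' @noRd
burstStartTimes <- function(acq) {
  seq(acq@burstOriginMin, acq@totalDurationMin, by = acq@burstIntervalMin)
}

#' Per-frame timestamps (minutes) of an acquisition, by burst
#' @return list with `timesMin` (per frame) and `burstIndex` (per frame).
#' @keywords internal
#' @noRd
frameTimestamps <- function(acq) {
  starts <- burstStartTimes(acq)
  offs <- (seq_len(acq@framesPerBurst) - 1L) * acq@frameIntervalS / 60
  list(timesMin = rep(starts, each = acq@framesPerBurst) +
         rep(offs, times = length(starts)),
       burstIndex = rep(seq_along(starts), each = acq@framesPerBurst))
}

#' Evaluate an expression under a local RNG seed, restoring caller state
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Rolling-mean smoothing with shrinking windows at the edges
#' @keywords internal
#' @noRd
rollMean <- function(x, window = 3L) {
  n <- length(x)
  if (n == 0L || window <= 1L) return(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}
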