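#' Fitted diffusion coefficient
#' @param x a [DiffusionEstimate-class].
#' @return numeric, um^2/s.
#' @export
setGeneric("diffusionCoefficient",
           function(x) standardGeneric("diffusionCoefficient"))

#' @rdname diffusionCoefficient
#' @export
setMethod("diffusionCoefficient", "DiffusionEstimate", function(x) x@D)

#' Spot table of a track set
#' @param x a [TrackSet-class].
#' @return data.frame with one row per (track, frame).
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))

#' @rdname spotTable
#' @export
setMethod("spotTable", "TrackSet", function(x) x@spots)

#' MSD values of an MSD result
#' @param x an [MSDResult-class].
#' @return data.frame with `lag_s`, `msd_um2`, `n_pairs`.
#' @export
setGeneric("msdTable", function(x) standardGeneric("msdTable"))

#' @rdname msdTable
#' @export
setMethod("msdTable", "MSDResult", function(x) {
  data.frame(lag_s = x@lagsS, msd_um2 = x@msdUm2, n_pairs = x@nPairs)
})

#' True event table of a simulated cohort
#' @param x a [MovieCohort-class].
#' @return data.frame with one row per cell.
#' @export
setGeneric("trueEvents", function(x) standardGeneric("trueEvents"))

#' @rdname trueEvents
#' @export
setMethod("trueEvents", "MovieCohort", function(x) x@events)
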