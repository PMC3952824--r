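#' Render one synthetic fluorescence frame per channel
#'
#' The expected image is an exponentially bleaching uniform background plus
#' one pixel-integrated 2D Gaussian per focus (so the total flux of a focus
#' equals its amplitude up to border truncation). The observed image adds
#' shot noise, `Poisson(expected)`, and Gaussian read noise, is scaled by
#' the camera gain, rounded, and clipped to the camera bit depth.
#'
#' Coordinates are continuous micrometres with origin at the top-left image
#' corner; pixel `(i, j)` (0-based row/column) spans
#' `[j*px, (j+1)*px) x [i*px, (i+1)*px)`.
#'
#' @param foci named list per channel; each element a data.frame (or NULL)
#'   with columns `x_um`, `y_um`, `amplitude` (expected photons).
#' @param tMin frame time in minutes (drives background bleaching).
#' @param render a [RenderParams-class].
#' @param acq an [AcquisitionParams-class].
#' @param seed integer seed; `NULL` renders the noise-free expectation.
#' @return Named list per channel of H x W numeric matrices (camera counts).
#' @examples
#' acq <- acquisitionParams(imageShape = c(32L, 32L))
#' f <- list(GFP = data.frame(x_um = 1, y_um = 1, amplitude = 2000))
#' img <- renderFrame(f, tMin = 0, renderParams(), acq, seed = 1)$GFP
#' @export
renderFrame <- function(foci, tMin, render, acq, seed = NULL) {
  validObject(render); validObject(acq)
  h <- acq@imageShape[1]; w <- acq@imageShape[2]
  if (h < 1L || w < 1L) stop("zero-size image")
  bg <- render@backgroundPhotons0 * exp(-tMin / render@bleachTauMin)
  out <- vector("list", length(foci))
  names(out) <- names(foci)
  maxval <- 2^acq@bitDepth - 1
  for (ch in seq_along(foci)) {
    expected <- matrix(bg, h, w)
    ff <- foci[[ch]]
    if (!is.null(ff) && nrow(ff)) {
      if (any(!is.finite(ff$amplitude)))
        stop("non-finite focus amplitude")
      for (k in seq_len(nrow(ff))) {
        if (ff$amplitude[k] <= 0) next
        expected <- expected +
          ff$amplitude[k] * psfPixelated(ff$x_um[k], ff$y_um[k], h, w,
                                         acq@pixelSizeUm, render@psfSigmaPx)
      }
    }
    img <- if (is.null(seed)) {
      expected
    } else {
      withSeed(childSeed(seed, ch), {
        matrix(stats::rpois(h * w, expected), h, w) +
          matrix(stats::rnorm(h * w, 0, render@readNoiseSd), h, w)
      })
    }
    img <- round(img * render@cameraGain)
    img[img < 0] <- 0
    img[img > maxval] <- maxval
    out[[ch]] <- img
  }
  out
}

#' Pixel-integrated unit-flux Gaussian PSF
#' @keywords internal
#' @noRd
psfPixelated <- function(xUm, yUm, h, w, pixelSizeUm, sigmaPx) {
  xc <- xUm / pixelSizeUm
  yc <- yUm / pixelSizeUm
  fx <- stats::pnorm(seq_len(w), xc, sigmaPx) -
    stats::pnorm(seq_len(w) - 1, xc, sigmaPx)
  fy <- stats::pnorm(seq_len(h), yc, sigmaPx) -
    stats::pnorm(seq_len(h) - 1, yc, sigmaPx)
  outer(fy, fx)
}
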