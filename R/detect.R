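#' Separable shift-and-add convolution with replicate border padding
#' @keywords internal
#' @noRd
sepFilter1 <- function(img, kernel, along = c("row", "col")) {
  along <- match.arg(along)
  half <- (length(kernel) - 1L) %/% 2L
  n <- if (along == "col") ncol(img) else nrow(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (o in -half:half) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    shifted <- if (along == "col") img[, idx, drop = FALSE]
               else img[idx, , drop = FALSE]
    out <- out + kernel[o + half + 1L] * shifted
  }
  out
}

#' @keywords internal
#' @noRd
sepFilter2 <- function(img, kx, ky = kx) {
  sepFilter1(sepFilter1(img, kx, "col"), ky, "row")
}

#' Square max/min filter via separable shift-and-extremum
#' @keywords internal
#' @noRd
rankFilter2 <- function(img, radius, fun = pmax) {
  half <- as.integer(radius)
  pass <- function(m, along) {
    n <- if (along == "col") ncol(m) else nrow(m)
    out <- m
    for (o in setdiff(-half:half, 0L)) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- if (along == "col") m[, idx, drop = FALSE]
                 else m[idx, , drop = FALSE]
      out <- fun(out, shifted)
    }
    out
  }
  pass(pass(img, "col"), "row")
}

#' Detect fluorescent foci in a single frame
#'
#' The detection pipeline is the classical matched-filter particle
#' detector: (1) local background, estimated by a boxcar mean of width
#' `2*radiusPx + 1`, is subtracted; (2) the background-subtracted image is
#' smoothed with a Gaussian matched filter of sd `radiusPx / 2`; (3) local
#' maxima within `radiusPx` are found; (4) maxima are retained when their
#' filtered intensity lies in the top `percentile` percent of all filtered
#' pixel values and their score (the filtered peak intensity) exceeds
#' `cutoff`; (5) positions are refined to sub-pixel accuracy by the
#' intensity-weighted centroid of the background-subtracted image in a
#' `(2*radiusPx + 1)^2` window.
#'
#' Positions are continuous pixel coordinates: the centre of 0-based pixel
#' column `j` is at `x_px = j + 0.5`, so `x_um = x_px * pixelSizeUm`.
#'
#' @param image numeric matrix (one frame).
#' @param params a [DetectionParams-class].
#' @return data.frame with columns `x_px`, `y_px`, `intensity`, `score`,
#'   sorted by descending score; zero rows when nothing is detected.
#' @examples
#' acq <- acquisitionParams(imageShape = c(32L, 32L))
#' f <- list(ch = data.frame(x_um = 1.04, y_um = 1.3, amplitude = 3000))
#' img <- renderFrame(f, 0, renderParams(readNoiseSd = 0), acq)$ch
#' detectSpots(img, detectionParams())
#' @export
detectSpots <- function(image, params = detectionParams()) {
  validObject(params)
  if (!is.matrix(image) || !nrow(image) || !ncol(image))
    stop("image must be a non-empty numeric matrix")
  if (any(!is.finite(image))) stop("image contains non-finite values")
  r <- params@radiusPx
  if (2L * r + 1L > min(dim(image)))
    stop("detection radius larger than the image")

  boxcar <- rep(1 / (2 * r + 1), 2 * r + 1)
  bg <- sepFilter2(image, boxcar)
  sub <- image - bg

  sigma <- r / 2
  half <- max(1L, ceiling(3 * sigma))
  gk <- stats::dnorm(-half:half, 0, sigma)
  gk <- gk / sum(gk)
  filt <- sepFilter2(sub, gk)

  thr <- stats::quantile(filt, 1 - params@percentile / 100, names = FALSE)
  mx <- rankFilter2(filt, r, pmax)
  mn <- rankFilter2(filt, r, pmin)
  # plateau guard (filt > mn) rejects flat regions such as constant images
  peaks <- which(filt >= mx & filt > mn & filt >= thr &
                 filt > params@cutoff, arr.ind = TRUE)
  if (!nrow(peaks))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), score = numeric(0)))

  # non-maximum suppression: ties on the same plateau (e.g. a focus on a
  # pixel boundary) collapse to one peak within the radius
  vals <- filt[peaks]
  ord <- order(-vals, peaks[, 1], peaks[, 2])
  keep <- integer(0)
  for (k in ord) {
    if (!length(keep) ||
        all((peaks[keep, 1] - peaks[k, 1])^2 +
            (peaks[keep, 2] - peaks[k, 2])^2 > r^2)) {
      keep <- c(keep, k)
    }
  }
  peaks <- peaks[keep, , drop = FALSE]

  h <- nrow(image); w <- ncol(image)
  res <- lapply(seq_len(nrow(peaks)), function(k) {
    i <- peaks[k, 1]; j <- peaks[k, 2]
    ri <- max(1L, i - r):min(h, i + r)
    rj <- max(1L, j - r):min(w, j + r)
    win <- pmax(sub[ri, rj, drop = FALSE], 0)
    tot <- sum(win)
    if (tot <= 0) {
      cx <- j - 0.5; cy <- i - 0.5
    } else {
      cx <- sum(t(win) * (rj - 0.5)) / tot
      cy <- sum(win * (ri - 0.5)) / tot
    }
    c(x_px = cx, y_px = cy, intensity = tot, score = filt[i, j])
  })
  res <- as.data.frame(do.call(rbind, res))
  res[order(-res$score), , drop = FALSE]
}
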