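# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

# Track set built directly from simulated trajectories (bypassing images),
# with optional localization noise, for MSD/diffusion tests.
simTrackSet <- function(model, nTracks, nFrames, dtS = 0.2,
                        pixelSizeUm = 0.065, locNoiseUm = 0, seed = 1) {
  tt <- (seq_len(nFrames) - 1) * dtS / 60
  rows <- lapply(seq_len(nTracks), function(i) {
    xy <- simulateTrajectory(model, tt, c(2, 2), seed = seed * 1000 + i)
    if (locNoiseUm > 0) {
      set.seed(seed * 2000 + i)
      xy <- xy + matrix(rnorm(length(xy), 0, locNoiseUm), ncol = 2)
    }
    data.frame(track_id = i, frame = seq_len(nFrames) - 1L,
               x_px = xy[, 1] / pixelSizeUm, y_px = xy[, 2] / pixelSizeUm)
  })
  new("TrackSet", spots = do.call(rbind, rows),
      pixelSizeUm = pixelSizeUm, frameIntervalS = dtS)
}

# Time-averaged ensemble MSD of raw trajectories (um), independent of the
# package's computeMSD; used as a cross-check oracle.
rawEnsembleMSD <- function(trajList, lags) {
  sapply(lags, function(k) {
    mean(unlist(lapply(trajList, function(xy) {
      n <- nrow(xy)
      if (n <= k) return(NULL)
      (xy[(1 + k):n, 1] - xy[1:(n - k), 1])^2 +
        (xy[(1 + k):n, 2] - xy[1:(n - k), 2])^2
    })))
  })
}

# Brute-force optimal one-frame-pair assignment: maximize number of links
# within maxDisp, then minimize total distance. Oracle for greedy linking.
bruteForceAssign <- function(a, b, maxDisp) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2)
  best <- NULL
  bestScore <- c(-1, Inf)  # (n links, total distance)
  # enumerate injective partial mappings a -> b
  rec <- function(i, used, links, tot) {
    if (i > na) {
      n <- nrow(links)
      if (n > bestScore[1] ||
          (n == bestScore[1] && tot < bestScore[2])) {
        bestScore <<- c(n, tot)
        best <<- links
      }
      return(invisible())
    }
    rec(i + 1L, used, links, tot)  # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && d[i, j] <= maxDisp) {
        used[j] <- TRUE
        rec(i + 1L, used, rbind(links, data.frame(a = i, b = j)),
            tot + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), data.frame(a = integer(0), b = integer(0)), 0)
  best[order(best$a), , drop = FALSE]
}

# Greedy linking reduced to one frame pair, via linkSpots.
greedyAssign <- function(a, b, maxDisp) {
  ts <- linkSpots(list(a, b), detectionParams(maxDisplacementPx = maxDisp))
  sp <- spotTable(ts)
  ids0 <- sp[sp$frame == 0L, ]
  ids1 <- sp[sp$frame == 1L, ]
  linked <- merge(ids0, ids1, by = "track_id")
  if (!nrow(linked)) return(data.frame(a = integer(0), b = integer(0)))
  ai <- match(paste(linked$x_px.x, linked$y_px.x),
              paste(a$x_px, a$y_px))
  bi <- match(paste(linked$x_px.y, linked$y_px.y),
              paste(b$x_px, b$y_px))
  out <- data.frame(a = ai, b = bi)
  out[order(out$a), , drop = FALSE]
}

# Compact acquisition for image tests: small field, short movie.
tinyAcq <- function(...) {
  acquisitionParams(imageShape = c(48L, 48L), ...)
}

quietRender <- function(...) {
  renderParams(...)
}
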