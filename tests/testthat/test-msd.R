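test_that("degenerate tracks give exact closed-form MSDs", {
  # stationary track: MSD identically zero
  sp <- data.frame(track_id = 1L, frame = 0:19, x_px = 10, y_px = 12)
  ts <- new("TrackSet", spots = sp, pixelSizeUm = 0.065, frameIntervalS = 0.2)
  m <- computeMSD(ts, maxLagS = 2)
  expect_true(all(m@msdUm2 == 0))

  # ballistic track: MSD(k dt) = (v k dt)^2
  v <- 0.5  # um/s
  dt <- 0.2
  x <- (0:29) * v * dt / 0.065
  sp <- data.frame(track_id = 1L, frame = 0:29, x_px = x, y_px = 0)
  ts <- new("TrackSet", spots = sp, pixelSizeUm = 0.065, frameIntervalS = dt)
  m <- computeMSD(ts, maxLagS = 2)
  k <- seq_along(m@lagsS)
  expect_equal(m@msdUm2, (v * k * dt)^2, tolerance = 1e-10)
})

test_that("pair counts satisfy the bookkeeping identity", {
  set.seed(3)
  lens <- c(20L, 35L, 50L)
  sp <- do.call(rbind, lapply(seq_along(lens), function(i) {
    data.frame(track_id = i, frame = 0:(lens[i] - 1L),
               x_px = cumsum(rnorm(lens[i])), y_px = cumsum(rnorm(lens[i])))
  }))
  ts <- new("TrackSet", spots = sp, pixelSizeUm = 0.065, frameIntervalS = 0.2)
  kMax <- 10L
  m <- computeMSD(ts, maxLagS = kMax * 0.2)
  expected <- sum(vapply(lens, function(n) {
    sum(pmax(n - seq_len(min(kMax, n - 1L)), 0L))
  }, numeric(1)))
  expect_equal(sum(m@nPairs), expected)
  expect_true(all(diff(m@nPairs) <= 0))
})

test_that("free-diffusion MSD matches 4*D*tau plus the localization offset", {
  D <- 0.019; sloc <- 0.02
  ts <- simTrackSet(motionModel("free", D), nTracks = 100, nFrames = 50,
                    locNoiseUm = sloc, seed = 5)
  m <- computeMSD(ts, maxLagS = 2)
  theo <- 4 * D * m@lagsS + 4 * sloc^2
  expect_true(all(abs(m@msdUm2 / theo - 1) < 0.10))
})

test_that("estimateD inverts exact linear and flat MSD curves", {
  lags <- (1:10) * 0.2
  m <- new("MSDResult", lagsS = lags, msdUm2 = 4 * 0.019 * lags,
           nPairs = rep(100, 10), nTracks = 10L)
  est <- estimateD(m)
  expect_equal(diffusionCoefficient(est), 0.019, tolerance = 1e-12)
  expect_equal(est@interceptUm2, 0, tolerance = 1e-12)

  flat <- new("MSDResult", lagsS = lags, msdUm2 = rep(0.02, 10),
              nPairs = rep(100, 10), nTracks = 10L)
  estF <- estimateD(flat)
  expect_equal(diffusionCoefficient(estF), 0)
  expect_equal(estF@interceptUm2, 0.02)

  # normalization to the uncut reference
  estN <- estimateD(new("MSDResult", lagsS = lags, msdUm2 = 4 * 0.003 * lags,
                        nPairs = rep(100, 10), nTracks = 10L), DRef = 0.019)
  expect_equal(estN@normalizedPercent, 100 * 0.003 / 0.019,
               tolerance = 1e-9)
  expect_equal(estN@normalizedPercent, 15.8, tolerance = 0.01)
})

test_that("estimateD recovers injected D within 15% over replicate seeds", {
  for (D in c(0.003, 0.019)) {
    ests <- vapply(1:20, function(s) {
      ts <- simTrackSet(motionModel("free", D), nTracks = 100, nFrames = 50,
                        locNoiseUm = 0.02, seed = 100 * s)
      diffusionCoefficient(estimateD(computeMSD(ts, maxLagS = 2)))
    }, numeric(1))
    expect_true(all(abs(ests / D - 1) < 0.15))
  }
})

test_that("the fitted intercept absorbs localization noise", {
  sloc <- 0.03
  ints <- vapply(1:20, function(s) {
    ts <- simTrackSet(motionModel("free", 0.019), nTracks = 100,
                      nFrames = 50, locNoiseUm = sloc, seed = 7000 + s)
    estimateD(computeMSD(ts, maxLagS = 2))@interceptUm2
  }, numeric(1))
  expect_lt(abs(mean(ints) / (4 * sloc^2) - 1), 0.30)
})

test_that("windowed D tracks a free-to-confined mobility switch", {
  freeD <- 0.019; confD <- 0.003
  mkBurst <- function(model, seedBase) {
    simTrackSet(model, nTracks = 12, nFrames = 50, seed = seedBase)
  }
  sets <- c(lapply(1:4, function(b) mkBurst(motionModel("free", freeD), b)),
            lapply(5:8, function(b) {
              mkBurst(motionModel("confined", confD, tauCS = 20), b)
            }))
  times <- seq(8, by = 5, length.out = 8)
  dser <- windowedD(sets, times, DRef = freeD)
  expect_equal(dser$time_min, times)
  # free phase: estimates cluster near freeD (CV < 25% at 12 tracks/burst)
  free <- dser$D_um2_s[1:4]
  expect_lt(stats::sd(free) / mean(free), 0.25)
  expect_lt(abs(mean(free) / freeD - 1), 0.25)
  # confined phase: short-time slope ~ confD, so the series drops
  conf <- dser$D_um2_s[5:8]
  expect_lt(mean(conf), 0.5 * mean(free))
  expect_lt(abs(mean(conf) / confD - 1), 0.35)
})

test_that("windows without tracks are emitted as missing", {
  sets <- list(simTrackSet(motionModel("free", 0.019), 5, 30, seed = 2),
               new("TrackSet", spots = data.frame(track_id = integer(0),
                                                  frame = integer(0),
                                                  x_px = numeric(0),
                                                  y_px = numeric(0)),
                   pixelSizeUm = 0.065, frameIntervalS = 0.2))
  dser <- windowedD(sets, c(8, 13))
  expect_false(is.na(dser$D_um2_s[1]))
  expect_true(is.na(dser$D_um2_s[2]))
  expect_false(isTRUE(dser$D_um2_s[2] == 0))
})

test_that("MSD input contracts are enforced", {
  ts <- simTrackSet(motionModel("free", 0.019), 3, 20, seed = 1)
  expect_error(computeMSD(ts, maxLagS = 0.1), "frame interval")
  empty <- new("TrackSet", spots = ts@spots[0, ], pixelSizeUm = 0.065,
               frameIntervalS = 0.2)
  expect_error(computeMSD(empty), "empty")
  m <- computeMSD(ts, maxLagS = 2)
  expect_error(estimateD(m, fitMaxLagS = 0.1), "fewer than 2")
})
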