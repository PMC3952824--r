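# Short movies on small fields keep these tests fast; the biology of the
# presets (cleavage-time law, speeds, lags) is untouched.

test_that("uncut movies keep both foci at full amplitude throughout", {
  acq <- tinyAcq(totalDurationMin = 20, framesPerBurst = 4L)
  coh <- generateMovie(scenarioPreset("uncut"), acq = acq, nCells = 3,
                       seed = 2)
  for (mv in coh@movies) {
    fr <- mv@truth$frames
    expect_true(all(fr$amp_int1 == renderParams()@focusPhotons))
    expect_true(all(fr$amp_int2 == renderParams()@focusPhotons))
    expect_true(all(fr$mode == "free"))
  }
})

test_that("wild-type cells never lose the INT2 focus", {
  acq <- tinyAcq(totalDurationMin = 40, framesPerBurst = 3L)
  coh <- generateMovie(scenarioPreset("wt"), acq = acq, nCells = 6, seed = 4)
  expect_true(all(is.na(coh@events$t_loss_int2_min)))
  for (mv in coh@movies) {
    expect_true(all(mv@truth$frames$amp_int2 > 0))
  }
})

test_that("cut cells extinguish INT1 linearly, reaching zero at t_loss", {
  acq <- tinyAcq(totalDurationMin = 45, framesPerBurst = 3L,
                 burstIntervalMin = 1)
  sc <- scenarioPreset("wt")
  coh <- generateMovie(sc, acq = acq, nCells = 8, seed = 6)
  cut <- which(coh@events$cut)
  expect_gt(length(cut), 0)
  for (i in cut) {
    mv <- coh@movies[[i]]
    fr <- mv@truth$frames
    tl <- coh@events$t_loss_int1_min[i]
    expect_true(all(fr$amp_int1[fr$time_min >= tl] == 0))
    before <- fr$time_min < coh@events$t_onset_min[i] +
      sc@int1ProximalNt / sc@vSlow
    expect_true(all(fr$amp_int1[before] == renderParams()@focusPhotons))
    # linear in time across the cassette
    mid <- fr$time_min > coh@events$t_onset_min[i] +
      sc@int1ProximalNt / sc@vSlow & fr$time_min < tl
    if (sum(mid) >= 3) {
      f <- fr$amp_int1[mid] / renderParams()@focusPhotons
      expected <- (sc@int1DistalNt - (fr$time_min[mid] -
        coh@events$t_onset_min[i]) * sc@vSlow) /
        (sc@int1DistalNt - sc@int1ProximalNt)
      expect_equal(f, expected, tolerance = 1e-9)
    }
  }
})

test_that("mobility switches to confined after cleavage and recovers", {
  acq <- tinyAcq(totalDurationMin = 58, framesPerBurst = 3L,
                 burstIntervalMin = 2)
  sc <- scenarioPreset("wt")
  coh <- generateMovie(sc, acq = acq, nCells = 6, seed = 11)
  cut <- which(coh@events$cut)
  expect_gt(length(cut), 0)
  for (i in cut) {
    fr <- coh@movies[[i]]@truth$frames
    tc <- coh@events$t_cleave_min[i]
    inConf <- fr$time_min >= tc + sc@confinementOnsetLagMin &
      fr$time_min < tc + sc@recoveryTimeMin
    expect_true(all(fr$mode[inConf] == "confined"))
    expect_true(all(fr$mode[!inConf] == "free"))
  }
})

test_that("the cohort cut count falls in the binomial 95% range", {
  acq <- tinyAcq(totalDurationMin = 13, framesPerBurst = 2L)
  coh <- generateMovie(scenarioPreset("wt"), acq = acq, nCells = 20, seed = 1)
  n <- sum(coh@events$cut)
  expect_gte(n, 5)   # qbinom(0.025, 20, 0.6)
  expect_lte(n, 19)  # qbinom(0.975, 20, 0.6)
})

test_that("movies are reproducible cell by cell for a fixed root seed", {
  acq <- tinyAcq(totalDurationMin = 14, framesPerBurst = 3L)
  a <- generateMovie(scenarioPreset("wt"), acq = acq, nCells = 2, seed = 9)
  b <- generateMovie(scenarioPreset("wt"), acq = acq, nCells = 2, seed = 9)
  expect_identical(a@events, b@events)
  expect_identical(a@movies[[2]]@stack@frames, b@movies[[2]]@stack@frames)
  c1 <- generateMovie(scenarioPreset("wt"), acq = acq, nCells = 2, seed = 10)
  expect_false(identical(a@movies[[1]]@stack@frames,
                         c1@movies[[1]]@stack@frames))
})

test_that("stack timestamps follow the burst schedule", {
  acq <- tinyAcq(totalDurationMin = 20, framesPerBurst = 5L,
                 burstIntervalMin = 5, burstOriginMin = 8)
  coh <- generateMovie(scenarioPreset("uncut"), acq = acq, nCells = 1,
                       seed = 1)
  st <- coh@movies[[1]]@stack
  expect_equal(unique(st@burstIndex), 1:3)  # bursts at 8, 13, 18 min
  expect_equal(st@timestampsMin[st@burstIndex == 2][1], 13)
  expect_equal(diff(st@timestampsMin[st@burstIndex == 1]),
               rep(0.2 / 60, 4))
  expect_true(validObject(st))
})
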