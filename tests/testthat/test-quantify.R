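makeTrace <- function(timesMin, ratio) {
  new("IntensityTrace", timesMin = timesMin,
      ratioPercent = 100 * ratio / ratio[1], channel = "INT1")
}

test_that("a uniform image gives a flat 100% ratio trace", {
  acq <- tinyAcq(framesPerBurst = 4L, totalDurationMin = 20)
  h <- acq@imageShape[1]; w <- acq@imageShape[2]
  ts <- frameTimes <- seq(8, 18, by = 5)
  nF <- length(ts) * 4L
  arr <- array(500, c(h, w, nF))
  stack <- new("ImageStack", frames = list(INT1 = arr),
               timestampsMin = seq(0, by = 0.1, length.out = nF) + 8,
               burstIndex = rep(seq_along(ts), each = 4L),
               acquisition = acq)
  xy <- matrix(rep(c(20, 20), each = nF), ncol = 2)
  tr <- intensityRatioTrace(stack, "INT1", xy)
  expect_true(all(tr@ratioPercent == 100))
})

test_that("background bleaching raises the raw ratio of an intact focus", {
  acq <- tinyAcq(framesPerBurst = 2L, totalDurationMin = 40,
                 burstIntervalMin = 4)
  coh <- generateMovie(scenarioPreset("uncut"), acq = acq,
                       render = renderParams(bleachTauMin = 15),
                       nCells = 1, seed = 3, noiseFree = TRUE)
  st <- coh@movies[[1]]@stack
  xy <- as.matrix(coh@movies[[1]]@truth$frames[, c("x_um", "y_um")]) / 0.065
  tr <- collapseTraceByBurst(intensityRatioTrace(st, "INT2", xy),
                             st@burstIndex)
  early <- tr@ratioPercent[tr@timesMin <= 24]
  expect_true(all(diff(early) > 0))
})

test_that("loss calling on constructed traces fires at the step time", {
  t <- seq(8, 58, by = 5)
  # constant trace: never lost
  ev <- callFocusLoss(makeTrace(t, rep(100, length(t))))
  expect_false(ev@lost)
  expect_true(is.na(ev@tLossMin))

  # step at 25 min to a low plateau: called at the step, persistence 3 met
  r <- ifelse(t < 25, 100, 20)
  ev <- callFocusLoss(makeTrace(t, r))
  expect_true(ev@lost)
  expect_equal(ev@tLossMin, 28)  # first burst at/after the step (smoothing
                                 # window 3 straddles the edge one point)
  # with a sharp drop well inside the series, the call is within one burst
  expect_lte(abs(ev@tLossMin - 25), 5)
})

test_that("loss calling is monotone in the threshold fraction", {
  t <- seq(8, 68, by = 5)
  set.seed(1)
  decline <- c(rep(100, 4), seq(95, 20, length.out = 5),
               rep(18, length(t) - 9)) + rnorm(length(t), 0, 1)
  tr <- makeTrace(t, decline)
  ths <- seq(0.2, 0.9, by = 0.1)
  calls <- vapply(ths, function(th) {
    ev <- callFocusLoss(tr, thresholdFraction = th)
    if (ev@lost) ev@tLossMin else Inf
  }, numeric(1))
  expect_true(all(diff(calls) <= 0))  # raising threshold never delays
})

test_that("detection-absence calls loss at the first persistent empty run", {
  t <- seq(8, 48, by = 5)
  present <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  ev <- callFocusLoss(presentByBurst = present, burstTimesMin = t,
                      persistencePoints = 3L)
  expect_true(ev@lost)
  expect_equal(ev@tLossMin, 23)
  # a short gap does not qualify
  ev2 <- callFocusLoss(presentByBurst = c(TRUE, FALSE, FALSE, TRUE, TRUE),
                       burstTimesMin = t[1:5], persistencePoints = 3L)
  expect_false(ev2@lost)
})

test_that("short traces are rejected", {
  expect_error(callFocusLoss(makeTrace(c(1, 2), c(100, 100))), "3 timepoints")
})

test_that("simulated wt focus loss is recovered within one burst interval", {
  # movie long enough that even late losses are followed by the three
  # empty bursts the persistence rule requires
  acq <- tinyAcq(totalDurationMin = 60, framesPerBurst = 20L)
  coh <- generateMovie(scenarioPreset("wt"), acq = acq, nCells = 6, seed = 14)
  an <- analyzeCohort(coh, framesPerBurstUsed = 20L)
  cut <- which(coh@events$cut)
  expect_gt(length(cut), 0)
  called <- an$events$t_loss_int1_min[cut]
  truth <- coh@events$t_loss_int1_min[cut]
  expect_true(all(!is.na(called)))
  expect_true(all(abs(called - truth) <= acq@burstIntervalMin))
  # and the trace declines from its plateau after loss
  i <- cut[1]
  tr <- an$traces[[i]]$INT1
  expect_gt(mean(tr@ratioPercent[tr@timesMin < truth[i] - 10]),
            3 * mean(tr@ratioPercent[tr@timesMin > truth[i] + 5]))
})

test_that("uncut cohorts produce zero loss events", {
  acq <- tinyAcq(totalDurationMin = 68, framesPerBurst = 20L)
  coh <- generateMovie(scenarioPreset("uncut"), acq = acq, nCells = 4,
                       seed = 21)
  an <- analyzeCohort(coh, framesPerBurstUsed = 20L)
  expect_true(all(!an$events$lost_int1))
  expect_true(all(!an$events$lost_int2))
  # the intensity method agrees on the absence of losses
  an2 <- analyzeCohort(coh, framesPerBurstUsed = 20L, method = "intensity")
  expect_true(all(!an2$events$lost_int1))
  expect_true(all(!an2$events$lost_int2))
})
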