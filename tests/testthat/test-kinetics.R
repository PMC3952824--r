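test_that("loss-time summaries reduce to sample moments", {
  d <- fitLossTimeDistribution(25)
  expect_equal(d@n, 1L)
  expect_equal(d@meanMin, 25)
  expect_equal(d@sdMin, 0)
  expect_equal(c(d@minMin, d@maxMin), c(25, 25))
  expect_error(fitLossTimeDistribution(numeric(0)), "no loss times")
})

test_that("loss-time mean matches a truncated-normal integration oracle", {
  m <- 15; s <- 2; floor <- 12
  Z <- 1 - pnorm(floor, m, s)
  oracle <- integrate(function(x) x * dnorm(x, m, s), floor, Inf)$value / Z
  set.seed(2)
  draws <- numeric(0)
  while (length(draws) < 200) {
    x <- rnorm(200, m, s)
    draws <- c(draws, x[x >= floor])
  }
  d <- fitLossTimeDistribution(draws[1:200])
  expect_lt(abs(d@meanMin - oracle), 0.5)
})

test_that("yku-preset loss times fall in the 12-19 min window", {
  ok <- vapply(1:20, function(s) {
    ev <- sampleEventTimes(scenarioPreset("yku70"), 20, seed = s)
    tl <- ev$t_loss_int1_min[!is.na(ev$t_loss_int1_min)]
    length(tl) > 0 && min(tl) >= 12 && max(tl) <= 19
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("resection durations anchor at the earliest cleavage time", {
  expect_equal(resectionDuration(25), 15)
  expect_equal(resectionDuration(12), 2)
  expect_equal(resectionDuration(10), 0)
  expect_error(resectionDuration(9), "earliest cleavage")
})

test_that("speed, duration and distance satisfy the round-trip identity", {
  expect_equal(resectionSpeed(1231, 15), 82.07, tolerance = 1e-4)
  expect_equal(resectionSpeed(1231, 1231), 1)
  expect_equal(resectionSpeed(1231, 4.1), 300.2, tolerance = 1e-3)
  expect_error(resectionSpeed(1231, 0), "positive")
  for (d in c(2, 7.5, 15)) {
    expect_equal(resectionSpeed(1231, d) * d, 1231)
  }
})

test_that("fast-phase speed follows from the INT1-to-INT2 interval", {
  expect_equal(twoPhaseSpeed(21, 25), (7612 - 1231) / 4)
  expect_equal(twoPhaseSpeed(21, 25), 1595.25)
  expect_equal(twoPhaseSpeed(0, 7612 - 1231), 1)
  expect_error(twoPhaseSpeed(25, 25), "later")
  # invariant under a common shift of both loss times
  expect_equal(twoPhaseSpeed(21, 25), twoPhaseSpeed(21 + 7, 25 + 7))
})

test_that("fast-phase recovery from simulated yku-like cohorts", {
  sc <- scenarioPreset("yku70")  # vFast = 1900
  ev <- sampleEventTimes(sc, 200, seed = 31)
  both <- which(!is.na(ev$t_loss_int1_min) & !is.na(ev$t_loss_int2_min))
  v <- twoPhaseSpeed(ev$t_loss_int1_min[both], ev$t_loss_int2_min[both])
  expect_lt(abs(mean(v) / 1900 - 1), 0.10)
})

test_that("commitment delay is the difference of mean loss times", {
  expect_equal(commitmentDelay(25, 15), 10)
  d1 <- fitLossTimeDistribution(c(24, 26, 25))
  expect_equal(commitmentDelay(d1, d1), 0)
  # parameter recovery: scenarios identical except the commitment lag
  lagged <- resectionScenario(commitmentLagMin = 10)
  unlagged <- resectionScenario(commitmentLagMin = 0)
  ok <- vapply(1:20, function(s) {
    a <- sampleEventTimes(lagged, 50, seed = 400 + s)
    b <- sampleEventTimes(unlagged, 50, seed = 800 + s)
    da <- fitLossTimeDistribution(a$t_loss_int1_min)
    db <- fitLossTimeDistribution(b$t_loss_int1_min)
    abs(commitmentDelay(da, db) - 10) <= 1.5
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("buildReport assembles distributions, speeds and fractions", {
  wt <- data.frame(cell_id = 1:5,
                   lost_int1 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   t_loss_int1_min = c(25, 27, 31, NA, NA),
                   lost_int2 = FALSE, t_loss_int2_min = NA_real_)
  rep1 <- buildReport(list(wt = wt))
  s <- rep1@scenarios$wt
  expect_equal(s$fraction_lost_int2, 0)
  expect_equal(s$fraction_lost_int1, 0.6)
  expect_equal(s$loss_int1@minMin, 25)
  expect_equal(s$duration_earliest_int1_min, 15)
  expect_equal(s$speed_earliest_nt_min, 1231 / 15, tolerance = 1e-9)
  expect_true(is.na(rep1@commitmentDelayMin))

  # all losses at 25 min: earliest-based INT1 speed is the canonical 82
  allAt25 <- data.frame(cell_id = 1:4, lost_int1 = TRUE,
                        t_loss_int1_min = 25, lost_int2 = FALSE,
                        t_loss_int2_min = NA_real_)
  r2 <- buildReport(list(wt = allAt25))
  expect_equal(r2@scenarios$wt$speed_earliest_nt_min, 82.07,
               tolerance = 1e-3)

  # two scenarios: delay = first minus second; empty mutant tolerated
  yku <- data.frame(cell_id = 1:4, lost_int1 = TRUE,
                    t_loss_int1_min = c(14, 15, 16, 15),
                    lost_int2 = TRUE, t_loss_int2_min = c(17, 19, 19, 18))
  r3 <- buildReport(list(wt = allAt25, yku70 = yku))
  expect_equal(r3@commitmentDelayMin, 25 - 15)
  expect_equal(r3@scenarios$yku70$fast_speed_nt_min,
               mean((7612 - 1231) / c(3, 4, 3, 3)))

  none <- data.frame(cell_id = 1:3, lost_int1 = FALSE,
                     t_loss_int1_min = NA_real_, lost_int2 = FALSE,
                     t_loss_int2_min = NA_real_)
  r4 <- buildReport(list(wt = allAt25, mutant = none))
  expect_true(is.na(r4@commitmentDelayMin))
  expect_s4_class(r4, "ResectionReport")
  expect_type(reportAsList(r4), "list")
})
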