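test_that("zero diffusion leaves the locus at its start position", {
  tt <- (0:20) * 0.2 / 60
  for (m in list(motionModel("free", 0),
                 motionModel("confined", 0, tauCS = 20))) {
    xy <- simulateTrajectory(m, tt, c(1.5, 2.5), seed = 4)
    expect_true(all(xy[, 1] == 1.5) && all(xy[, 2] == 2.5))
  }
})

test_that("trajectories are reproducible per seed and reject bad input", {
  tt <- (0:10) * 0.2 / 60
  m <- motionModel("free", 0.019)
  expect_identical(simulateTrajectory(m, tt, c(0, 0), seed = 9),
                   simulateTrajectory(m, tt, c(0, 0), seed = 9))
  expect_false(isTRUE(all.equal(
    simulateTrajectory(m, tt, c(0, 0), seed = 9),
    simulateTrajectory(m, tt, c(0, 0), seed = 10))))
  expect_error(simulateTrajectory(m, rev(tt), c(0, 0), seed = 1),
               "increasing")
  expect_error(simulateTrajectory(m, tt, c(0, 0)), "seed")
  expect_error(motionModel("free", -1), "nonnegative")
  expect_error(motionModel("confined", 0.01), "tauCS")
})

test_that("Brownian ensemble MSD matches 4*D*tau within 5% up to 2 s", {
  D <- 0.019; dt <- 0.2
  tt <- (0:2000) * dt / 60
  trajs <- lapply(1:500, function(i) {
    simulateTrajectory(motionModel("free", D), tt, c(0, 0), seed = i)
  })
  lags <- 1:10
  emp <- rawEnsembleMSD(trajs, lags)
  expect_true(all(abs(emp / (4 * D * lags * dt) - 1) < 0.05))
})

test_that("Brownian single-step increments pass a chi-square test", {
  D <- 0.019; dt <- 0.2
  tt <- (0:50) * dt / 60
  ss <- 0
  n <- 0
  for (i in 1:500) {
    xy <- simulateTrajectory(motionModel("free", D), tt, c(0, 0),
                             seed = 100 + i)
    dxy <- diff(xy)
    ss <- ss + sum(dxy^2) / (2 * D * dt)
    n <- n + length(dxy)
  }
  p <- pchisq(ss, df = n)
  expect_gt(p, 0.005)
  expect_lt(p, 0.995)
})

test_that("OU increments have the exact conditional distribution", {
  D <- 0.003; tau <- 20; dt <- 0.2
  tt <- (0:500) * dt / 60
  a <- exp(-dt / tau)
  s2 <- D * tau * (1 - exp(-2 * dt / tau))
  ss <- 0; n <- 0
  for (i in 1:100) {
    xy <- simulateTrajectory(motionModel("confined", D, tauCS = tau),
                             tt, c(0, 0), seed = 300 + i)
    # OU centre is the start position (first confined segment)
    resid <- xy[-1, ] - a * xy[-nrow(xy), ]  # centre at 0 = start
    ss <- ss + sum(resid^2) / s2
    n <- n + length(resid)
  }
  p <- pchisq(ss, df = n)
  expect_gt(p, 0.005)
  expect_lt(p, 0.995)
})

test_that("OU stationary variance and MSD plateau match closed forms", {
  D <- 0.003; tau <- 20; dt <- 1
  nStep <- 2e5
  tt <- (0:nStep) * dt / 60
  xy <- simulateTrajectory(motionModel("confined", D, tauCS = tau),
                           tt, c(0, 0), seed = 11)
  burn <- xy[-(1:1000), ]
  # stationary per-axis variance D*tau within 5%
  expect_lt(abs(mean(c(var(burn[, 1]), var(burn[, 2]))) / (D * tau) - 1),
            0.05)
  # MSD plateau 4*D*tau within 10% at lags >> tau
  lagS <- 200  # 10 tau
  d2 <- (burn[-(1:lagS), 1] - burn[1:(nrow(burn) - lagS), 1])^2 +
        (burn[-(1:lagS), 2] - burn[1:(nrow(burn) - lagS), 2])^2
  expect_lt(abs(mean(d2) / (4 * D * tau) - 1), 0.10)
})

test_that("OU MSD follows 4*D*tau_c*(1 - exp(-tau/tau_c)) at all lags", {
  D <- 0.003; tau <- 20; dt <- 0.2
  nStep <- 4000
  tt <- (0:nStep) * dt / 60
  trajs <- lapply(1:150, function(i) {
    xy <- simulateTrajectory(motionModel("confined", D, tauCS = tau),
                             tt, c(0, 0), seed = 500 + i)
    xy[-(1:500), , drop = FALSE]  # discard 100 s of burn-in
  })
  lags <- c(1, 2, 5, 10, 25, 50, 100, 250, 500)
  emp <- rawEnsembleMSD(trajs, lags)
  theo <- 4 * D * tau * (1 - exp(-lags * dt / tau))
  expect_true(all(abs(emp / theo - 1) < 0.10))
})

test_that("a mobility schedule switches models at the scheduled times", {
  sched <- mobilitySchedule(
    c(0, 10), list(motionModel("free", 0.019), motionModel("free", 0)))
  tt <- seq(0, 20, by = 0.5)
  xy <- simulateTrajectory(sched, tt, c(0, 0), seed = 2)
  after <- which(tt >= 10)
  expect_true(all(xy[after, 1] == xy[after[1], 1]))  # frozen after switch
  expect_gt(stats::var(xy[tt < 10, 1]), 0)
})
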