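# Movement process: closed-form summaries, exact simulation, population
# sampling.

test_that("position autocovariance has the closed-form values and limits", {
  ou <- MovementModel("OU", tauP = "1 day", sigma = 1)
  expect_identical(positionACF(ou, 0), 1)
  expect_equal(positionACF(ou, 86400), exp(-1))

  ouf <- MovementModel("OUF", tauP = 10, tauV = 1, sigma = 2)
  expect_equal(positionACF(ouf, 0), 2)
  expect_lt(positionACF(ouf, 1e6), 1e-12)          # stationarity
  expect_error(positionACF(ouf, -1), "non-negative")

  iid <- MovementModel("IID", sigma = 3)
  expect_equal(positionACF(iid, c(0, 1)), c(3, 0))

  # OU is the tauV -> 0 limit of OUF
  lags <- c(0.5, 1, 5, 20) * 86400
  oufSmall <- MovementModel("OUF", tauP = 86400, tauV = 86.4, sigma = 1)
  ouRef <- MovementModel("OU", tauP = 86400, sigma = 1)
  expect_lt(max(abs(positionACF(oufSmall, lags) / positionACF(ouRef, lags)
                    - 1)), 0.01)

  # repeated-root limit is continuous
  near <- MovementModel("OUF", tauP = 100, tauV = 100 * (1 - 1e-7),
                        sigma = 1)
  at <- MovementModel("OUF", tauP = 100, tauV = 100, sigma = 1)
  expect_equal(positionACF(near, c(10, 100, 500)),
               positionACF(at, c(10, 100, 500)), tolerance = 1e-5)
})

test_that("OUF lag covariance matches a dense multivariate-normal oracle", {
  model <- MovementModel("OUF", tauP = 10, tauV = 1, sigma = 1)
  set.seed(421)
  nSim <- 1e5
  C <- outer(c(0, 1), c(0, 1),
             function(a, b) positionACF(model, abs(a - b)))
  L <- chol(C)
  Z <- matrix(rnorm(2 * nSim), ncol = 2) %*% L
  emp <- mean(Z[, 1] * Z[, 2])
  se <- sd(Z[, 1] * Z[, 2]) / sqrt(nSim)
  expect_lt(abs(emp - positionACF(model, 1)), 3 * se)
})

test_that("velocity variance is the curvature of the ACF at zero", {
  expect_equal(velocityVariance(
    MovementModel("OUF", tauP = 2, tauV = 1, sigma = 2)), 1)
  m <- MovementModel("OUF", tauP = 10 * 86400, tauV = 3600, sigma = 1e6)
  h <- 1e-4 * 3600
  # central second difference at 0, using that the ACF is even in the lag
  num <- -2 * (positionACF(m, h) - positionACF(m, 0)) / h^2
  expect_equal(velocityVariance(m), num, tolerance = 1e-4)
  expect_error(velocityVariance(MovementModel("OU", tauP = 1, sigma = 1)),
               "velocity not defined")
  # continuity into the repeated-root regime
  a <- MovementModel("OUF", tauP = 100, tauV = 100 * (1 - 1e-8), sigma = 1)
  b <- MovementModel("OUF", tauP = 100, tauV = 100, sigma = 1)
  expect_equal(velocityVariance(a), velocityVariance(b), tolerance = 1e-6)
})

test_that("true area is the quantile ellipse, checked by Monte Carlo", {
  m <- MovementModel("OU", tauP = 1, sigma = 1)
  A <- trueArea(m, 0.95)
  expect_equal(A, pi * qchisq(0.95, 2))
  set.seed(7)
  n <- 1e6
  r2 <- rnorm(n)^2 + rnorm(n)^2       # (x^2+y^2)/sigma ~ chisq(2)
  inside <- mean(r2 <= A / pi)        # radius^2 of the ellipse = q * sigma
  se <- sqrt(0.95 * 0.05 / n)
  expect_lt(abs(inside - 0.95), 3 * se)

  m2 <- MovementModel("OU", tauP = 1, sigma = 2)
  expect_equal(trueArea(m2), 2 * A)
  expect_true(trueArea(m, 0.99) > trueArea(m, 0.95))
  expect_error(trueArea(m, 1.2))
})

test_that("true mean speed is the Rayleigh mean of the velocity law", {
  m <- MovementModel("OUF", tauP = 2, tauV = 1, sigma = 2)  # vel var = 1
  expect_equal(trueMeanSpeed(m), sqrt(pi / 2))
  set.seed(11)
  mods <- sqrt(rnorm(1e6)^2 + rnorm(1e6)^2)
  expect_lt(abs(mean(mods) - trueMeanSpeed(m)), 3 * sd(mods) / 1e3)
  m4 <- MovementModel("OUF", tauP = 2, tauV = 1, sigma = 8)
  expect_equal(trueMeanSpeed(m4), 2 * trueMeanSpeed(m))
  expect_error(trueMeanSpeed(MovementModel("OU", tauP = 1, sigma = 1)),
               "not defined")
})

test_that("simulation is deterministic, exact, and matches the dense law", {
  m <- MovementModel("OUF", tauP = "1 day", tauV = "1 hour", sigma = 1e6)
  sch <- SamplingSchedule("2 days", "1 hour")
  a <- simulateTrack(m, sch, seed = 99)
  b <- simulateTrack(m, sch, seed = 99)
  expect_identical(a@x, b@x)
  expect_identical(a@y, b@y)

  # iid limit: OU sampled at dt = 100 tauP
  ou <- MovementModel("OU", tauP = 1, sigma = 4)
  tr <- simulateTrack(ou, SamplingSchedule(1e4 * 100, 100), seed = 12)
  n <- length(tr@times)
  s2 <- mean(c(var(tr@x), var(tr@y)))
  se <- 4 * sqrt(2 / (2 * n))          # chi-square sampling error, 2 axes
  expect_lt(abs(s2 - 4), 3 * se)

  # state-space recursion and dense-covariance draws share one law:
  # Kolmogorov-Smirnov on a fixed linear functional over 200 replicates
  times <- seq(0, 3600 * 12, by = 1800)
  w <- sin(seq_along(times))           # fixed functional
  set.seed(33)
  fDense <- replicate(200, sum(w * denseSimulate(m, times)@x))
  fState <- sapply(1:200, function(i)
    sum(w * simulateTrack(m, SamplingSchedule(3600 * 12, 1800),
                          seed = 5000 + i)@x))
  expect_gt(suppressWarnings(ks.test(fDense, fState))$p.value, 0.01)
  sdTheory <- sqrt(as.numeric(
    t(w) %*% outer(times, times,
                   function(a, b) positionACF(m, abs(a - b))) %*% w))
  expect_lt(abs(sd(fState) / sdTheory - 1), 0.2)

  expect_error(simulateTrack(ou, SamplingSchedule(2e6, 1), seed = 1),
               "coarsen")
})

test_that("replicated simulations reproduce the ACF at fixed lags", {
  for (m in list(MovementModel("OUF", tauP = 7200, tauV = 900, sigma = 1e4),
                 MovementModel("OU", tauP = 7200, sigma = 1e4),
                 MovementModel("IID", sigma = 1e4))) {
    sch <- SamplingSchedule(7200 * 4, 900)
    nRep <- 500
    X <- sapply(1:nRep, function(i)
      simulateTrack(m, sch, seed = 7000 + i)@x)
    for (lagIdx in c(0L, 1L, 5L)) {
      prods <- X[1, ] * X[1 + lagIdx, ]
      target <- positionACF(m, lagIdx * 900)
      se <- sd(prods) / sqrt(nRep)
      expect_lt(abs(mean(prods) - target), 3 * se)
    }
  }
})

test_that("population sampling honors prototype mode and the log-normal law", {
  proto <- PopulationModel("OUF", tauP = "1 day", tauV = "30 min",
                           sigma = 1e6)
  mods <- samplePopulation(proto, 5, seed = 4)
  expect_length(mods, 5)
  expect_true(all(sapply(mods, tauP) == tauP(mods[[1]])))
  expect_equal(tauP(mods[[1]]), 86400)
  expect_identical(attr(mods, "rejections"), 0L)

  het <- PopulationModel("OUF", tauP = "1 day", tauV = "30 min",
                         sigma = 1e6, covLog = c(0.25, 0.25, 0.25))
  big <- samplePopulation(het, 1e4, seed = 8)
  lt <- log(sapply(big, tauP))
  expect_lt(abs(mean(lt) - log(86400)), 3 * 0.5 / sqrt(1e4))

  one <- samplePopulation(het, 1, seed = 3)
  two <- samplePopulation(het, 1, seed = 3)
  expect_identical(one[[1]]@tauP, two[[1]]@tauP)
  # sub-seeding: individual i is reproducible within a larger draw
  ten <- samplePopulation(het, 10, seed = 3)
  expect_identical(ten[[1]]@tauP, one[[1]]@tauP)
})

test_that("model and schedule validity is enforced", {
  expect_error(MovementModel("OUF", tauP = 1, tauV = 2, sigma = 1),
               "tauP >= tauV")
  expect_error(MovementModel("OU", tauP = -1, sigma = 1), "tauP > 0")
  expect_error(MovementModel("OU", tauP = 1, sigma = 0), "sigma")
  expect_error(SamplingSchedule("1 hour", "2 hours"), "interval")
  expect_equal(length(scheduleTimes(SamplingSchedule("10 days", "1 day"))),
               11L)
  expect_equal(asSeconds("2 months"), 2 * 30.4375 * 86400)
  expect_equal(asSeconds("1 year"), 365.25 * 86400)
  expect_error(asSeconds("three days"), "cannot parse")
})
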