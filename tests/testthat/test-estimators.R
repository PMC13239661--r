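# Individual-level estimators: areas and speeds.

# a FitResult with prescribed estimates and information, for plug-in tests
injectFit <- function(model, Narea, n = ceiling(Narea) + 10L, Nspeed = 0) {
  pn <- c("tauP", "tauV", "sigma")
  vcov <- matrix(NA_real_, 3, 3, dimnames = list(pn, pn))
  vcov["sigma", "sigma"] <- 1 / Narea
  new("FitResult", selectedKind = model@kind, model = model,
      ciLog = matrix(NA_real_, 3, 2, dimnames = list(pn, c("low", "high"))),
      vcovLog = vcov, loglik = 0, aicc = c(OUF = 0), dofArea = Narea,
      dofSpeed = Nspeed, n = as.integer(n), errVar = 0)
}

test_that("Gaussian area is the exact plug-in ellipse area", {
  m <- MovementModel("OU", tauP = 86400, sigma = 1e6)
  fit <- injectFit(m, Narea = 50)
  est <- gaussianArea(fit)
  expect_identical(est@value, trueArea(m))
  expect_true(est@ciLow <= est@value && est@value <= est@ciHigh)
  # CI width vanishes as the DOF grows
  wide <- gaussianArea(injectFit(m, Narea = 10))
  tight <- gaussianArea(injectFit(m, Narea = 1e6))
  expect_lt(tight@ciHigh / tight@ciLow, wide@ciHigh / wide@ciLow)
  expect_lt(tight@ciHigh / tight@ciLow, 1.01)
})

test_that("AKDE area converges under grid refinement", {
  m <- MovementModel("OUF", tauP = "1 day", tauV = "1 hour", sigma = 1e6)
  trk <- simulateTrack(m, SamplingSchedule("16 days", "1 hour"), seed = 31)
  fit <- suppressWarnings(fitTrack(trk, candidates = "OUF"))
  a1 <- akdeArea(trk, fit, gridSize = 151L)
  a2 <- akdeArea(trk, fit, gridSize = 301L)
  expect_lt(abs(a2@value / a1@value - 1), 0.01)
})

test_that("AKDE and Gaussian areas agree at high effective sample size", {
  m <- MovementModel("OUF", tauP = "1 day", tauV = "2 hours", sigma = 1e6)
  sch <- SamplingSchedule("64 days", "2 hours")
  rel <- sapply(1:10, function(i) {
    trk <- simulateTrack(m, sch, seed = 4100 + i)
    fit <- suppressWarnings(fitTrack(trk, candidates = "OUF"))
    akdeArea(trk, fit)@value / gaussianArea(fit)@value
  })
  expect_lt(abs(mean(rel) - 1), 0.10)
})

test_that("chi-square area CIs are calibrated near Narea = 20", {
  m <- MovementModel("OU", tauP = 86400, sigma = 1e6)
  truth <- trueArea(m)
  sch <- SamplingSchedule(20 * 86400, 86400 / 4)
  cover <- sapply(1:300, function(i) {
    trk <- simulateTrack(m, sch, seed = 5200 + i)
    fit <- suppressWarnings(fitTrack(trk, candidates = "OU"))
    est <- akdeArea(trk, fit)
    est@ciLow <= truth && truth <= est@ciHigh
  })
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})

test_that("speed estimation fails informatively without correlated velocity", {
  m <- MovementModel("OU", tauP = 86400, sigma = 1e6)
  trk <- simulateTrack(m, SamplingSchedule("10 days", "6 hours"), seed = 3)
  fit <- suppressWarnings(fitTrack(trk, candidates = c("IID", "OU")))
  est <- ctsdSpeed(trk, fit)
  expect_true(est@failed)
  expect_match(est@reason, "too coarse")
})

test_that("conditional-simulation speed is consistent at fine sampling", {
  m <- MovementModel("OUF", tauP = "1 day", tauV = "3 hours", sigma = 1e6)
  truth <- trueMeanSpeed(m)
  sch <- SamplingSchedule("20 days", asSeconds("3 hours") / 8)
  re <- sapply(1:12, function(i) {
    trk <- simulateTrack(m, sch, seed = 6100 + i)
    fit <- suppressWarnings(fitTrack(trk, candidates = "OUF"))
    relativeError(ctsdSpeed(trk, fit, nDraws = 100, seed = i)@value, truth)
  })
  expect_lt(abs(mean(re)), 6)
  # deterministic given the seed
  trk <- simulateTrack(m, sch, seed = 6200)
  fit <- suppressWarnings(fitTrack(trk, candidates = "OUF"))
  expect_identical(ctsdSpeed(trk, fit, seed = 9)@value,
                   ctsdSpeed(trk, fit, seed = 9)@value)
})

test_that("speed bias is negative near the detectability boundary", {
  m <- MovementModel("OUF", tauP = "1 day", tauV = "3 hours", sigma = 1e6)
  truth <- trueMeanSpeed(m)
  sch <- SamplingSchedule("30 days", asSeconds("3 hours") * 3)
  re <- sapply(1:30, function(i) {
    trk <- simulateTrack(m, sch, seed = 6500 + i)
    fit <- suppressWarnings(fitTrack(trk, candidates = c("OU", "OUF")))
    est <- ctsdSpeed(trk, fit, nDraws = 60, seed = i)
    if (est@failed) NA else relativeError(est@value, truth)
  })
  expect_lt(mean(re, na.rm = TRUE), 0)
})

test_that("straight-line displacement speed behaves as documented", {
  expect_equal(sldSpeed(Track("a", c(0, 100), c(0, 100), c(0, 0))), 1)
  # noiseless straight-line motion at 2 m/s
  expect_equal(sldSpeed(Track("b", 0:10, 2 * (0:10), rep(0, 11))), 2)
  # stationary animal + iid error of RMS r per axis:
  # per-step displacement has mean sqrt(pi) * r
  set.seed(8)
  r <- 5
  n <- 20001
  trk <- Track("c", 0:(n - 1), rnorm(n, 0, r), rnorm(n, 0, r))
  d <- sqrt(diff(trk@x)^2 + diff(trk@y)^2)
  expect_lt(abs(sldSpeed(trk) - sqrt(pi) * r),
            3 * sd(d) / sqrt(n - 1))
  expect_error(sldSpeed(Track("d", 1, 0, 0)), "at least 2")
})

test_that("estimates serialize to JSON rows and back", {
  pool <- list(mkEstimate(12, 30, id = "a"),
               failedEstimate("area", "no usable data", "b"))
  path <- tempfile(fileext = ".json")
  estimatesToJSON(pool, path)
  back <- estimatesFromJSON(path)
  expect_length(back, 2)
  expect_equal(back[[1]]@value, 12)
  expect_true(back[[2]]@failed)
  expect_identical(back[[2]]@individual, "b")
})
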