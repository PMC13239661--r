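# Design evaluation: corruption, relative errors, the outer loop,
# resampling and leave-one-out sensitivity.

test_that("corruption applies hazards in causal order", {
  m <- MovementModel("OUF", tauP = 7200, tauV = 600, sigma = 1e4)
  trk <- simulateTrack(m, SamplingSchedule(600 * 9999, 600), seed = 71)

  # identity when nothing is corrupted
  same <- corruptTrack(trk, CorruptionSpec(), seed = 1)
  expect_identical(same@x, trk@x)
  expect_identical(same@times, trk@times)

  # storage cap keeps exactly the earliest fixes
  capped <- corruptTrack(trk, CorruptionSpec(storageCap = 100), seed = 1)
  expect_length(capped@times, 100)
  expect_identical(capped@x, trk@x[1:100])

  # Bernoulli thinning retains about p * n fixes
  thinned <- corruptTrack(trk, CorruptionSpec(fixSuccess = 0.5), seed = 2)
  n <- length(trk@times)
  expect_lt(abs(length(thinned@times) - 0.5 * n),
            3 * sqrt(n * 0.25))

  # location error is added and recorded
  noisy <- corruptTrack(trk, CorruptionSpec(errorRMS = 25), seed = 3)
  expect_identical(unique(noisy@errorSD), 25)
  rmse <- sd(noisy@x - trk@x)
  expect_lt(abs(rmse / 25 - 1), 0.05)

  # premature failure truncates at an exponential time
  dead <- corruptTrack(trk, CorruptionSpec(failureHazard = 1 / 6000),
                       seed = 4)
  expect_lt(length(dead@times), n)
  expect_identical(dead@x, trk@x[seq_along(dead@times)])

  # determinism
  a <- corruptTrack(trk, CorruptionSpec(fixSuccess = 0.7, errorRMS = 10),
                    seed = 5)
  b <- corruptTrack(trk, CorruptionSpec(fixSuccess = 0.7, errorRMS = 10),
                    seed = 5)
  expect_identical(a@x, b@x)
})

test_that("relative error follows the sign convention", {
  expect_identical(relativeError(1, 1), 0)
  expect_identical(relativeError(0.75, 1), -25)
  expect_equal(relativeError(1.014, 1), 1.4)
  expect_equal(relativeError(c(2, 0.5), 1), c(100, -50))
  expect_error(relativeError(1, 0), "positive")
})

test_that("resampling enumerates or caps combinations without duplicates", {
  pool5 <- lapply(1:5, function(i) mkEstimate(10 + i, 30))
  rc <- resampleCombinations(pool5, 2)
  expect_identical(nrow(rc), 10L)            # C(5,2) = 10, all enumerated
  combos <- attr(rc, "combos")
  expect_identical(nrow(unique(t(combos))), 10L)

  pool50 <- lapply(1:50, function(i) mkEstimate(9 + (i %% 7), 30))
  rc2 <- resampleCombinations(pool50, 25, maxCombos = 250, seed = 3)
  expect_identical(nrow(rc2), 250L)          # capped at 250
  combos2 <- attr(rc2, "combos")
  expect_identical(nrow(unique(t(combos2))), 250L)

  # m = |pool|: the single full-pool combination
  rcAll <- resampleCombinations(pool5, 5)
  expect_identical(nrow(rcAll), 1L)
  expect_equal(rcAll$mean[1], popMean(pool5)@mean)
  expect_error(resampleCombinations(pool5, 1))
})

test_that("leave-one-out correctness reproduces direct enumeration", {
  set.seed(72)
  pool <- lapply(1:10, function(i)
    mkEstimate(exp(rnorm(1, log(10), 0.25)), runif(1, 20, 60)))
  looMeans <- sapply(1:10, function(i) popMean(pool[-i])@mean)

  # truth chosen so that all leave-one-out estimates fall inside
  expect_equal(looCorrectness(pool, mean(looMeans), threshold = 50), 100,
               ignore_attr = TRUE)
  # truth scaled so none fall inside
  expect_equal(looCorrectness(pool, mean(looMeans) * 10), 0,
               ignore_attr = TRUE)
  # truth placed so that exactly 2 of the 10 fall outside +-5%
  re <- sort(abs(relativeError(looMeans, mean(looMeans))))
  # pick a truth for which the 2 most extreme deviations exceed the
  # threshold: shift until exactly 8 lie within
  ord <- looMeans[order(abs(looMeans - median(looMeans)))]
  target <- ord[1]
  thr <- 5
  within <- function(tr) sum(abs(relativeError(looMeans, tr)) <= thr)
  candidates <- seq(min(looMeans) / 1.06, max(looMeans) * 1.06,
                    length.out = 20001)
  hit <- candidates[vapply(candidates, within, numeric(1)) == 8][1]
  expect_false(is.na(hit))
  expect_equal(looCorrectness(pool, hit), 80, ignore_attr = TRUE)
  expect_error(looCorrectness(pool[1:2], 10), "n >= 3")
})

test_that("design evaluation is deterministic and internally consistent", {
  pop <- PopulationModel("OUF", tauP = "1 day", tauV = "2 hours",
                         sigma = 1e6)
  des <- DesignSpec(SamplingSchedule("16 days", "2 hours"), m = 4,
                    replicates = 2, seed = 41,
                    targets = c("area", "speed"))
  r1 <- evaluateDesign(pop, des)
  r2 <- evaluateDesign(pop, des)
  expect_identical(r1@detail, r2@detail)
  expect_identical(r1@summary, r2@summary)

  # verdicts recomputable from the stored relative errors
  for (tg in c("area", "speed")) {
    s <- r1@summary[r1@summary$target == tg, ]
    d <- r1@detail[r1@detail$target == tg & is.finite(r1@detail$re), ]
    expect_equal(s$meanRE, mean(d$re))
    expectedPass <- abs(s$meanRE) <= r1@threshold &&
      abs(s$ciLowRE) <= r1@threshold && abs(s$ciHighRE) <= r1@threshold
    expect_identical(s$pass, expectedPass)
  }
  # closed-form truths recorded
  expect_equal(unname(r1@truth["area"]), trueArea(pop))
  expect_equal(unname(r1@truth["speed"]), trueMeanSpeed(pop))
})

test_that("corrupted deployments are counted, not imputed", {
  pop <- PopulationModel("OUF", tauP = "1 day", tauV = "2 hours",
                         sigma = 1e6)
  # brutal hazard: most deployments die almost immediately
  des <- DesignSpec(SamplingSchedule("8 days", "2 hours"), m = 3,
                    corruption = CorruptionSpec(failureHazard = 1 / 3600),
                    replicates = 2, seed = 42, targets = "area")
  rep <- evaluateDesign(pop, des)
  expect_true(all(rep@detail$failedFraction > 0))
  expect_true(all(rep@detail$failedFraction <= 1))
})

test_that("design and corruption specs validate their inputs", {
  expect_error(CorruptionSpec(fixSuccess = 0), "fixSuccess")
  expect_error(CorruptionSpec(storageCap = 1), "storageCap")
  expect_error(DesignSpec(SamplingSchedule(10, 1), m = 1), "m must be")
  expect_error(DesignSpec(SamplingSchedule(10, 1), m = 5,
                          targets = "distance"), "targets")
  sp <- DesignSpec("2 days", m = 4, interval = "1 hour")
  expect_s4_class(sp@schedule, "SamplingSchedule")
  expect_identical(sp@schedule@interval, 3600)
})

test_that("design reports serialize to JSON and tidy CSV", {
  pop <- PopulationModel("OU", tauP = "1 day", sigma = 1e6)
  des <- DesignSpec(SamplingSchedule("12 days", "6 hours"), m = 3,
                    replicates = 2, seed = 43, targets = "area")
  rep <- evaluateDesign(pop, des)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  reportToJSON(rep, jp, cp)
  js <- jsonlite::fromJSON(jp)
  expect_equal(js$threshold, 5)
  expect_equal(nrow(js$detail), nrow(rep@detail))
  expect_equal(nrow(read.csv(cp)), nrow(rep@detail))
})
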