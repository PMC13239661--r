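# Population-level inference.

test_that("log-chi-square bias has its analytic values and properties", {
  # nu = 2: psi(1) - log(1) = -Euler-Mascheroni
  expect_equal(logChi2Bias(2), digamma(1), tolerance = 1e-12)
  set.seed(61)
  mc <- mean(log(rchisq(2e6, 2) / 2))
  expect_lt(abs(mc - logChi2Bias(2)), 4 * sqrt(trigamma(1) / 2e6))
  expect_lt(abs(logChi2Bias(1e6)), 1e-5)
  nus <- c(1, 2, 5, 20, 100)
  expect_true(all(diff(logChi2Bias(nus)) > 0))
  expect_true(all(logChi2Bias(nus) < 0))
  expect_error(logChi2Bias(0), "positive")
})

test_that("degenerate pools collapse to the common value", {
  pool <- replicate(6, mkEstimate(42, 1e8), simplify = FALSE)
  pe <- popMean(pool)
  expect_equal(pe@mean, 42, tolerance = 1e-5)
  expect_equal(pe@betweenVarLog, 0, tolerance = 1e-8)
})

test_that("equal within-variances reduce to the unweighted log-scale mean", {
  set.seed(62)
  vals <- exp(rnorm(12, log(20), 0.4))
  pool <- lapply(vals, mkEstimate, dof = 10)
  pe <- popMean(pool)
  yBar <- mean(log(vals) - logChi2Bias(10))
  expect_equal(pe@logMean, yBar, tolerance = 1e-8)
})

test_that("uncertain estimates are downweighted", {
  set.seed(63)
  vals <- exp(rnorm(10, log(20), 0.3))
  dofs <- c(4, rep(40, 8), 400)
  mk <- function(v) lapply(seq_along(v), function(i) mkEstimate(v[i], dofs[i]))
  base <- popMean(mk(vals))@logMean
  eps <- 0.05
  bumpNoisy <- vals; bumpNoisy[1] <- vals[1] * exp(eps)       # dof 4
  bumpPrecise <- vals; bumpPrecise[10] <- vals[10] * exp(eps) # dof 400
  dNoisy <- popMean(mk(bumpNoisy))@logMean - base
  dPrecise <- popMean(mk(bumpPrecise))@logMean - base
  expect_gt(dPrecise, dNoisy)
})

test_that("outputs are invariant under permuting individuals", {
  set.seed(64)
  pool <- lapply(1:9, function(i)
    mkEstimate(exp(rnorm(1, 3, 0.5)), runif(1, 5, 80)))
  a <- popMean(pool)
  b <- popMean(pool[c(5, 1, 9, 3, 7, 2, 8, 4, 6)])
  expect_identical(a@mean, b@mean)
  expect_identical(a@ciLow, b@ciLow)
  expect_identical(a@betweenVarLog, b@betweenVarLog)
})

test_that("a single individual keeps its own chi-square interval", {
  e <- mkEstimate(15, 20)
  pe <- popMean(list(e))
  expect_equal(pe@mean, 15)
  expect_equal(pe@ciLow, e@ciLow)
  expect_match(pe@note, "no between-individual")
  expect_error(popMean(list(failedEstimate("area", "x"))), "no usable")
})

test_that("the hierarchical estimator recovers a log-normal population", {
  set.seed(65)
  truth <- exp(log(10) + 0.25 / 2)
  res <- t(sapply(1:60, function(r) {
    pool <- lapply(1:50, function(i) {
      A <- exp(rnorm(1, log(10), 0.5))
      nu <- runif(1, 10, 100)
      mkEstimate(A * rchisq(1, nu) / nu, nu)
    })
    pe <- popMean(pool)
    c(re = relativeError(pe@mean, truth),
      cover = pe@ciLow <= truth && truth <= pe@ciHigh)
  }))
  expect_lt(abs(mean(res[, "re"])), 5)
  expect_gte(mean(res[, "cover"]), 0.85)
})

test_that("the log-chi-square correction removes most of the log-mean bias", {
  set.seed(66)
  nu <- 6
  truth <- exp(log(10) + 0.01 / 2)
  res <- t(sapply(1:120, function(r) {
    A <- exp(rnorm(50, log(10), 0.1))
    x <- A * rchisq(50, nu) / nu
    raw <- exp(mean(log(x)))   # naive log-scale mean, back-transformed
    pool <- lapply(x, mkEstimate, dof = nu)
    c(raw = raw, corrected = popMean(pool)@mean)
  }))
  rawBias <- mean(res[, "raw"]) - truth
  corrBias <- mean(res[, "corrected"]) - truth
  expect_lt(rawBias, 0)
  expect_lt(abs(corrBias), 0.5 * abs(rawBias))
})

test_that("the inverse-Gaussian population model agrees and recovers", {
  # near-zero between-individual variance: matches the normal-normal fit
  set.seed(67)
  pool <- lapply(1:50, function(i) {
    nu <- runif(1, 40, 80)
    mkEstimate(10 * rchisq(1, nu) / nu, nu)
  })
  expect_lt(abs(popMeanIG(pool)@mean / popMean(pool)@mean - 1), 0.02)

  # an actual inverse-Gaussian population, tight sampling kernels
  rinvgauss <- function(n, mu, lambda) {
    # Michael-Schucany-Haas
    y <- rnorm(n)^2
    x <- mu + mu^2 * y / (2 * lambda) -
      mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
    ifelse(runif(n) <= mu / (mu + x), x, mu^2 / x)
  }
  re <- sapply(1:10, function(r) {
    A <- rinvgauss(100, 10, 80)
    pool <- lapply(A, function(a) mkEstimate(a * rchisq(1, 400) / 400, 400))
    relativeError(popMeanIG(pool)@mean, 10)
  })
  expect_lt(abs(mean(re)), 5)

  # tiny pools do not crash and give wide intervals
  tiny <- popMeanIG(list(mkEstimate(8, 10), mkEstimate(12, 10)))
  expect_s4_class(tiny, "PopulationEstimate")
  expect_gt(tiny@ciHigh / tiny@ciLow, 1.1)
})

test_that("population-averaged models pool fits parameter by parameter", {
  pn <- c("tauP", "tauV", "sigma")
  mkFit <- function(model, nu) {
    vcov <- diag(2 / nu, 3)
    dimnames(vcov) <- list(pn, pn)
    new("FitResult", selectedKind = model@kind, model = model,
        ciLog = matrix(NA_real_, 3, 2,
                       dimnames = list(pn, c("low", "high"))),
        vcovLog = vcov, loglik = 0, aicc = c(OUF = 0), dofArea = nu / 2,
        dofSpeed = if (model@kind == "OUF") nu / 2 else 0,
        n = 100000L, errVar = 0)
  }
  # homogeneous population, precise fits: between-variance collapses
  set.seed(68)
  nu <- 4000
  fits <- lapply(1:12, function(i) {
    noise <- rchisq(3, nu) / nu
    mkFit(MovementModel("OUF", tauP = 86400 * noise[1],
                        tauV = 1800 * noise[2],
                        sigma = 1e6 * noise[3]), nu)
  })
  pa <- popAverageModel(fits)
  expect_s4_class(pa, "PopulationModel")
  expect_true(all(diag(pa@covLog) < 0.01))
  expect_lt(abs(pa@meanLog[["tauP"]] - log(86400)), 0.1)

  # known heterogeneity is recovered within 50%
  vTrue <- 0.25
  recov <- sapply(1:20, function(r) {
    fits <- lapply(1:50, function(i) {
      lp <- rnorm(3, c(log(86400), log(1800), log(1e6)), sqrt(vTrue))
      noise <- rchisq(3, 40) / 40
      mkFit(MovementModel("OUF", tauP = exp(lp[1]) * noise[1],
                          tauV = min(exp(lp[2]) * noise[2],
                                     exp(lp[1]) * noise[1] * 0.99),
                          sigma = exp(lp[3]) * noise[3]), 40)
    })
    popAverageModel(fits)@covLog["sigma", "sigma"]
  })
  expect_lt(abs(mean(recov) / vTrue - 1), 0.5)

  # mixed kinds: majority-complex kind used, others excluded with warning
  fitsMixed <- c(fits[1:5],
                 list(mkFit(MovementModel("OU", tauP = 86400, sigma = 1e6),
                            400)))
  expect_warning(pam <- popAverageModel(fitsMixed), "excluded")
  expect_identical(pam@kind, "OUF")
  expect_warning(popAverageModel(fits[1:2]), "low confidence")
})
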