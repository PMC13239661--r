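# Independent oracles used across the suite.  These deliberately avoid the
# package's state-space code paths: Gaussian densities and draws are built
# from the dense covariance matrix implied by the autocovariance function.

# dense multivariate-normal log-likelihood of a track under a model
denseLogLik <- function(track, model, errVar = 0) {
  t <- track@times
  C <- outer(t, t, function(a, b) positionACF(model, abs(a - b)))
  diag(C) <- diag(C) + errVar
  L <- chol(C)
  ll1 <- function(z, mu) {
    r <- backsolve(L, z - mu, transpose = TRUE)
    -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
  }
  ll1(track@x, model@center[1]) + ll1(track@y, model@center[2])
}

# exact draw of the process at given times from the dense covariance
denseSimulate <- function(model, times) {
  C <- outer(times, times, function(a, b) positionACF(model, abs(a - b)))
  L <- chol(C)
  x <- as.numeric(crossprod(L, rnorm(length(times)))) + model@center[1]
  y <- as.numeric(crossprod(L, rnorm(length(times)))) + model@center[2]
  Track(id = "dense", times = times, x = x, y = y)
}

# a ScalarEstimate with the chi-square CI implied by (value, dof)
mkEstimate <- function(value, dof, kind = "area", id = "") {
  ci <- chisqCI(value, dof)
  ScalarEstimate(kind, value, dof, ci[["low"]], ci[["high"]],
                 individual = id)
}

# random OUF model with log-uniform scales, for oracle sweeps
randomOUF <- function() {
  tauV <- exp(runif(1, log(600), log(36000)))
  tauP <- tauV * exp(runif(1, log(4), log(50)))
  MovementModel("OUF", tauP = tauP, tauV = tauV,
                sigma = exp(runif(1, log(1e4), log(1e7))),
                center = rnorm(2, 0, 1000))
}
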