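# Population-level inference: log-chi-square bias correction, the
# normal-normal hierarchical mean with downweighting, the inverse-Gaussian
# alternative, and the population-averaged movement model.

#' Log-chi-square bias
#'
#' The expectation `E[log(chisq_nu / nu)] = digamma(nu/2) - log(nu/2)`.
#' Subtracting it before treating log-scale estimates as normal removes
#' the small-sample bias of the log transform; the matching log-scale
#' sampling variance is `trigamma(nu/2)`.
#'
#' @param dof chi-square degrees of freedom, positive.
#' @return the (negative) bias; increases to 0 as `dof` grows.
#' @examples
#' logChi2Bias(2)   # = -Euler-Mascheroni constant
#' @export
logChi2Bias <- function(dof) {
  if (any(dof <= 0)) stop("dof must be positive")
  digamma(dof / 2) - log(dof / 2)
}

# normal-normal ML on precomputed (y, s2): returns mu, v, and loglik fn
.nnFit <- function(y, s2) {
  nll <- function(mu, v) {
    w <- 1 / (s2 + v)
    0.5 * sum(log(s2 + v) + w * (y - mu)^2)
  }
  profMu <- function(v) sum(y / (s2 + v)) / sum(1 / (s2 + v))
  fv <- function(v) nll(profMu(v), v)
  vmax <- max(var(y) * 10, max(s2) * 10, 1e-6)
  opt <- optimize(fv, c(0, vmax))
  v <- if (fv(0) <= opt$objective) 0 else opt$minimum
  mu <- profMu(v)
  list(mu = mu, v = v, nll = nll, value = nll(mu, v))
}

#' @rdname popMean
#' @export
setMethod("popMean", "list", function(estimates, level = 0.95) {
  kinds <- unique(vapply(estimates, function(e) e@kind, character(1)))
  if (length(kinds) != 1L) stop("estimates must share a single kind")
  nFailed <- sum(vapply(estimates, function(e) e@failed, logical(1)))
  est <- Filter(function(e) !e@failed, estimates)
  m <- length(est)
  if (m < 1L) stop("no usable (non-failed) estimates")

  if (m == 1L) {
    e <- est[[1]]
    ci <- chisqCI(e@value, e@dof, level)
    return(new("PopulationEstimate", kind = kinds, mean = e@value,
               ciLow = ci[["low"]], ciHigh = ci[["high"]],
               logMean = log(e@value), betweenVarLog = 0, m = 1L,
               nFailed = as.integer(nFailed),
               note = "no between-individual information (m = 1)"))
  }

  vals <- vapply(est, function(e) e@value, numeric(1))
  dofs <- vapply(est, function(e) e@dof, numeric(1))
  y <- log(vals) - logChi2Bias(dofs)
  s2 <- trigamma(dofs / 2)
  fit <- .nnFit(y, s2)

  # profile-likelihood CI for the log population mean xi = mu + v/2,
  # then back-transform (population mean of a log-normal law)
  xiHat <- fit$mu + fit$v / 2
  cut <- qchisq(level, df = 1) / 2
  profXi <- function(xi) {
    vmax <- max(var(y) * 10, max(s2) * 10, 1e-6)
    o <- optimize(function(v) fit$nll(xi - v / 2, v), c(0, vmax))
    -min(o$objective, fit$nll(xi, 0))
  }
  llHat <- -fit$value
  bound <- function(dir) {
    f <- function(xi) llHat - profXi(xi) - cut
    step <- max(sqrt(max(s2 + fit$v) / m), 1e-4)
    hi <- xiHat + dir * step
    for (i in 1:60) {
      if (f(hi) >= 0) break
      hi <- xiHat + dir * (hi - xiHat) * 2 / dir  # double the step
    }
    if (f(hi) < 0) return(xiHat + dir * Inf)
    uniroot(f, sort(c(xiHat, hi)), tol = 1e-8)$root
  }
  lo <- bound(-1); hi <- bound(+1)

  new("PopulationEstimate", kind = kinds, mean = exp(xiHat),
      ciLow = exp(lo), ciHigh = exp(hi), logMean = fit$mu,
      betweenVarLog = fit$v, m = as.integer(m),
      nFailed = as.integer(nFailed), note = "")
})

#' Population mean under an inverse-Gaussian population law
#'
#' Alternative to [popMean()]: individual estimates keep their chi-square
#' sampling kernels, but the population of true values is modeled as
#' inverse-Gaussian; the marginal likelihood is integrated numerically and
#' maximized over the IG mean and shape.  Falls back to [popMean()] with a
#' warning on non-convergence.
#'
#' @param estimates list of [ScalarEstimate-class] objects.
#' @param level confidence level (default 0.95).
#' @return a [PopulationEstimate-class].
#' @name popMeanIG
#' @export
setMethod("popMeanIG", "list", function(estimates, level = 0.95) {
  kinds <- unique(vapply(estimates, function(e) e@kind, character(1)))
  nFailed <- sum(vapply(estimates, function(e) e@failed, logical(1)))
  est <- Filter(function(e) !e@failed, estimates)
  m <- length(est)
  if (m < 3L) {
    # too few individuals to identify the two-parameter population law
    return(popMean(estimates, level))
  }
  vals <- vapply(est, function(e) e@value, numeric(1))
  dofs <- vapply(est, function(e) e@dof, numeric(1))

  digl <- function(a, mu, lambda)   # inverse-Gaussian log-density
    0.5 * (log(lambda) - log(2 * pi) - 3 * log(a)) -
      lambda * (a - mu)^2 / (2 * mu^2 * a)
  # marginal log-density of one estimate x with dof nu:
  # x | A ~ A chisq_nu / nu;  A ~ IG(mu, lambda)
  marg1 <- function(x, nu, mu, lambda) {
    # integrate on the log scale over the union of the chi-square kernel
    # support (around a = x, log-sd ~ sqrt(2/nu)) and the population bulk
    # (around mu, log-sd ~ sqrt(mu/lambda)), so the quadrature resolves
    # a sharp kernel inside a wide population law
    f <- function(la) {
      a <- exp(la)
      exp(stats::dchisq(x * nu / a, df = nu, log = TRUE) + log(nu / a) +
            digl(a, mu, lambda) + la)
    }
    sk <- sqrt(2 / nu) + 1e-3
    sp <- sqrt(mu / lambda) + 1e-3
    lo <- min(log(x) - 12 * sk, log(mu) - 12 * sp)
    hi <- max(log(x) + 12 * sk, log(mu) + 12 * sp)
    val <- tryCatch(
      integrate(f, lower = lo, upper = hi, rel.tol = 1e-7,
                subdivisions = 400L, stop.on.error = FALSE)$value,
      error = function(e) NA_real_)
    if (!is.finite(val) || val <= 0) return(-1e6)
    log(val)
  }
  nll <- function(p) {
    mu <- exp(p[1]); lambda <- exp(p[2])
    -sum(vapply(seq_len(m),
                function(i) marg1(vals[i], dofs[i], mu, lambda),
                numeric(1)))
  }
  mu0 <- mean(vals)
  lam0 <- mu0^3 / max(var(vals), (0.1 * mu0)^2)
  opt <- tryCatch(
    optim(c(log(mu0), log(lam0)), nll, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e5) {
    warning("inverse-Gaussian fit did not converge; falling back to the ",
            "normal-normal estimator")
    return(popMean(estimates, level))
  }
  H <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  seLog <- if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && is.finite(V[1, 1]) && V[1, 1] > 0) sqrt(V[1, 1])
    else NA_real_
  } else NA_real_
  muHat <- exp(opt$par[1]); lamHat <- exp(opt$par[2])
  z <- qnorm(1 - (1 - level) / 2)
  if (!is.finite(seLog)) seLog <- 1 / sqrt(m)  # conservative small-m width
  new("PopulationEstimate", kind = kinds, mean = muHat,
      ciLow = muHat * exp(-z * seLog), ciHigh = muHat * exp(z * seLog),
      logMean = opt$par[1], betweenVarLog = muHat / lamHat,
      m = as.integer(m), nFailed = as.integer(nFailed),
      note = "inverse-Gaussian population model")
})

#' @rdname popAverageModel
#' @export
setMethod("popAverageModel", "list", function(fits) {
  stopifnot(length(fits) >= 2L)
  kinds <- vapply(fits, function(f) f@selectedKind, character(1))
  tab <- table(kinds)
  # most complex kind fitted by a majority; fall back to the modal kind,
  # ties toward the more complex
  ranks <- match(names(tab), .KINDS)
  maj <- names(tab)[tab > length(fits) / 2]
  kind <- if (length(maj)) maj[which.max(match(maj, .KINDS))]
          else names(tab)[order(-tab, -ranks)][1]
  keep <- kinds == kind
  if (!all(keep))
    warning(sum(!keep), " fit(s) of other kinds excluded from the ",
            "population average (", kind, " used)")
  fits <- fits[keep]
  m <- length(fits)
  if (m < 2L) stop("need at least 2 fits of the common kind")
  if (m == 2L)
    warning("population-averaged model from only 2 individuals; ",
            "low confidence")

  pars <- switch(kind, IID = "sigma", OU = c("tauP", "sigma"),
                 OUF = c("tauP", "tauV", "sigma"))
  meanLog <- setNames(numeric(length(pars)), pars)
  vLog <- setNames(numeric(length(pars)), pars)
  for (p in pars) {
    theta <- vapply(fits, function(f) switch(p, tauP = f@model@tauP,
                                             tauV = f@model@tauV,
                                             sigma = f@model@sigma),
                    numeric(1))
    varLog <- vapply(fits, function(f) f@vcovLog[p, p], numeric(1))
    varLog[!is.finite(varLog) | varLog <= 0] <- NA
    if (any(is.na(varLog))) {
      ok <- !is.na(varLog)
      theta <- theta[ok]; varLog <- varLog[ok]
      if (length(theta) < 2L)
        stop("too few informative fits for parameter ", p)
    }
    nu <- 2 / varLog
    y <- log(theta) - logChi2Bias(nu)
    s2 <- trigamma(nu / 2)
    fit <- .nnFit(y, s2)
    meanLog[p] <- fit$mu
    vLog[p] <- fit$v
  }
  covLog <- diag(as.numeric(vLog), nrow = length(pars))
  dimnames(covLog) <- list(pars, pars)
  new("PopulationModel", kind = kind, meanLog = meanLog, covLog = covLog,
      centerDispersion = 0)
})

setMethod("show", "PopulationEstimate", function(object) {
  unit <- if (object@kind == "area") "m^2" else "m/s"
  cat(sprintf("PopulationEstimate (%s): mean = %.4g %s [%.4g, %.4g]\n",
              object@kind, object@mean, unit, object@ciLow, object@ciHigh))
  cat(sprintf("  m = %d (failed: %d), between-individual log-variance = %.3g\n",
              object@m, object@nFailed, object@betweenVarLog))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' Serialize a population estimate to JSON
#'
#' @param popEst a [PopulationEstimate-class].
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
popEstimateToJSON <- function(popEst, path = NULL) {
  obj <- list(kind = popEst@kind, m = popEst@m, mean = popEst@mean,
              ci_low = popEst@ciLow, ci_high = popEst@ciHigh,
              between_var_log = popEst@betweenVarLog,
              n_failed = popEst@nFailed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
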