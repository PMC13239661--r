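# Maximum-likelihood fitting of IID/OU/OUF models via the Kalman filter,
# AICc model selection, Wald CIs and effective sample sizes.

# resolve the observation-error variance vector for a track
.errVarOf <- function(track, errorSD = NULL) {
  n <- length(track@times)
  e <- if (!is.null(errorSD)) errorSD else track@errorSD
  if (!length(e)) e <- 0
  rep(as.numeric(e)^2, length.out = n)
}

#' @rdname kalmanLogLik
#' @export
setMethod("kalmanLogLik", "Track", function(track, model, errorSD = NULL) {
  errVar <- .errVarOf(track, errorSD)
  tp <- if (is.na(model@tauP)) 0 else model@tauP
  tv <- if (is.na(model@tauV)) 0 else model@tauV
  .ck_loglik(track@times, track@x, track@y, .kindInt(model@kind),
             tp, tv, model@sigma, model@center[1], model@center[2], errVar)
})

# pooled semivariance of both axes at (approximately) a target lag
.semivariance <- function(track, lagTarget, maxPairs = 2000L) {
  t <- track@times
  n <- length(t)
  k <- max(1L, round(lagTarget / stats::median(diff(t))))
  if (k >= n) k <- n - 1L
  i <- seq_len(n - k)
  if (length(i) > maxPairs) i <- i[seq(1L, length(i), length.out = maxPairs)]
  dx <- track@x[i + k] - track@x[i]
  dy <- track@y[i + k] - track@y[i]
  list(gamma = mean(c(dx^2, dy^2)) / 2, lag = mean(t[i + k] - t[i]))
}

# variogram-based starting values for the log-parameters
.initParams <- function(track, kind) {
  t <- track@times
  n <- length(t)
  span <- t[n] - t[1]
  dt <- stats::median(diff(t))
  s0 <- max(mean(c(var(track@x), var(track@y))), 1e-12)
  g1 <- .semivariance(track, dt)
  gT <- .semivariance(track, span / 4)
  # tauP from the long-lag semivariance gamma(L) = sigma (1 - exp(-L/tauP))
  r <- min(max(1 - gT$gamma / s0, 1e-6), 1 - 1e-6)
  tp0 <- -gT$lag / log(r)
  tp0 <- min(max(tp0, dt / 10), 100 * span)
  if (kind == "OU") return(c(logTauP = log(tp0), logSigma = log(s0)))
  # short-lag expansion gamma(l) ~ sigma l^2 / (2 tauP tauV)
  tv0 <- s0 * g1$lag^2 / (2 * tp0 * max(g1$gamma, 1e-12 * s0))
  tv0 <- min(max(tv0, dt / 100), tp0 * 0.9)
  c(logTauP = log(tp0), logTauV = log(tv0), logSigma = log(s0))
}

# negative restricted log-likelihood over c(log-timescales, log sigma);
# the center is profiled out by GLS inside the filter (REML mode), so the
# variance parameters are estimated free of mean-estimation bias
.nllFactory <- function(track, kind, errVar, mode = 2L) {
  t <- track@times; x <- track@x; y <- track@y
  ki <- .kindInt(kind)
  function(par) {
    np <- length(par)
    sg <- exp(par[np])
    tp <- 0; tv <- 0
    if (kind == "OU") tp <- exp(par[1])
    if (kind == "OUF") {
      # the OUF law is symmetric in its two timescales; order them
      a <- exp(par[1]); b <- exp(par[2])
      tp <- max(a, b); tv <- min(a, b)
    }
    if (!all(is.finite(c(tp, tv, sg)))) return(1e12)
    ll <- tryCatch(
      .ck_profile(t, x, y, ki, tp, tv, sg, errVar, mode)[1],
      error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
}

# Fit of one candidate kind; returns NULL if it cannot be fitted.
# Point estimates maximize the profile-ML likelihood (stable even when the
# duration barely exceeds the crossing time); uncertainty and effective
# sample sizes use the restricted-likelihood curvature (.fitVcov), which
# accounts for the information spent estimating the center.
.fitCandidate <- function(track, kind, errVar, nStarts) {
  n <- length(track@times)
  sd0 <- sqrt(max(mean(c(var(track@x), var(track@y))), 1e-12))
  nll <- .nllFactory(track, kind, errVar, mode = 1L)
  remlNll <- .nllFactory(track, kind, errVar, mode = 2L)

  init <- if (kind == "IID") c(logSigma = log(sd0^2))
          else .initParams(track, kind)
  nTime <- length(init) - 1L   # timescale parameters

  if (kind == "IID") {
    # one-dimensional: optimize directly (closed form when error-free)
    if (all(errVar == 0)) {
      s2 <- (sum((track@x - mean(track@x))^2) +
               sum((track@y - mean(track@y))^2)) / (2 * n)
      par <- c(logSigma = log(s2))
    } else {
      opt <- optimize(function(ls) nll(ls), init[1] + c(-8, 8))
      par <- c(logSigma = opt$minimum)
    }
    return(list(kind = kind, par = par, nll = nll(par), nllFun = nll,
                remlNll = remlNll))
  }

  # deterministic multi-start grid on the timescales
  scales <- list(c(1, 1), c(0.25, 0.25), c(4, 4), c(4, 0.25),
                 c(0.0625, 0.25), c(16, 1))
  scales <- scales[seq_len(max(1L, min(nStarts, length(scales))))]
  best <- NULL
  for (sc in scales) {
    st <- init
    if (nTime >= 1) st[1] <- st[1] + log(sc[1])
    if (nTime >= 2) st[2] <- st[2] + log(sc[2])
    opt <- tryCatch(
      optim(st, nll, method = "Nelder-Mead",
            control = list(maxit = 4000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e11) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(NULL)
  list(kind = kind, par = best$par, nll = best$value, nllFun = nll,
       remlNll = remlNll)
}

# Observed-information covariance of the log-scale parameters from the
# restricted-likelihood curvature at its own optimum (so that the
# information spent on the center is accounted for; IID data then give
# exactly Narea = n - 1).  When the restricted surface has no interior
# optimum -- the short-duration ridge where only the diffusion rate is
# identified -- the curvature at the ML estimates is used instead.
# Returns NULL when singular.
.fitVcov <- function(cand, span) {
  par <- cand$par
  if (length(par) > 1L) {
    opt2 <- tryCatch(
      optim(par, cand$remlNll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    ok <- !is.null(opt2) && is.finite(opt2$value) && opt2$value < 1e11 &&
      exp(opt2$par[1]) <= 4 * span
    if (ok) par <- opt2$par
  } else {
    opt2 <- tryCatch(optimize(function(p) cand$remlNll(setNames(p, names(par))),
                              par + c(-2, 2)),
                     error = function(e) NULL)
    if (!is.null(opt2) && is.finite(opt2$objective))
      par <- setNames(opt2$minimum, names(par))
  }
  H <- tryCatch(optimHess(par, cand$remlNll), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0))
    return(NULL)
  list(V = V, par = par)
}

.aicc <- function(nll, k, nObs) {
  2 * nll + 2 * k + 2 * k * (k + 1) / max(nObs - k - 1, 1)
}

#' @rdname fitTrack
#' @export
setMethod("fitTrack", "Track",
  function(track, candidates = c("IID", "OU", "OUF"), errorSD = NULL,
           nStarts = 4L) {
    n <- length(track@times)
    if (n < 5L) stop("track must have at least 5 locations for fitting")
    candidates <- match.arg(candidates, .KINDS, several.ok = TRUE)
    errVar <- .errVarOf(track, errorSD)

    # deterministic (straight-line) motion has no stochastic component
    if (n >= 3L) {
      d2x <- diff(diff(track@x)); d2y <- diff(diff(track@y))
      scale2 <- mean(track@x^2 + track@y^2) + 1e-300
      if (mean(d2x^2 + d2y^2) < 1e-20 * scale2 && all(errVar == 0))
        stop("track is degenerate (deterministic motion); no stochastic ",
             "movement model can be fitted")
    }

    kPar <- c(IID = 3, OU = 4, OUF = 5)
    fits <- list()
    for (kind in candidates) {
      cand <- .fitCandidate(track, kind, errVar, nStarts)
      if (is.null(cand)) {
        warning("candidate ", kind, " failed to converge; excluded")
        next
      }
      # AICc on the profile-ML likelihood, with parameter counts that
      # include the profiled center
      cand$aicc <- .aicc(cand$nll, kPar[[kind]], 2 * n)
      fits[[kind]] <- cand
    }
    if (!length(fits)) stop("all candidate models failed to fit")

    aicc <- vapply(fits, `[[`, numeric(1), "aicc")
    # ties (< 1e-6) broken toward the simpler model: stable order IID<OU<OUF
    ord <- order(aicc + 1e-7 * match(names(aicc), .KINDS))
    best <- fits[[ord[1]]]
    sel <- best$kind
    par <- best$par
    np <- length(par)

    # GLS center and profile-ML log-likelihood at the REML estimates
    selPar <- switch(sel,
      IID = c(0, 0, exp(par[np])),
      OU  = c(exp(par[1]), 0, exp(par[np])),
      OUF = {
        a <- exp(par[1]); b <- exp(par[2])
        c(max(a, b), min(a, b), exp(par[np]))
      })
    prof <- .ck_profile(track@times, track@x, track@y, .kindInt(sel),
                        selPar[1], selPar[2], selPar[3], errVar, 1L)
    ctr <- prof[2:3]

    est <- switch(sel,
      IID = MovementModel("IID", sigma = selPar[3], center = ctr),
      OU  = MovementModel("OU", tauP = selPar[1], sigma = selPar[3],
                          center = ctr),
      OUF = MovementModel("OUF", tauP = selPar[1], tauV = selPar[2],
                          sigma = selPar[3], center = ctr))

    pnames <- c("tauP", "tauV", "sigma")
    vcovLog <- matrix(NA_real_, 3, 3, dimnames = list(pnames, pnames))
    ciLog <- matrix(NA_real_, 3, 2,
                    dimnames = list(pnames, c("low", "high")))
    dofArea <- 0; dofSpeed <- 0
    fv <- .fitVcov(best, span = diff(range(track@times)))
    if (is.null(fv)) {
      warning("singular information matrix; effective sample sizes ",
              "reported as 0")
    } else {
      V <- fv$V
      idx <- switch(sel, IID = c(sigma = 1L),
                    OU = c(tauP = 1L, sigma = 2L),
                    OUF = c(tauP = 1L, tauV = 2L, sigma = 3L))
      for (p in names(idx)) for (q in names(idx))
        vcovLog[p, q] <- V[idx[[p]], idx[[q]]]
      # center the intervals on the restricted-likelihood estimates (the
      # point where the curvature was taken); REML largely removes the
      # downward bias of the timescale estimates
      rp <- fv$par
      np2 <- length(rp)
      logEst <- c(tauP = log(est@tauP), tauV = log(est@tauV),
                  sigma = log(est@sigma))
      logEst["sigma"] <- rp[np2]
      if (sel == "OU") logEst["tauP"] <- rp[1]
      if (sel == "OUF") {
        logEst["tauP"] <- max(rp[1], rp[2])
        logEst["tauV"] <- min(rp[1], rp[2])
      }
      for (p in names(idx)) {
        se <- sqrt(vcovLog[p, p])
        ciLog[p, ] <- logEst[[p]] + c(-1, 1) * qnorm(0.975) * se
      }
      # Narea = 1 / Var(log sigma_hat)  (nu = 2 * Narea chi^2 DOF)
      dofArea <- min(1 / vcovLog["sigma", "sigma"], n)
      if (sel == "OUF") {
        a <- c(tauP = -1, tauV = -1, sigma = 1)  # log velocity variance
        vv <- as.numeric(t(a) %*% vcovLog %*% a)
        if (is.finite(vv) && vv > 0) dofSpeed <- 1 / vv
      }
    }

    new("FitResult", selectedKind = sel, model = est, ciLog = ciLog,
        vcovLog = vcovLog, loglik = prof[1], aicc = aicc,
        dofArea = dofArea, dofSpeed = dofSpeed, n = as.integer(n),
        errVar = errVar)
  })

#' @rdname effectiveSizes
#' @export
setMethod("effectiveSizes", "FitResult", function(fit, schedule = NULL) {
  c(Narea = fit@dofArea, Nspeed = fit@dofSpeed)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %s selected (n = %d)\n", object@selectedKind,
              object@n))
  cat("  AICc:", paste(sprintf("%s = %.2f", names(object@aicc),
                               object@aicc), collapse = ", "), "\n")
  m <- object@model
  if (!is.na(m@tauP)) cat(sprintf("  tauP = %.4g days\n", m@tauP / 86400))
  if (!is.na(m@tauV)) cat(sprintf("  tauV = %.4g hours\n", m@tauV / 3600))
  cat(sprintf("  sigma = %.4g m^2\n", m@sigma))
  cat(sprintf("  Narea = %.2f, Nspeed = %.2f\n", object@dofArea,
              object@dofSpeed))
})

#' Serialize a fit summary to JSON
#'
#' @param fit a [FitResult-class].
#' @param path optional output file; if missing the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
fitToJSON <- function(fit, path = NULL) {
  m <- fit@model
  obj <- list(
    selected = fit@selectedKind,
    estimates = list(tauP = m@tauP, tauV = m@tauV, sigma = m@sigma,
                     center = m@center),
    ciLog = as.data.frame(fit@ciLog),
    loglik = fit@loglik,
    aicc = as.list(fit@aicc),
    Narea = fit@dofArea, Nspeed = fit@dofSpeed, n = fit@n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
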