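# Individual-level estimators: AKDE home-range area, model-based Gaussian
# area, conditional-simulation mean speed, straight-line-displacement
# reference.

# mean pairwise positional correlation over the sampled times under a
# fitted model (regular-grid approximation at the median interval)
.meanPairwiseRho <- function(model, t) {
  n <- length(t)
  if (n < 2L) return(1)
  dt <- stats::median(diff(t))
  k <- seq_len(n - 1L)
  rho <- positionACF(model, k * dt) / model@sigma
  (n + 2 * sum((n - k) * rho)) / n^2
}

#' @rdname akdeArea
#' @export
setMethod("akdeArea", "Track",
  function(track, fit, level = 0.95, gridSize = 151L) {
    stopifnot(level > 0, level < 1)
    n <- length(track@times)
    sel <- fit@selectedKind
    reason <- ""
    if (sel == "IID") {
      # no autocorrelation model: classical KDE with the nominal n
      N <- max(n - 1, 1)
      reason <- "IID selected; classical KDE with nominal sample size"
    } else {
      N <- max(fit@dofArea, 1)
    }
    sg <- fit@model@sigma
    h2 <- sg * N^(-1 / 3)            # Gaussian reference bandwidth variance
    ctr <- fit@model@center
    half <- 4 * sqrt(sg + h2)
    gx <- seq(ctr[1] - half, ctr[1] + half, length.out = gridSize)
    gy <- seq(ctr[2] - half, ctr[2] + half, length.out = gridSize)
    h <- sqrt(h2)
    Dx <- dnorm(outer(gx, track@x, "-"), sd = h)
    Dy <- dnorm(outer(gy, track@y, "-"), sd = h)
    cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
    p <- as.numeric(Dx %*% t(Dy)) * cell / n
    p <- p / sum(p)
    # area of the `level` highest-density region, fractional last cell
    ps <- sort(p, decreasing = TRUE)
    cum <- cumsum(ps)
    k <- which(cum >= level)[1]
    frac <- if (k > 1) (level - cum[k - 1]) / ps[k] else level / ps[k]
    rawArea <- ((k - 1) + frac) * cell
    # calibrate against the Gaussian reference: the raw region reflects
    # the observed point spread, whose expectation under the fitted
    # autocorrelation is sigma * (1 - kappa) with kappa the mean pairwise
    # correlation of the sampled times, plus the kernel variance h2 --
    # so the expected raw area is (1 - kappa + N^{-1/3}) times the truth
    kap <- if (sel == "IID") 1 / n else .meanPairwiseRho(fit@model,
                                                         track@times)
    area <- rawArea / ((1 - kap) + N^(-1 / 3))
    nu <- 2 * N
    ci <- chisqCI(area, nu, level = 0.95)
    if (N < 2) reason <- paste0(reason, if (nzchar(reason)) "; ",
                                "unreliable: Narea < 2")
    ScalarEstimate("area", area, nu, ci["low"], ci["high"],
                   reason = reason, individual = track@id)
  })

#' @rdname gaussianArea
#' @export
setMethod("gaussianArea", "FitResult", function(fit, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (!fit@selectedKind %in% c("OU", "OUF"))
    return(failedEstimate("area",
      "selected model is not range-resident (OU/OUF)"))
  area <- pi * qchisq(level, df = 2) * fit@model@sigma
  N <- max(fit@dofArea, 1e-8)
  nu <- 2 * N
  ci <- chisqCI(area, nu)
  reason <- if (N < 2) "unreliable: Narea < 2" else ""
  ScalarEstimate("area", area, nu, ci["low"], ci["high"], reason = reason)
})

#' @rdname ctsdSpeed
#' @export
setMethod("ctsdSpeed", "Track",
  function(track, fit, nDraws = 200L, seed = 1L) {
    if (fit@selectedKind != "OUF")
      return(failedEstimate("speed",
        "data too coarse to support a model with correlated velocity",
        individual = track@id))
    m <- fit@model
    t <- track@times
    errVar <- rep(fit@errVar, length.out = length(t))
    hasErr <- any(errVar > 0)
    # conditional (kriging) mean of the velocity given the observations
    smX <- .ck_smooth(t, track@x, m@tauP, m@tauV, m@sigma, m@center[1],
                      errVar)
    smY <- .ck_smooth(t, track@y, m@tauP, m@tauV, m@sigma, m@center[2],
                      errVar)
    set.seed(as.integer(seed))
    draws <- numeric(nDraws)
    for (d in seq_len(nDraws)) {
      sim <- .ck_simulate(t, 2L, m@tauP, m@tauV, m@sigma, m@center[1],
                          m@center[2])
      ox <- sim[, 1]; oy <- sim[, 2]
      if (hasErr) {
        ox <- ox + rnorm(length(t), 0, sqrt(errVar))
        oy <- oy + rnorm(length(t), 0, sqrt(errVar))
      }
      sx <- .ck_smooth(t, ox, m@tauP, m@tauV, m@sigma, m@center[1], errVar)
      sy <- .ck_smooth(t, oy, m@tauP, m@tauV, m@sigma, m@center[2], errVar)
      # conditional draw = conditional mean + (simulation - its own
      # conditional mean): exact Gaussian conditioning
      vx <- smX[, 2] + (sim[, 3] - sx[, 2])
      vy <- smY[, 2] + (sim[, 4] - sy[, 2])
      draws[d] <- mean(sqrt(vx^2 + vy^2))
    }
    value <- mean(draws)
    # combine parameter uncertainty (chi^2 with nu = 2 Nspeed) with the
    # conditional-draw Monte-Carlo dispersion via an effective DOF
    N <- max(fit@dofSpeed, 1e-8)
    relVar <- 1 / N + var(draws) / (nDraws * value^2)
    nuEff <- 2 / relVar
    ci <- chisqCI(value, nuEff)
    ScalarEstimate("speed", value, nuEff, ci["low"], ci["high"],
                   individual = track@id)
  })

#' @rdname sldSpeed
#' @export
setMethod("sldSpeed", "Track", function(track) {
  n <- length(track@times)
  if (n < 2L) stop("need at least 2 locations")
  d <- sqrt(diff(track@x)^2 + diff(track@y)^2)
  sum(d) / (track@times[n] - track@times[1])
})

setMethod("show", "ScalarEstimate", function(object) {
  if (object@failed) {
    cat(sprintf("ScalarEstimate (%s) FAILED: %s\n", object@kind,
                object@reason))
  } else {
    unit <- if (object@kind == "area") "m^2" else "m/s"
    cat(sprintf("ScalarEstimate (%s): %.4g %s [%.4g, %.4g], dof = %.1f\n",
                object@kind, object@value, unit, object@ciLow,
                object@ciHigh, object@dof))
    if (nzchar(object@reason)) cat("  note:", object@reason, "\n")
  }
})

#' Serialize scalar estimates to JSON rows
#'
#' @param estimates list of [ScalarEstimate-class] objects.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
estimatesToJSON <- function(estimates, path = NULL) {
  rows <- lapply(estimates, function(e) list(
    individual = e@individual, kind = e@kind, value = e@value, dof = e@dof,
    ci_low = e@ciLow, ci_high = e@ciHigh, failed = e@failed,
    reason = e@reason))
  js <- jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Parse scalar estimates from JSON rows
#'
#' @param path JSON file written by [estimatesToJSON()].
#' @return list of [ScalarEstimate-class] objects.
#' @export
estimatesFromJSON <- function(path) {
  rows <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(rows, function(r) {
    if (isTRUE(r$failed))
      failedEstimate(r$kind, r$reason %||% "", r$individual %||% "")
    else
      ScalarEstimate(r$kind, r$value, r$dof, r$ci_low, r$ci_high,
                     reason = r$reason %||% "",
                     individual = r$individual %||% "")
  })
}
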