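# Movement-process operations: closed-form summaries, exact simulation,
# population sampling.

#' Accessors
#'
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("modelKind", "MovementModel", function(object) object@kind)

#' @rdname accessors
#' @export
setMethod("tauP", "MovementModel", function(object) object@tauP)

#' @rdname accessors
#' @export
setMethod("tauV", "MovementModel", function(object) object@tauV)

#' @rdname accessors
#' @export
setMethod("homeCenter", "MovementModel", function(object) object@center)

#' @describeIn accessors per-axis stationary positional variance (m^2).
#' @param ... ignored.
#' @export
setMethod("sigma", "MovementModel", function(object, ...) object@sigma)

#' @rdname accessors
#' @export
setMethod("modelKind", "PopulationModel", function(object) object@kind)

#' @rdname accessors
#' @export
setMethod("scheduleTimes", "SamplingSchedule", function(object) {
  seq(0, floor(object@duration / object@interval)) * object@interval
})

setMethod("show", "MovementModel", function(object) {
  cat(sprintf("MovementModel (%s)\n", object@kind))
  if (!is.na(object@tauP))
    cat(sprintf("  tauP : %.4g s (%.3g days)\n", object@tauP,
                object@tauP / 86400))
  if (!is.na(object@tauV))
    cat(sprintf("  tauV : %.4g s (%.3g hours)\n", object@tauV,
                object@tauV / 3600))
  cat(sprintf("  sigma: %.4g m^2\n", object@sigma))
  cat(sprintf("  center: (%.4g, %.4g) m\n", object@center[1],
              object@center[2]))
})

setMethod("show", "SamplingSchedule", function(object) {
  cat(sprintf("SamplingSchedule: T = %.4g days, dt = %.4g hours (n = %d)\n",
              object@duration / 86400, object@interval / 3600,
              length(scheduleTimes(object))))
})

setMethod("show", "Track", function(object) {
  cat(sprintf("Track '%s': %d locations", object@id, length(object@times)))
  if (length(object@times) > 1L)
    cat(sprintf(" over %.4g days", diff(range(object@times)) / 86400))
  if (length(object@errorSD)) cat(", with location error")
  cat("\n")
})

setMethod("show", "PopulationModel", function(object) {
  cat(sprintf("PopulationModel (%s), %s\n", object@kind,
              if (all(object@covLog == 0)) "prototype (no individual variation)"
              else "with individual variation"))
  ml <- object@meanLog
  for (p in names(ml))
    cat(sprintf("  %s: exp(meanLog) = %.4g, betweenVarLog = %.3g\n",
                p, exp(ml[[p]]), object@covLog[p, p]))
})

#' @rdname positionACF
#' @export
setMethod("positionACF", "MovementModel", function(model, lag) {
  if (any(lag < 0)) stop("lag must be non-negative")
  s <- model@sigma
  switch(model@kind,
    IID = ifelse(lag == 0, s, 0),
    OU  = s * exp(-lag / model@tauP),
    OUF = {
      tp <- model@tauP; tv <- model@tauV
      if (abs(tp - tv) < 1e-6 * tp) {
        # repeated-root limit of (tp e^{-t/tp} - tv e^{-t/tv})/(tp - tv)
        s * exp(-lag / tp) * (1 + lag / tp)
      } else {
        s * (tp * exp(-lag / tp) - tv * exp(-lag / tv)) / (tp - tv)
      }
    })
})

#' @rdname velocityVariance
#' @export
setMethod("velocityVariance", "MovementModel", function(model) {
  if (model@kind != "OUF")
    stop("velocity not defined for this model (kind ", model@kind, ")")
  model@sigma / (model@tauP * model@tauV)
})

#' @rdname trueArea
#' @export
setMethod("trueArea", "MovementModel", function(model, level = 0.95) {
  stopifnot(level > 0, level < 1)
  pi * qchisq(level, df = 2) * model@sigma
})

#' @rdname trueArea
#' @export
setMethod("trueArea", "PopulationModel", function(model, level = 0.95) {
  stopifnot(level > 0, level < 1)
  # population mean of pi * q * sigma_i with log sigma_i normal
  mu <- model@meanLog[["sigma"]]
  v <- model@covLog["sigma", "sigma"]
  pi * qchisq(level, df = 2) * exp(mu + v / 2)
})

#' @rdname trueMeanSpeed
#' @export
setMethod("trueMeanSpeed", "MovementModel", function(model) {
  sqrt(pi / 2) * sqrt(velocityVariance(model))
})

#' @rdname trueMeanSpeed
#' @export
setMethod("trueMeanSpeed", "PopulationModel", function(model) {
  if (model@kind != "OUF") stop("speed not defined for this model")
  # mean of sqrt(pi sigma / (2 tauP tauV)) = sqrt(pi/2) E[exp(a'X)] with
  # X = (log tauP, log tauV, log sigma), a = (-1/2, -1/2, 1/2)
  a <- c(tauP = -0.5, tauV = -0.5, sigma = 0.5)
  mu <- sum(a * model@meanLog[names(a)])
  vv <- as.numeric(t(a) %*% model@covLog[names(a), names(a)] %*% a)
  sqrt(pi / 2) * exp(mu + vv / 2)
})

#' @rdname simulateTrack
#' @export
setMethod("simulateTrack", "MovementModel",
  function(model, schedule, seed = 1L, id = "sim1") {
    times <- scheduleTimes(schedule)
    if (length(times) > 1e6)
      stop("schedule has more than 1e6 fixes; coarsen the interval")
    set.seed(as.integer(seed))
    tp <- if (is.na(model@tauP)) 0 else model@tauP
    tv <- if (is.na(model@tauV)) 0 else model@tauV
    zz <- .ck_simulate(times, .kindInt(model@kind), tp, tv,
                       model@sigma, model@center[1], model@center[2])
    Track(id = id, times = times, x = zz[, 1], y = zz[, 2])
  })

#' @rdname samplePopulation
#' @export
setMethod("samplePopulation", "PopulationModel",
  function(pop, m, seed = 1L) {
    stopifnot(m >= 1)
    nm <- names(pop@meanLog)
    zeroVar <- all(pop@covLog == 0)
    L <- if (zeroVar) NULL else {
      ev <- eigen(pop@covLog, symmetric = TRUE)
      ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
    }
    rejections <- 0L
    models <- vector("list", m)
    for (i in seq_len(m)) {
      set.seed(subSeed(seed, i))
      repeat {
        lp <- pop@meanLog
        if (!zeroVar)
          lp <- pop@meanLog + as.numeric(L %*% rnorm(length(nm)))
        center <- if (pop@centerDispersion > 0)
          rnorm(2, 0, pop@centerDispersion) else c(0, 0)
        ok <- switch(pop@kind,
          IID = TRUE,
          OU  = is.finite(lp[["tauP"]]),
          OUF = lp[["tauP"]] > lp[["tauV"]])
        if (ok) {
          models[[i]] <- MovementModel(pop@kind,
            tauP = if ("tauP" %in% nm) exp(lp[["tauP"]]) else NA,
            tauV = if ("tauV" %in% nm) exp(lp[["tauV"]]) else NA,
            sigma = exp(lp[["sigma"]]), center = center)
          break
        }
        rejections <- rejections + 1L
      }
    }
    attr(models, "rejections") <- rejections
    models
  })
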