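# S4 classes for movement models, tracks, fits, estimates and designs.

.KINDS <- c("IID", "OU", "OUF")
.kindInt <- function(kind) match(kind, .KINDS) - 1L

#' MovementModel: a stationary Gaussian movement process
#'
#' Isotropic IID, Ornstein-Uhlenbeck (OU) or Ornstein-Uhlenbeck with
#' foraging (OUF) process describing the movement of one range-resident
#' individual.  `tauP` is the position autocorrelation timescale (home-range
#' crossing time, seconds), `tauV` the velocity autocorrelation timescale
#' (directional persistence, seconds; OUF only), `sigma` the per-axis
#' stationary positional variance (m^2) and `center` the home-range center
#' (m).
#'
#' @slot kind one of `"IID"`, `"OU"`, `"OUF"`.
#' @slot tauP,tauV timescales in seconds (`NA_real_` where not applicable).
#' @slot sigma per-axis stationary positional variance, m^2.
#' @slot center numeric length 2, home-range center in meters.
#' @export
setClass("MovementModel",
  representation(kind = "character", tauP = "numeric", tauV = "numeric",
                 sigma = "numeric", center = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(length(object@kind) == 1L && object@kind %in% .KINDS))
      msg <- c(msg, "kind must be one of IID, OU, OUF")
    if (!(length(object@sigma) == 1L && is.finite(object@sigma) &&
          object@sigma > 0))
      msg <- c(msg, "sigma must be a single positive finite number")
    if (length(object@center) != 2L || any(!is.finite(object@center)))
      msg <- c(msg, "center must be two finite coordinates")
    if (object@kind == "OU" &&
        !(is.finite(object@tauP) && object@tauP > 0))
      msg <- c(msg, "OU requires tauP > 0")
    if (object@kind == "OUF") {
      if (!(is.finite(object@tauP) && is.finite(object@tauV) &&
            object@tauP >= object@tauV && object@tauV > 0))
        msg <- c(msg, "OUF requires tauP >= tauV > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a MovementModel
#'
#' @param kind `"IID"`, `"OU"` or `"OUF"`.
#' @param tauP,tauV timescales, numeric seconds or strings like `"1 day"`.
#' @param sigma per-axis stationary positional variance (m^2).
#' @param center home-range center (m), length 2.
#' @return a [MovementModel-class] object.
#' @examples
#' MovementModel("OUF", tauP = "1 day", tauV = "30 min", sigma = 1e6)
#' @export
MovementModel <- function(kind = c("OUF", "OU", "IID"), tauP = NA_real_,
                          tauV = NA_real_, sigma, center = c(0, 0)) {
  kind <- match.arg(kind)
  tauP <- if (all(is.na(tauP))) NA_real_ else asSeconds(tauP)
  tauV <- if (all(is.na(tauV))) NA_real_ else asSeconds(tauV)
  if (kind %in% c("IID")) { tauP <- NA_real_; tauV <- NA_real_ }
  if (kind == "OU") tauV <- NA_real_
  new("MovementModel", kind = kind, tauP = tauP, tauV = tauV,
      sigma = as.numeric(sigma), center = as.numeric(center))
}

#' SamplingSchedule: a regular sampling design for one deployment
#'
#' @slot duration total sampling duration T, seconds.
#' @slot interval sampling interval (time between fixes), seconds.
#' @export
setClass("SamplingSchedule",
  representation(duration = "numeric", interval = "numeric"),
  validity = function(object) {
    if (!(is.finite(object@duration) && is.finite(object@interval) &&
          object@interval > 0 && object@interval <= object@duration))
      "requires 0 < interval <= duration" else TRUE
  })

#' Construct a SamplingSchedule
#'
#' @param duration total duration T (seconds or string, e.g. `"10 days"`).
#' @param interval time between fixes (seconds or string, e.g. `"1 hour"`).
#' @return a [SamplingSchedule-class]; the fix times are
#'   `0, interval, ..., floor(duration/interval) * interval`.
#' @examples
#' sch <- SamplingSchedule("10 days", "1 hour")
#' length(scheduleTimes(sch))
#' @export
SamplingSchedule <- function(duration, interval) {
  new("SamplingSchedule", duration = asSeconds(duration),
      interval = asSeconds(interval))
}

#' Track: one individual's time-stamped planar locations
#'
#' @slot id individual identifier.
#' @slot times seconds since deployment start, strictly increasing.
#' @slot x,y planar coordinates in meters.
#' @slot errorSD optional per-fix location-error standard deviation (m);
#'   length 0 (none), 1 (common) or `length(times)`.
#' @export
setClass("Track",
  representation(id = "character", times = "numeric", x = "numeric",
                 y = "numeric", errorSD = "numeric"),
  validity = function(object) {
    n <- length(object@times)
    msg <- character()
    if (length(object@x) != n || length(object@y) != n)
      msg <- c(msg, "times, x, y must have equal length")
    if (n > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(!is.finite(object@x)) || any(!is.finite(object@y)))
      msg <- c(msg, "coordinates must be finite")
    if (!length(object@errorSD) %in% c(0L, 1L, n))
      msg <- c(msg, "errorSD must have length 0, 1 or length(times)")
    if (length(object@errorSD) && any(object@errorSD < 0))
      msg <- c(msg, "errorSD must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct a Track
#'
#' @param id individual identifier.
#' @param times numeric seconds, strictly increasing.
#' @param x,y planar meters.
#' @param errorSD optional per-fix location-error SD (m).
#' @return a [Track-class] object.
#' @export
Track <- function(id = "ind1", times, x, y, errorSD = numeric()) {
  new("Track", id = as.character(id), times = as.numeric(times),
      x = as.numeric(x), y = as.numeric(y), errorSD = as.numeric(errorSD))
}

#' PopulationModel: distribution of movement parameters across individuals
#'
#' Individual log-parameters (log tauP, log tauV, log sigma, in the order
#' relevant for `kind`) are multivariate normal with mean `meanLog` and
#' covariance `covLog`.  A zero `covLog` is the "prototype" mode: every
#' individual shares the population-averaged parameters.
#'
#' @slot kind movement process kind shared by the population.
#' @slot meanLog named numeric of population means of log-parameters.
#' @slot covLog covariance of the same logs (positive semi-definite).
#' @slot centerDispersion SD (m) used to scatter individual home-range
#'   centers around the origin; 0 keeps all centers at the origin.
#' @export
setClass("PopulationModel",
  representation(kind = "character", meanLog = "numeric",
                 covLog = "matrix", centerDispersion = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- length(object@meanLog)
    want <- switch(object@kind, IID = "sigma", OU = c("tauP", "sigma"),
                   OUF = c("tauP", "tauV", "sigma"))
    if (!identical(names(object@meanLog), want))
      msg <- c(msg, paste("meanLog must be named", paste(want, collapse = ", ")))
    if (!all(dim(object@covLog) == c(p, p)))
      msg <- c(msg, "covLog dimensions must match meanLog")
    else {
      if (max(abs(object@covLog - t(object@covLog))) > 1e-8)
        msg <- c(msg, "covLog must be symmetric")
      ev <- eigen(object@covLog, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev < -1e-8 * max(1, abs(ev))))
        msg <- c(msg, "covLog must be positive semi-definite")
    }
    if (object@centerDispersion < 0)
      msg <- c(msg, "centerDispersion must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a PopulationModel
#'
#' @param kind `"IID"`, `"OU"` or `"OUF"`.
#' @param tauP,tauV,sigma population *median* (i.e. exp of the mean log)
#'   parameters; timescales accept strings like `"1 day"`.
#' @param covLog covariance matrix of the log-parameters, or a vector of
#'   diagonal entries; defaults to the zero matrix (prototype mode).
#' @param centerDispersion SD (m) for scattering individual centers.
#' @return a [PopulationModel-class] object.
#' @examples
#' PopulationModel("OUF", tauP = "1 day", tauV = "30 min", sigma = 1e6,
#'                 covLog = c(0.25, 0.25, 0.25))
#' @export
PopulationModel <- function(kind = c("OUF", "OU", "IID"), tauP = NA, tauV = NA,
                            sigma, covLog = NULL, centerDispersion = 0) {
  kind <- match.arg(kind)
  meanLog <- switch(kind,
    IID = c(sigma = log(as.numeric(sigma))),
    OU  = c(tauP = log(asSeconds(tauP)), sigma = log(as.numeric(sigma))),
    OUF = c(tauP = log(asSeconds(tauP)), tauV = log(asSeconds(tauV)),
            sigma = log(as.numeric(sigma))))
  p <- length(meanLog)
  if (is.null(covLog)) covLog <- matrix(0, p, p)
  if (is.vector(covLog) && !is.matrix(covLog)) covLog <- diag(covLog, p)
  dimnames(covLog) <- list(names(meanLog), names(meanLog))
  new("PopulationModel", kind = kind, meanLog = meanLog, covLog = covLog,
      centerDispersion = as.numeric(centerDispersion))
}

#' FitResult: maximum-likelihood fit of movement models to one track
#'
#' @slot selectedKind kind selected by AICc.
#' @slot model point estimates as a [MovementModel-class].
#' @slot ciLog 95% Wald intervals for the log-parameters (rows tauP, tauV,
#'   sigma; `NA` where a parameter is absent from the selected kind).
#' @slot vcovLog covariance of the log-parameter estimates (same layout).
#' @slot loglik maximized log-likelihood of the selected model.
#' @slot aicc named AICc per candidate kind.
#' @slot dofArea effective sample size for home-range area (`N_area`).
#' @slot dofSpeed effective sample size for speed (`N_speed`; 0 unless OUF).
#' @slot n number of locations in the track.
#' @slot errVar per-fix observation-error variance used in the fit.
#' @export
setClass("FitResult",
  representation(selectedKind = "character", model = "MovementModel",
                 ciLog = "matrix", vcovLog = "matrix", loglik = "numeric",
                 aicc = "numeric", dofArea = "numeric", dofSpeed = "numeric",
                 n = "integer", errVar = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@loglik)) msg <- c(msg, "loglik must be finite")
    if (object@dofArea < 0) msg <- c(msg, "dofArea must be >= 0")
    if (object@dofSpeed < 0) msg <- c(msg, "dofSpeed must be >= 0")
    if (object@selectedKind != "OUF" && object@dofSpeed != 0)
      msg <- c(msg, "dofSpeed must be 0 for non-OUF fits")
    if (object@dofArea > object@n + 1e-9)
      msg <- c(msg, "dofArea cannot exceed n")
    if (length(msg)) msg else TRUE
  })

#' ScalarEstimate: a positive scalar estimate with chi-square uncertainty
#'
#' Home-range area (m^2) or mean speed (m/s) for one individual, treated as
#' having a chi-square sampling distribution with `dof` degrees of freedom.
#' A failed estimate (e.g. speed when the data were too coarse to support a
#' correlated-velocity model) carries `failed = TRUE` and a `reason`.
#'
#' @slot kind `"area"` or `"speed"`.
#' @slot value point estimate (m^2 or m/s).
#' @slot dof chi-square degrees of freedom of the estimate.
#' @slot ciLow,ciHigh 95% confidence bounds.
#' @slot failed logical.
#' @slot reason character, non-empty when failed or flagged.
#' @slot individual individual identifier.
#' @export
setClass("ScalarEstimate",
  representation(kind = "character", value = "numeric", dof = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", failed = "logical",
                 reason = "character", individual = "character"),
  validity = function(object) {
    if (object@failed) return(TRUE)
    msg <- character()
    if (!object@kind %in% c("area", "speed"))
      msg <- c(msg, "kind must be 'area' or 'speed'")
    if (!(object@value > 0)) msg <- c(msg, "value must be positive")
    if (!(object@dof > 0)) msg <- c(msg, "dof must be positive")
    if (!(object@ciLow > 0 && object@ciLow <= object@value &&
          object@value <= object@ciHigh))
      msg <- c(msg, "need 0 < ciLow <= value <= ciHigh")
    if (length(msg)) msg else TRUE
  })

#' Construct a ScalarEstimate
#'
#' @param kind `"area"` or `"speed"`.
#' @param value point estimate.
#' @param dof chi-square degrees of freedom.
#' @param ciLow,ciHigh confidence bounds.
#' @param failed logical.
#' @param reason failure or diagnostic note.
#' @param individual individual identifier.
#' @return a [ScalarEstimate-class].
#' @export
ScalarEstimate <- function(kind, value, dof, ciLow, ciHigh, failed = FALSE,
                           reason = "", individual = "") {
  new("ScalarEstimate", kind = kind, value = as.numeric(value),
      dof = as.numeric(dof), ciLow = as.numeric(ciLow),
      ciHigh = as.numeric(ciHigh), failed = failed, reason = reason,
      individual = as.character(individual))
}

#' @rdname ScalarEstimate
#' @export
failedEstimate <- function(kind, reason, individual = "") {
  new("ScalarEstimate", kind = kind, value = NA_real_, dof = NA_real_,
      ciLow = NA_real_, ciHigh = NA_real_, failed = TRUE, reason = reason,
      individual = as.character(individual))
}

#' PopulationEstimate: population mean of a positive quantity
#'
#' @slot kind `"area"` or `"speed"`.
#' @slot mean population mean estimate.
#' @slot ciLow,ciHigh 95% confidence bounds for the mean.
#' @slot logMean estimate of the mean of the log-scale population
#'   distribution (mu).
#' @slot betweenVarLog between-individual variance on the log scale.
#' @slot m number of individuals used.
#' @slot nFailed number of individuals excluded as failed.
#' @slot note diagnostic note (e.g. single-individual estimates).
#' @export
setClass("PopulationEstimate",
  representation(kind = "character", mean = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", logMean = "numeric",
                 betweenVarLog = "numeric", m = "integer",
                 nFailed = "integer", note = "character"),
  validity = function(object) {
    msg <- character()
    if (!(object@ciLow <= object@mean && object@mean <= object@ciHigh))
      msg <- c(msg, "need ciLow <= mean <= ciHigh")
    if (object@m < 1L) msg <- c(msg, "m must be >= 1")
    if (object@betweenVarLog < 0)
      msg <- c(msg, "betweenVarLog must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' CorruptionSpec: deployment hazards applied to simulated tracks
#'
#' @slot fixSuccess probability that a scheduled fix succeeds.
#' @slot failureHazard rate (1/s) of premature permanent device failure
#'   (exponential failure time).
#' @slot storageCap maximum number of stored fixes (`Inf` for none).
#' @slot errorRMS per-axis location-error SD in meters (0 for none).
#' @slot errorMult optional per-fix error multipliers (DOP-like).
#' @export
setClass("CorruptionSpec",
  representation(fixSuccess = "numeric", failureHazard = "numeric",
                 storageCap = "numeric", errorRMS = "numeric",
                 errorMult = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@fixSuccess > 0 && object@fixSuccess <= 1))
      msg <- c(msg, "fixSuccess must be in (0, 1]")
    if (object@failureHazard < 0) msg <- c(msg, "failureHazard must be >= 0")
    if (is.finite(object@storageCap) && object@storageCap < 2)
      msg <- c(msg, "storageCap must be >= 2")
    if (object@errorRMS < 0) msg <- c(msg, "errorRMS must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a CorruptionSpec
#'
#' @param fixSuccess probability a scheduled fix succeeds (default 1).
#' @param failureHazard device failure rate per second (default 0).
#' @param storageCap maximum stored fixes (default `Inf`).
#' @param errorRMS per-axis location-error SD, meters (default 0).
#' @param errorMult optional per-fix error multipliers.
#' @return a [CorruptionSpec-class].
#' @export
CorruptionSpec <- function(fixSuccess = 1, failureHazard = 0,
                           storageCap = Inf, errorRMS = 0,
                           errorMult = numeric()) {
  new("CorruptionSpec", fixSuccess = as.numeric(fixSuccess),
      failureHazard = as.numeric(failureHazard),
      storageCap = as.numeric(storageCap), errorRMS = as.numeric(errorRMS),
      errorMult = as.numeric(errorMult))
}

#' DesignSpec: one candidate study design to evaluate
#'
#' @slot schedule the [SamplingSchedule-class] (duration T, interval dt).
#' @slot m population sample size (individuals tracked).
#' @slot corruption deployment hazards ([CorruptionSpec-class]).
#' @slot replicates number of simulation replicates.
#' @slot seed integer seed controlling all randomness.
#' @slot targets subset of `c("area", "speed")`.
#' @slot errorThreshold relative-error threshold in percent (default 5).
#' @export
setClass("DesignSpec",
  representation(schedule = "SamplingSchedule", m = "integer",
                 corruption = "CorruptionSpec", replicates = "integer",
                 seed = "integer", targets = "character",
                 errorThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@m < 2L) msg <- c(msg, "m must be >= 2")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (!(object@errorThreshold > 0))
      msg <- c(msg, "errorThreshold must be > 0")
    if (!all(object@targets %in% c("area", "speed")) ||
        length(object@targets) < 1L)
      msg <- c(msg, "targets must be a subset of c('area', 'speed')")
    if (length(msg)) msg else TRUE
  })

#' Construct a DesignSpec
#'
#' @param schedule a [SamplingSchedule-class], or duration if `interval`
#'   given.
#' @param m population sample size.
#' @param corruption a [CorruptionSpec-class] (default: none).
#' @param replicates simulation replicates (default 1).
#' @param seed integer seed.
#' @param targets which targets to evaluate.
#' @param errorThreshold percent threshold for the verdict (default 5).
#' @param interval optional; with `schedule` a duration, builds the
#'   schedule.
#' @return a [DesignSpec-class].
#' @export
DesignSpec <- function(schedule, m, corruption = CorruptionSpec(),
                       replicates = 1, seed = 1,
                       targets = c("area", "speed"), errorThreshold = 5,
                       interval = NULL) {
  if (!is(schedule, "SamplingSchedule"))
    schedule <- SamplingSchedule(schedule, interval)
  new("DesignSpec", schedule = schedule, m = as.integer(m),
      corruption = corruption, replicates = as.integer(replicates),
      seed = as.integer(seed), targets = targets,
      errorThreshold = as.numeric(errorThreshold))
}

#' DesignReport: outcome of evaluating one study design
#'
#' @slot summary one row per target: mean relative error (%), confidence
#'   bounds of the mean, mean population-CI width (%), pass/fail verdict,
#'   failure fraction, mean effective sample sizes and mean leave-one-out
#'   correctness rate.
#' @slot detail one row per replicate and target.
#' @slot truth named closed-form population truths (area m^2, speed m/s).
#' @slot threshold percent threshold used for verdicts.
#' @export
setClass("DesignReport",
  representation(summary = "data.frame", detail = "data.frame",
                 truth = "numeric", threshold = "numeric"))
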