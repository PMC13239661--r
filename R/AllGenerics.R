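# Generics.  Accessors first, then the workflow verbs.

#' @rdname accessors
#' @param object,x an object.
#' @export
setGeneric("modelKind", function(object) standardGeneric("modelKind"))

#' @rdname accessors
#' @export
setGeneric("tauP", function(object) standardGeneric("tauP"))

#' @rdname accessors
#' @export
setGeneric("tauV", function(object) standardGeneric("tauV"))

#' @rdname accessors
#' @export
setGeneric("homeCenter", function(object) standardGeneric("homeCenter"))

#' @rdname accessors
#' @export
setGeneric("scheduleTimes", function(object) standardGeneric("scheduleTimes"))

#' Position autocovariance function
#'
#' Per-axis positional autocovariance of the process at a time lag:
#' `C(t) = sigma * exp(-t/tauP)` for OU,
#' `C(t) = sigma * (tauP * exp(-t/tauP) - tauV * exp(-t/tauV)) /
#' (tauP - tauV)` for OUF (with the analytic repeated-root limit when
#' `tauP = tauV`), and `sigma * 1{t = 0}` for IID.
#'
#' @param model a [MovementModel-class].
#' @param lag non-negative time lag(s), seconds.
#' @return autocovariance in m^2, vectorized over `lag`.
#' @examples
#' m <- MovementModel("OUF", tauP = "1 day", tauV = "1 hour", sigma = 1e6)
#' positionACF(m, c(0, 3600, 86400))
#' @export
setGeneric("positionACF", function(model, lag) standardGeneric("positionACF"))

#' Stationary velocity variance of an OUF process
#'
#' Per-axis stationary velocity variance, `sigma / (tauP * tauV)` (the
#' negative second derivative of the position autocovariance at lag 0).
#' Velocity is undefined for IID and OU processes.
#'
#' @param model a [MovementModel-class] of kind OUF.
#' @return velocity variance in (m/s)^2.
#' @export
setGeneric("velocityVariance",
           function(model) standardGeneric("velocityVariance"))

#' True home-range area of a movement process
#'
#' Area of the `level`-quantile ellipse of the stationary bivariate
#' Gaussian position distribution: `pi * qchisq(level, 2) * sigma`.
#' For a [PopulationModel-class] the population mean area under the
#' log-normal parameter distribution is returned (closed form).
#'
#' @param model a [MovementModel-class] or [PopulationModel-class].
#' @param level coverage probability (default 0.95).
#' @return area in m^2.
#' @export
setGeneric("trueArea",
           function(model, level = 0.95) standardGeneric("trueArea"))

#' True mean speed of an OUF movement process
#'
#' Mean modulus of the stationary bivariate Gaussian velocity:
#' `sqrt(pi * sigma / (2 * tauP * tauV))` (the Rayleigh mean).  For a
#' [PopulationModel-class] the population mean speed under the log-normal
#' parameter distribution is returned (closed form).
#'
#' @param model a [MovementModel-class] of kind OUF, or a
#'   [PopulationModel-class].
#' @return speed in m/s.
#' @export
setGeneric("trueMeanSpeed", function(model) standardGeneric("trueMeanSpeed"))

#' Simulate a track from a movement model
#'
#' Exact draw of the stationary Gaussian process at the schedule's fix
#' times, per axis through the (position, velocity) state-space recursion.
#' Identical `(model, schedule, seed)` give identical tracks.
#'
#' @param model a [MovementModel-class].
#' @param schedule a [SamplingSchedule-class].
#' @param seed integer seed.
#' @param id individual identifier for the returned track.
#' @return a [Track-class].
#' @export
setGeneric("simulateTrack", function(model, schedule, seed = 1L, id = "sim1")
  standardGeneric("simulateTrack"))

#' Draw individual movement models from a population model
#'
#' Log-parameters are drawn from `Normal(meanLog, covLog)`; draws violating
#' the model invariants (e.g. `tauV >= tauP`) are rejected and redrawn, and
#' the rejection count is reported as an attribute.  A zero `covLog`
#' returns `m` copies of the prototype model.  Sub-seeds are derived per
#' individual so populations are reproducible individual-by-individual.
#'
#' @param pop a [PopulationModel-class].
#' @param m number of individuals.
#' @param seed integer seed.
#' @return list of `m` [MovementModel-class] objects, with attribute
#'   `"rejections"`.
#' @export
setGeneric("samplePopulation", function(pop, m, seed = 1L)
  standardGeneric("samplePopulation"))

#' Exact Gaussian log-likelihood of a track under a movement model
#'
#' Kalman-filter evaluation of the log-density of the observed coordinates
#' (both axes) under the model, with observation-noise variance
#' `errorSD^2` added to the measurement equation.
#'
#' @param track a [Track-class].
#' @param model a [MovementModel-class]; its `center` is the mean.
#' @param errorSD observation-error SD (scalar or per fix); defaults to the
#'   track's own `errorSD` (0 if absent).
#' @return log-likelihood (numeric scalar).
#' @export
setGeneric("kalmanLogLik", function(track, model, errorSD = NULL)
  standardGeneric("kalmanLogLik"))

#' Fit movement models to a track by maximum likelihood
#'
#' Fits each candidate kind by multi-start Nelder-Mead over log-parameters
#' (timescales, variance) and the center, selects by small-sample AICc
#' (ties broken toward the simpler model), and computes Wald confidence
#' intervals and effective sample sizes from the observed Fisher
#' information.
#'
#' @param track a [Track-class] with at least 5 locations.
#' @param candidates subset of `c("IID", "OU", "OUF")`.
#' @param errorSD observation-error SD used in fitting (defaults to the
#'   track's recorded `errorSD`).
#' @param nStarts number of optimizer starts (default 4).
#' @return a [FitResult-class].
#' @export
setGeneric("fitTrack",
  function(track, candidates = c("IID", "OU", "OUF"), errorSD = NULL,
           nStarts = 4L) standardGeneric("fitTrack"))

#' Effective sample sizes of a fitted model
#'
#' Returns `c(Narea, Nspeed)`.  The chi-square degrees of freedom of the
#' area estimate are `nu = 2 * (sigma / SE(sigma))^2` from the observed
#' Fisher information, and `Narea = nu / 2`; so IID data give
#' `Narea ~ n - 1` and long OU tracks give `Narea ~ T / tauP`.  `Nspeed`
#' is defined analogously from the velocity-variance information (0 for
#' non-OUF fits).
#'
#' @param fit a [FitResult-class].
#' @param schedule optional [SamplingSchedule-class] (unused; kept for a
#'   stable interface).
#' @return named numeric `c(Narea = ..., Nspeed = ...)`.
#' @export
setGeneric("effectiveSizes", function(fit, schedule = NULL)
  standardGeneric("effectiveSizes"))

#' Home-range area by autocorrelated kernel density estimation
#'
#' Kernel density estimate whose Gaussian reference bandwidth uses the
#' effective sample size `Narea` of the fitted autocorrelation model in
#' place of the nominal sample size (per-axis bandwidth variance
#' `sigma * Narea^(-1/3)`).  The area of the `level` highest-density
#' region is evaluated on a grid, corrected for the kernel-induced
#' dispersion of the Gaussian reference, and given a chi-square confidence
#' interval with `nu = 2 * Narea` degrees of freedom.
#'
#' @param track a [Track-class].
#' @param fit the corresponding [FitResult-class].
#' @param level coverage of the home-range region (default 0.95).
#' @param gridSize grid resolution per axis (default 151).
#' @return a [ScalarEstimate-class] of kind `"area"`.
#' @export
setGeneric("akdeArea", function(track, fit, level = 0.95, gridSize = 151L)
  standardGeneric("akdeArea"))

#' Model-based Gaussian home-range area
#'
#' Fast alternative to [akdeArea()]: `pi * qchisq(level, 2) * sigma_hat`
#' with the same chi-square confidence-interval convention.
#'
#' @param fit a [FitResult-class] with selected kind OU or OUF.
#' @param level coverage (default 0.95).
#' @return a [ScalarEstimate-class] of kind `"area"`.
#' @export
setGeneric("gaussianArea", function(fit, level = 0.95)
  standardGeneric("gaussianArea"))

#' Mean movement speed by conditional simulation
#'
#' Continuous-time speed estimation: velocities are sampled from the
#' conditional (kriging) distribution of the fitted state-space model given
#' the observed locations, the mean modulus over the track's span is
#' averaged over `nDraws` conditional draws, and the confidence interval
#' combines conditional-draw dispersion with parameter uncertainty through
#' a chi-square scaling with `2 * Nspeed` degrees of freedom.  If the
#' selected model lacks correlated velocities (IID/OU), the estimate fails
#' with reason `"data too coarse to support a model with correlated
#' velocity"` — the design loop counts these failures.
#'
#' @param track a [Track-class].
#' @param fit the corresponding [FitResult-class].
#' @param nDraws number of conditional draws (default 200).
#' @param seed integer seed for the conditional draws.
#' @return a [ScalarEstimate-class] of kind `"speed"`.
#' @export
setGeneric("ctsdSpeed", function(track, fit, nDraws = 200L, seed = 1L)
  standardGeneric("ctsdSpeed"))

#' Straight-line-displacement speed
#'
#' Naive reference estimator: total summed displacement divided by the
#' track's time span.  Unlike [ctsdSpeed()], it diverges as the sampling
#' interval shrinks when uncorrelated location error is present.
#'
#' @param track a [Track-class] with at least 2 locations.
#' @return speed in m/s.
#' @export
setGeneric("sldSpeed", function(track) standardGeneric("sldSpeed"))

#' Population mean of individual estimates
#'
#' Log-chi-square bias-corrected normal-normal hierarchical estimator; see
#' [popMean()].
#'
#' @param estimates list of [ScalarEstimate-class] objects.
#' @param level confidence level (default 0.95).
#' @return a [PopulationEstimate-class].
#' @export
setGeneric("popMean", function(estimates, level = 0.95)
  standardGeneric("popMean"))

#' @rdname popMeanIG
#' @export
setGeneric("popMeanIG", function(estimates, level = 0.95)
  standardGeneric("popMeanIG"))

#' Population-averaged movement model from multiple fits
#'
#' Applies the log-chi-square bias-corrected normal-normal machinery to
#' each log-parameter (tauP, tauV, sigma) across fitted individuals,
#' returning a [PopulationModel-class] whose `meanLog` holds the population
#' means and whose diagonal `covLog` holds the between-individual
#' variances.  This population model can seed [samplePopulation()].
#'
#' @param fits list of [FitResult-class] objects.
#' @return a [PopulationModel-class].
#' @export
setGeneric("popAverageModel", function(fits)
  standardGeneric("popAverageModel"))

#' Corrupt a simulated track with deployment hazards
#'
#' Applies, in causal order: premature failure truncation (exponential
#' failure time), storage cap (first fixes kept), Bernoulli fix-success
#' thinning, and additive iid Gaussian location error per axis (recorded
#' on the returned track's `errorSD`).
#'
#' @param track a [Track-class].
#' @param spec a [CorruptionSpec-class].
#' @param seed integer seed.
#' @return a [Track-class] (possibly with fewer than 2 locations; callers
#'   count such deployments as unusable rather than erroring).
#' @export
setGeneric("corruptTrack", function(track, spec, seed = 1L)
  standardGeneric("corruptTrack"))

#' Evaluate a candidate study design against a population model
#'
#' The outer loop of the workflow: per replicate, sample `m` individuals
#' from the population model, simulate and corrupt their tracks, fit
#' movement models, estimate the targets, pool them with [popMean()], and
#' compare with the closed-form population truth as relative errors
#' against the percent threshold.
#'
#' @param pop a [PopulationModel-class].
#' @param design a [DesignSpec-class].
#' @return a [DesignReport-class].
#' @export
setGeneric("evaluateDesign", function(pop, design)
  standardGeneric("evaluateDesign"))
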