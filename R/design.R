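# Design evaluation: track corruption, relative errors, the outer
# simulation loop, resampling combinations and leave-one-out correctness.

#' @rdname corruptTrack
#' @export
setMethod("corruptTrack", "Track", function(track, spec, seed = 1L) {
  set.seed(as.integer(seed))
  t <- track@times; x <- track@x; y <- track@y
  n <- length(t)
  mult <- if (length(spec@errorMult)) rep(spec@errorMult, length.out = n)
          else rep(1, n)
  # 1. premature permanent failure: exponential failure time
  if (spec@failureHazard > 0) {
    tf <- rexp(1, rate = spec@failureHazard)
    keep <- (t - t[1]) <= tf
    t <- t[keep]; x <- x[keep]; y <- y[keep]; mult <- mult[keep]
  }
  # 2. storage cap: earliest fixes kept
  if (is.finite(spec@storageCap) && length(t) > spec@storageCap) {
    idx <- seq_len(spec@storageCap)
    t <- t[idx]; x <- x[idx]; y <- y[idx]; mult <- mult[idx]
  }
  # 3. fix-success thinning
  if (spec@fixSuccess < 1 && length(t)) {
    keep <- runif(length(t)) <= spec@fixSuccess
    t <- t[keep]; x <- x[keep]; y <- y[keep]; mult <- mult[keep]
  }
  # 4. additive location error, recorded on the track
  errorSD <- numeric()
  if (spec@errorRMS > 0 && length(t)) {
    errorSD <- spec@errorRMS * mult
    x <- x + rnorm(length(t), 0, errorSD)
    y <- y + rnorm(length(t), 0, errorSD)
  }
  Track(id = track@id, times = t, x = x, y = y, errorSD = errorSD)
})

#' Relative error in percent
#'
#' `100 * (estimate - truth) / truth`; negative values indicate
#' underestimation.
#'
#' @param estimate estimated value(s).
#' @param truth positive expected (true) value.
#' @return percent relative error, vectorized over `estimate`.
#' @examples
#' relativeError(0.75, 1)   # -25
#' @export
relativeError <- function(estimate, truth) {
  if (any(truth <= 0)) stop("truth must be positive")
  100 * (estimate - truth) / truth
}

# closed-form population truths for the requested targets
.designTruth <- function(pop, targets) {
  truth <- c()
  if ("area" %in% targets) truth["area"] <- trueArea(pop)
  if ("speed" %in% targets) truth["speed"] <- trueMeanSpeed(pop)
  truth
}

#' @rdname evaluateDesign
#' @export
setMethod("evaluateDesign", signature(pop = "PopulationModel",
                                      design = "DesignSpec"),
  function(pop, design) {
    targets <- design@targets
    truth <- .designTruth(pop, targets)
    sch <- design@schedule
    thr <- design@errorThreshold
    detail <- list()

    for (r in seq_len(design@replicates)) {
      seedR <- subSeed(design@seed, r)
      models <- samplePopulation(pop, design@m, seedR)
      pools <- setNames(vector("list", length(targets)), targets)
      nArea <- c(); nSpeed <- c()
      for (i in seq_len(design@m)) {
        tseed <- subSeed(seedR, 10000 + i)
        trk <- simulateTrack(models[[i]], sch, seed = tseed,
                             id = sprintf("ind%02d", i))
        trk <- corruptTrack(trk, design@corruption,
                            seed = subSeed(tseed, 777))
        if (length(trk@times) < 5L) {
          for (tg in targets)
            pools[[tg]] <- c(pools[[tg]],
              list(failedEstimate(tg, "deployment yielded no usable data",
                                  individual = trk@id)))
          next
        }
        fit <- tryCatch(suppressWarnings(fitTrack(trk)),
                        error = function(e) NULL)
        if (is.null(fit)) {
          for (tg in targets)
            pools[[tg]] <- c(pools[[tg]],
              list(failedEstimate(tg, "model fitting failed",
                                  individual = trk@id)))
          next
        }
        nArea <- c(nArea, fit@dofArea)
        if ("area" %in% targets)
          pools[["area"]] <- c(pools[["area"]], list(akdeArea(trk, fit)))
        if ("speed" %in% targets) {
          sp <- ctsdSpeed(trk, fit, seed = subSeed(tseed, 999))
          pools[["speed"]] <- c(pools[["speed"]], list(sp))
          if (!sp@failed) nSpeed <- c(nSpeed, fit@dofSpeed)
        }
      }
      for (tg in targets) {
        pool <- pools[[tg]]
        ok <- !vapply(pool, function(e) e@failed, logical(1))
        row <- data.frame(replicate = r, target = tg,
                          re = NA_real_, ciLowRE = NA_real_,
                          ciHighRE = NA_real_, ciWidth = NA_real_,
                          failedFraction = mean(!ok),
                          meanNarea = if (length(nArea)) mean(nArea) else NA,
                          meanNspeed = if (length(nSpeed)) mean(nSpeed)
                                       else NA,
                          loo = NA_real_)
        if (any(ok)) {
          pe <- popMean(pool)
          row$re <- relativeError(pe@mean, truth[[tg]])
          row$ciLowRE <- relativeError(pe@ciLow, truth[[tg]])
          row$ciHighRE <- relativeError(pe@ciHigh, truth[[tg]])
          row$ciWidth <- 100 * (pe@ciHigh - pe@ciLow) / truth[[tg]]
          if (sum(ok) >= 3L)
            row$loo <- looCorrectness(pool[ok], truth[[tg]], thr)
        }
        detail[[length(detail) + 1L]] <- row
      }
    }
    detail <- do.call(rbind, detail)

    summ <- do.call(rbind, lapply(targets, function(tg) {
      d <- detail[detail$target == tg & is.finite(detail$re), ]
      meanRE <- mean(d$re)
      ciRE <- if (nrow(d) >= 2L) {
        se <- sd(d$re) / sqrt(nrow(d))
        meanRE + c(-1, 1) * qt(0.975, nrow(d) - 1) * se
      } else c(d$ciLowRE, d$ciHighRE)
      pass <- is.finite(meanRE) && abs(meanRE) <= thr &&
        all(is.finite(ciRE)) && all(abs(ciRE) <= thr)
      data.frame(target = tg, meanRE = meanRE, ciLowRE = ciRE[1],
                 ciHighRE = ciRE[2], meanCIWidth = mean(d$ciWidth),
                 pass = pass,
                 failedFraction = mean(detail$failedFraction[
                   detail$target == tg]),
                 meanNarea = mean(d$meanNarea),
                 meanNspeed = if (tg == "speed") mean(d$meanNspeed)
                              else NA_real_,
                 looCorrectness = mean(d$loo[is.finite(d$loo)]))
    }))

    new("DesignReport", summary = summ, detail = detail, truth = truth,
        threshold = thr)
  })

#' Resampling sensitivity analysis over combinations of individuals
#'
#' Draws combinations of `m` individuals from the pool (all of them when
#' `choose(length(pool), m) <= maxCombos`, otherwise `maxCombos` distinct
#' combinations sampled uniformly without replacement) and recomputes the
#' population mean for each.
#'
#' @param pool list of [ScalarEstimate-class] objects.
#' @param m combination size, `2 <= m <= length(pool)`.
#' @param maxCombos maximum number of combinations (default 250).
#' @param seed integer seed (used only when sampling is needed).
#' @return data.frame with one row per combination (`mean`, `ciLow`,
#'   `ciHigh`) plus attributes `summary` (across-combination mean and
#'   envelope) and `combos` (the index matrix).
#' @export
resampleCombinations <- function(pool, m, maxCombos = 250L, seed = 1L) {
  n <- length(pool)
  stopifnot(m >= 2, m <= n)
  total <- choose(n, m)
  if (total <= maxCombos) {
    combos <- combn(n, m)
  } else {
    set.seed(as.integer(seed))
    seen <- new.env(hash = TRUE)
    combos <- matrix(0L, nrow = m, ncol = maxCombos)
    got <- 0L
    while (got < maxCombos) {
      cand <- sort(sample.int(n, m))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        combos[, got] <- cand
      }
    }
  }
  rows <- apply(combos, 2, function(idx) {
    pe <- popMean(pool[idx])
    c(mean = pe@mean, ciLow = pe@ciLow, ciHigh = pe@ciHigh)
  })
  out <- as.data.frame(t(rows))
  out$combo <- seq_len(ncol(combos))
  attr(out, "combos") <- combos
  attr(out, "summary") <- c(m = m, mean = mean(out$mean),
                            lo = min(out$mean), hi = max(out$mean))
  out
}

#' Leave-one-out correctness rate
#'
#' Excludes each individual in turn, recomputes the population mean, and
#' reports the percentage of leave-one-out estimates whose relative error
#' against `truth` lies within `threshold` percent.
#'
#' @param pool list of at least 3 [ScalarEstimate-class] objects.
#' @param truth positive true value.
#' @param threshold percent threshold (default 5).
#' @return correctness rate in percent, with attribute `"re"` holding the
#'   leave-one-out relative errors.
#' @export
looCorrectness <- function(pool, truth, threshold = 5) {
  n <- length(pool)
  stopifnot(n >= 3L)
  re <- vapply(seq_len(n), function(i) {
    relativeError(popMean(pool[-i])@mean, truth)
  }, numeric(1))
  rate <- 100 * mean(abs(re) <= threshold)
  attr(rate, "re") <- re
  rate
}

setMethod("show", "DesignReport", function(object) {
  cat("DesignReport (threshold ±", object@threshold, "%)\n", sep = "")
  print(object@summary, row.names = FALSE, digits = 4)
})

#' Write a design report to JSON and tidy CSV
#'
#' @param report a [DesignReport-class].
#' @param jsonPath,csvPath optional output files.
#' @return the JSON string, invisibly.
#' @export
reportToJSON <- function(report, jsonPath = NULL, csvPath = NULL) {
  obj <- list(threshold = report@threshold, truth = as.list(report@truth),
              summary = report@summary, detail = report@detail)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  if (!is.null(jsonPath)) writeLines(js, jsonPath)
  if (!is.null(csvPath)) write.csv(report@detail, csvPath,
                                   row.names = FALSE)
  invisible(js)
}
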