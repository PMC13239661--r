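# Plot helpers: relative error against population sample size with the
# error-threshold guides.

#' Plot relative errors across designs
#'
#' Relative error (%) of the population mean against population sample
#' size m, one facet per sampling duration or interval, with dotted
#' guides at the error threshold.
#'
#' @param reports list of [DesignReport-class] objects as returned by
#'   [evaluateProject()] (with its `"grid"` attribute), or a single
#'   report.
#' @param target `"area"` or `"speed"`.
#' @param facet facet variable: `"duration"` or `"interval"`.
#' @return a ggplot object.
#' @export
plotDesignReports <- function(reports, target = "area",
                              facet = c("duration", "interval")) {
  facet <- match.arg(facet)
  if (is(reports, "DesignReport")) reports <- list(reports)
  grid <- attr(reports, "grid")
  if (is.null(grid))
    grid <- data.frame(duration = NA, interval = NA,
                       m = seq_along(reports))
  thr <- reports[[1]]@threshold
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    s <- reports[[i]]@summary
    s <- s[s$target == target, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    s$m <- grid$m[i]
    s$duration <- grid$duration[i] / 86400
    s$interval <- grid$interval[i] / 3600
    s
  }))
  if (is.null(rows) || !nrow(rows)) stop("no rows for target ", target)
  rows$facetVar <- if (facet == "duration")
    sprintf("T = %.3g d", rows$duration) else
    sprintf("dt = %.3g h", rows$interval)
  ggplot2::ggplot(rows, ggplot2::aes(x = m, y = meanRE)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ciLowRE, ymax = ciHighRE,
                                          color = pass)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#2166ac",
                                           `FALSE` = "#b2182b"),
                                guide = "none") +
    ggplot2::facet_wrap(~facetVar) +
    ggplot2::labs(x = "population sample size (m)",
                  y = "relative error (%)",
                  title = sprintf("Population mean %s", target)) +
    ggplot2::theme_minimal()
}

# figure from the JSON written by the CLI's evaluate-design command
plotReportJSON <- function(obj) {
  summ <- do.call(rbind, lapply(seq_len(length(obj$m)), function(i) {
    s <- obj$summary[[i]]
    s$m <- obj$m[i]
    s$duration <- obj$duration_s[i] / 86400
    s$interval <- obj$interval_s[i] / 3600
    s
  }))
  thr <- obj$threshold[1]
  summ$facetVar <- sprintf("T = %.3g d, dt = %.3g h", summ$duration,
                           summ$interval)
  ggplot2::ggplot(summ, ggplot2::aes(x = m, y = meanRE)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ciLowRE, ymax = ciHighRE,
                                          color = target)) +
    ggplot2::facet_wrap(~facetVar) +
    ggplot2::labs(x = "population sample size (m)",
                  y = "relative error (%)") +
    ggplot2::theme_minimal()
}
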