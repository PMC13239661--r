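# Data interchange: planar and Movebank-dialect CSV, the local
# azimuthal-equidistant projection, and project configuration files.

.EARTH_RADIUS <- 6378137  # meters, spherical model

# forward azimuthal-equidistant projection about (lon0, lat0), degrees in,
# meters out: x east, y north
.projectAEQD <- function(lon, lat, lon0, lat0) {
  d2r <- pi / 180
  phi1 <- lat0 * d2r; phi2 <- lat * d2r
  dl <- (lon - lon0) * d2r
  # great-circle distance (haversine) and initial bearing
  a <- sin((phi2 - phi1) / 2)^2 + cos(phi1) * cos(phi2) * sin(dl / 2)^2
  dist <- 2 * .EARTH_RADIUS * asin(pmin(1, sqrt(a)))
  brg <- atan2(sin(dl) * cos(phi2),
               cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dl))
  list(x = dist * sin(brg), y = dist * cos(brg))
}

# inverse: planar meters about (lon0, lat0) back to degrees
.unprojectAEQD <- function(x, y, lon0, lat0) {
  d2r <- pi / 180
  dist <- sqrt(x^2 + y^2)
  brg <- atan2(x, y)
  phi1 <- lat0 * d2r
  dr <- dist / .EARTH_RADIUS
  phi2 <- asin(sin(phi1) * cos(dr) + cos(phi1) * sin(dr) * cos(brg))
  lam2 <- lon0 * d2r +
    atan2(sin(brg) * sin(dr) * cos(phi1),
          cos(dr) - sin(phi1) * sin(phi2))
  list(lon = lam2 / d2r, lat = phi2 / d2r)
}

# strict UTC ISO-8601 parser; naive timestamps (no explicit UTC marker and
# no "+00:00") are rejected to avoid silent timezone drift
.parseUTC <- function(ts) {
  ts <- trimws(ts)
  ok <- grepl(
    "^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?(Z|\\+00:00|UTC)$",
    ts)
  if (any(!ok))
    stop("unparseable or non-UTC timestamp(s), e.g. '", ts[!ok][1],
         "' (rows ", paste(utils::head(which(!ok), 5), collapse = ", "),
         "); timestamps must be ISO-8601 with an explicit UTC marker")
  clean <- sub("(Z|\\+00:00|UTC)$", "", ts)
  clean <- sub("T", " ", clean, fixed = TRUE)
  out <- as.POSIXct(clean, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  if (any(is.na(out)))
    stop("unparseable timestamp(s) at rows ",
         paste(utils::head(which(is.na(out)), 5), collapse = ", "))
  as.numeric(out)
}

#' Read Movebank-dialect CSV tracking data
#'
#' Expects columns `timestamp`, `location-long`, `location-lat`,
#' `individual-local-identifier` (an optional `error_sd` column, meters, is
#' carried through).  Timestamps must be ISO-8601 UTC.  Coordinates are
#' projected to planar meters by an azimuthal-equidistant projection about
#' the dataset centroid (spherical model, radius 6378137 m); tracks are
#' sorted by time per individual and duplicate timestamps rejected.
#'
#' @param path CSV file.
#' @param origin optional projection center `c(lon, lat)`; defaults to the
#'   dataset centroid.  Pass the writer's origin to recover planar
#'   coordinates exactly.
#' @return named list of [Track-class] objects, with attribute `"origin"`
#'   (the projection center, `c(lon, lat)`).
#' @export
readMovebankCSV <- function(path, origin = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("timestamp", "location-long", "location-lat",
            "individual-local-identifier")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  tsec <- .parseUTC(as.character(df$timestamp))
  if (is.null(origin)) {
    lon0 <- mean(df[["location-long"]]); lat0 <- mean(df[["location-lat"]])
  } else {
    lon0 <- origin[1]; lat0 <- origin[2]
  }
  xy <- .projectAEQD(df[["location-long"]], df[["location-lat"]],
                     lon0, lat0)
  ids <- as.character(df[["individual-local-identifier"]])
  t0 <- min(tsec)
  tracks <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    o <- idx[order(tsec[idx])]
    tt <- tsec[o]
    if (anyDuplicated(tt))
      stop("duplicate timestamps for individual '", ids[o[1]],
           "' at input rows ",
           paste(utils::head(o[duplicated(tt)], 5), collapse = ", "))
    err <- if ("error_sd" %in% names(df)) as.numeric(df$error_sd[o])
           else numeric()
    Track(id = ids[o[1]], times = tt - t0, x = xy$x[o], y = xy$y[o],
          errorSD = err)
  })
  attr(tracks, "origin") <- c(lon = lon0, lat = lat0)
  tracks
}

#' Write tracks as Movebank-dialect CSV
#'
#' Inverse of the projection in [readMovebankCSV()]: planar coordinates
#' are mapped back to longitude/latitude about `origin`, and track times
#' (seconds) are rendered as UTC timestamps counted from `epoch`.
#'
#' @param tracks list of [Track-class] objects.
#' @param path output CSV file.
#' @param origin projection center `c(lon, lat)` in degrees.
#' @param epoch POSIXct origin for the timestamps.
#' @return `path`, invisibly.
#' @export
writeMovebankCSV <- function(tracks, path, origin = c(0, 0),
                             epoch = as.POSIXct("2020-01-01 00:00:00",
                                                tz = "UTC")) {
  rows <- lapply(tracks, function(tr) {
    ll <- .unprojectAEQD(tr@x, tr@y, origin[1], origin[2])
    data.frame(
      timestamp = paste0(format(epoch + tr@times, "%Y-%m-%d %H:%M:%S",
                                tz = "UTC"), "Z"),
      `location-long` = ll$lon, `location-lat` = ll$lat,
      `individual-local-identifier` = tr@id, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write planar track CSV
#'
#' Plain planar dialect with header `individual,t,x,y[,error_sd]`
#' (seconds and meters).
#'
#' @param path CSV file.
#' @return `readTracksCSV`: named list of [Track-class] objects.
#' @export
readTracksCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$individual), function(d) {
    d <- d[order(d$t), ]
    err <- if ("error_sd" %in% names(d)) as.numeric(d$error_sd)
           else numeric()
    if (length(err) && all(is.na(err))) err <- numeric()
    Track(id = as.character(d$individual[1]), times = d$t, x = d$x,
          y = d$y, errorSD = err)
  })
}

#' @rdname readTracksCSV
#' @param tracks list of [Track-class] objects.
#' @export
writeTracksCSV <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    d <- data.frame(individual = tr@id, t = tr@times, x = tr@x, y = tr@y)
    if (length(tr@errorSD))
      d$error_sd <- rep(tr@errorSD, length.out = length(tr@times))
    d
  })
  hasErr <- any(vapply(rows, function(d) "error_sd" %in% names(d),
                       logical(1)))
  if (hasErr)
    rows <- lapply(rows, function(d) {
      if (!"error_sd" %in% names(d)) d$error_sd <- 0
      d
    })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- project configuration ------------------------------------------------

.CONFIG_KEYS <- list(
  top = c("population", "design", "corruption", "replicates", "seed",
          "targets", "threshold", "out"),
  population = c("kind", "tauP", "tauV", "sigma", "covLogDiag",
                 "centerDispersion", "pilot"),
  design = c("duration", "interval", "m"),
  corruption = c("fixSuccess", "failureHazard", "storageCap", "errorRMS"))

.checkKeys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Read a project configuration file
#'
#' YAML (or JSON) description of a design-evaluation project: a
#' `population` block (either explicit parameters or a `pilot` planar-CSV
#' path from which a population model is extracted by fitting), a `design`
#' grid (lists of durations, intervals and population sample sizes), an
#' optional `corruption` block, `replicates`, `seed`, `targets` and
#' `threshold`.  Unknown keys are errors.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return list with elements `pop` ([PopulationModel-class]), `grid`
#'   (data.frame of duration/interval/m), `corruption`, `replicates`,
#'   `seed`, `targets`, `threshold`, `out`.
#' @export
readProjectConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path,
                                                         simplifyVector = TRUE)
         else yaml::read_yaml(path)
  .checkKeys(cfg, .CONFIG_KEYS$top, "top level")
  if (is.null(cfg$population)) stop("config must have a population block")
  if (is.null(cfg$design)) stop("config must have a design block")
  .checkKeys(cfg$population, .CONFIG_KEYS$population, "population")
  .checkKeys(cfg$design, .CONFIG_KEYS$design, "design")

  pb <- cfg$population
  if (!is.null(pb$pilot)) {
    if (!file.exists(pb$pilot))
      stop("pilot data file not found: ", pb$pilot)
    tracks <- readTracksCSV(pb$pilot)
    fits <- lapply(tracks, function(tr) suppressWarnings(fitTrack(tr)))
    pop <- suppressWarnings(popAverageModel(fits))
  } else {
    covd <- pb$covLogDiag
    pop <- PopulationModel(pb$kind %||% "OUF", tauP = pb$tauP %||% NA,
                           tauV = pb$tauV %||% NA, sigma = pb$sigma,
                           covLog = if (is.null(covd)) NULL
                                    else as.numeric(covd),
                           centerDispersion = pb$centerDispersion %||% 0)
  }

  grid <- expand.grid(
    duration = vapply(as.list(cfg$design$duration), asSeconds, numeric(1)),
    interval = vapply(as.list(cfg$design$interval), asSeconds, numeric(1)),
    m = as.integer(unlist(cfg$design$m)),
    KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("design grid is empty")

  cb <- cfg$corruption
  corruption <- if (is.null(cb)) CorruptionSpec() else {
    .checkKeys(cb, .CONFIG_KEYS$corruption, "corruption")
    CorruptionSpec(fixSuccess = cb$fixSuccess %||% 1,
                   failureHazard = cb$failureHazard %||% 0,
                   storageCap = cb$storageCap %||% Inf,
                   errorRMS = cb$errorRMS %||% 0)
  }

  list(pop = pop, grid = grid, corruption = corruption,
       replicates = as.integer(cfg$replicates %||% 1),
       seed = as.integer(cfg$seed %||% 1),
       targets = cfg$targets %||% c("area", "speed"),
       threshold = as.numeric(cfg$threshold %||% 5),
       out = cfg$out %||% ".")
}

#' Evaluate every design in a project configuration
#'
#' @param config path to a configuration file or the list returned by
#'   [readProjectConfig()].
#' @return list of [DesignReport-class] objects, one per grid row, with
#'   the grid as attribute `"grid"`.
#' @export
evaluateProject <- function(config) {
  if (is.character(config)) config <- readProjectConfig(config)
  reports <- lapply(seq_len(nrow(config$grid)), function(i) {
    g <- config$grid[i, ]
    design <- DesignSpec(SamplingSchedule(g$duration, g$interval),
                         m = g$m, corruption = config$corruption,
                         replicates = config$replicates,
                         seed = subSeed(config$seed, i),
                         targets = config$targets,
                         errorThreshold = config$threshold)
    evaluateDesign(config$pop, design)
  })
  attr(reports, "grid") <- config$grid
  reports
}
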