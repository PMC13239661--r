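# Seeded fixture generator: small, fully reproducible example datasets
# with a manifest of closed-form truths.

#' Generate the package's seeded fixture bundle
#'
#' Writes to `dir`: (a) `homogeneous_tracks.csv`, ten tracks simulated
#' from a prototype OUF population (tauP = 1 day, tauV = 30 min,
#' sigma = 1 km^2); (b) `heterogeneous_population.yaml`, the same
#' population with between-individual log-variance 0.25 per parameter,
#' plus `heterogeneous_tracks.csv` simulated from it; (c)
#' `homogeneous_movebank.csv`, the Movebank-dialect export of (a); and
#' `manifest.json` with the closed-form true areas and mean speeds.
#' Regeneration with the same seed is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param duration,interval sampling schedule of the simulated tracks
#'   (defaults: 16 days at 10-minute fixes).
#' @return named list of written file paths, invisibly.
#' @export
makeFixtures <- function(dir = tempfile("fixtures"), seed = 1L,
                         duration = "16 days", interval = "10 min") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sch <- SamplingSchedule(duration, interval)
  proto <- PopulationModel("OUF", tauP = "1 day", tauV = "30 min",
                           sigma = 1e6)
  hetero <- PopulationModel("OUF", tauP = "1 day", tauV = "30 min",
                            sigma = 1e6, covLog = c(0.25, 0.25, 0.25))

  homMods <- samplePopulation(proto, 10, seed = seed)
  homTracks <- lapply(seq_along(homMods), function(i)
    simulateTrack(homMods[[i]], sch, seed = subSeed(seed, 100 + i),
                  id = sprintf("hom%02d", i)))
  hetMods <- samplePopulation(hetero, 10, seed = subSeed(seed, 5000))
  hetTracks <- lapply(seq_along(hetMods), function(i)
    simulateTrack(hetMods[[i]], sch, seed = subSeed(seed, 200 + i),
                  id = sprintf("het%02d", i)))

  paths <- list(
    homogeneous = file.path(dir, "homogeneous_tracks.csv"),
    heterogeneous = file.path(dir, "heterogeneous_tracks.csv"),
    population = file.path(dir, "heterogeneous_population.yaml"),
    movebank = file.path(dir, "homogeneous_movebank.csv"),
    manifest = file.path(dir, "manifest.json"))

  writeTracksCSV(homTracks, paths$homogeneous)
  writeTracksCSV(hetTracks, paths$heterogeneous)
  writeMovebankCSV(homTracks, paths$movebank, origin = c(23.5, -19.5))
  yaml::write_yaml(list(
    population = list(kind = "OUF", tauP = "1 day", tauV = "30 min",
                      sigma = 1e6, covLogDiag = c(0.25, 0.25, 0.25)),
    design = list(duration = list("16 days"), interval = list("10 min"),
                  m = list(10)),
    replicates = 1, seed = as.integer(seed)), paths$population)

  manifest <- list(
    seed = as.integer(seed),
    schedule = list(duration_s = sch@duration, interval_s = sch@interval),
    prototype = list(tauP_s = 86400, tauV_s = 1800, sigma_m2 = 1e6,
                     trueArea_m2 = trueArea(proto),
                     trueMeanSpeed_ms = trueMeanSpeed(proto)),
    heterogeneous = list(covLogDiag = 0.25,
                         trueArea_m2 = trueArea(hetero),
                         trueMeanSpeed_ms = trueMeanSpeed(hetero)),
    individuals = lapply(seq_along(hetMods), function(i) {
      mdl <- hetMods[[i]]
      list(id = sprintf("het%02d", i), tauP_s = mdl@tauP,
           tauV_s = mdl@tauV, sigma_m2 = mdl@sigma,
           trueArea_m2 = trueArea(mdl),
           trueMeanSpeed_ms = trueMeanSpeed(mdl))
    }))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths$manifest)
  invisible(paths)
}
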