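#' Default demonstration pipeline configuration
#'
#' A reduced-size synthetic deployment that preserves the statistical
#' structure of the full study: a duty-cycled "index" recorder sampled fast
#' enough to resolve the 86 Hz component (used for the long-term
#' spectrogram and FIN series) and a low-rate continuous recorder analysed
#' for call abundance, plus ADCP and sea-ice scenarios. Problem sizes are
#' deliberately small so a full run completes in minutes; scale `start`/
#' `end`, `sample_rate` and `file_duration_s` up for larger experiments.
#'
#' @param outdir artefact directory
#' @param seed RNG seed for every stage
#' @param days number of days to simulate (from 1 January)
#' @return nested configuration list
#' @export
default_pipeline_config <- function(outdir = tempfile("finpam"),
                                    seed = 1L, days = 365L) {
  start <- as.POSIXct("2013-01-01 00:00:00", tz = "UTC")
  end <- start + days * 86400
  profile <- seasonal_profile()
  list(
    outdir = outdir, seed = as.integer(seed), days = days,
    site = c(-61.0147, -55.9755),
    profile = profile,
    index_scenario = scenario_config(
      "aural_like", sample_rate = 1024, file_duration_s = 30,
      duty = c(0.5, 360), start = start, end = end, seed = seed),
    cab_scenario = scenario_config(
      "sonovault_like", sample_rate = 500, file_duration_s = 60,
      duty = c(1, 10), seed = seed + 1L,
      start = as.POSIXct("2013-05-10 00:00:00", tz = "UTC"),
      end = as.POSIXct("2013-05-12 00:00:00", tz = "UTC")),
    psd = psd_config(512L, "hamming", 0.5, 1024),
    bands = fin_band_presets("fin86"),
    detector_threshold = 7,
    adcp = list(days = 60L, dvm_amplitude = 100, seed = seed + 2L),
    ice = list(winter_peak_fraction = 0.6, seed = seed + 3L))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates every stage end-to-end: synthesis of the recording sets,
#' long-term spectrogram on quietest windows, FIN series with 14-day
#' smoothing, call counting with censoring/exclusion and CAB, daily
#' acoustic occurrence, ADCP MVBS with migration amplitudes, sea-ice radius
#' averaging, and the diel Kruskal-Wallis test. Artefact CSVs are written
#' under `config$outdir`; the same objects are returned invisibly.
#'
#' @param config a [default_pipeline_config()]-style list
#' @param stages character vector of stages to run (default all):
#'   `"index"` (LTS + FIN), `"cab"`, `"dao"`, `"env"`, `"diel"`
#' @param quiet suppress progress messages
#' @return (invisibly) list of stage results and artefact paths
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("index", "cab", "dao", "env", "diel"),
                         quiet = FALSE) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  res <- list(outdir = config$outdir)

  if (any(c("index", "dao") %in% stages)) {
    say("synthesising index recording set ...")
    synth <- synthesize_recording_set(config$index_scenario, config$profile,
                                      file.path(config$outdir, "audio_index"))
    res$index_manifest <- synth$manifest
    res$index_log <- synth$log
  }

  if ("index" %in% stages) {
    say("building long-term spectrogram and FIN series ...")
    lts <- build_lts(res$index_manifest, config$psd,
                     calib = config$index_scenario$calibration)
    fin <- fin_series(lts, config$bands)
    utils::write.csv(fin, file.path(config$outdir, "fin_series.csv"),
                     row.names = FALSE)
    res$lts <- lts
    res$fin <- fin
  }

  if ("cab" %in% stages || "diel" %in% stages) {
    say("synthesising CAB recording set and counting calls ...")
    synth <- synthesize_recording_set(config$cab_scenario, config$profile,
                                      file.path(config$outdir, "audio_cab"))
    m <- synth$manifest
    intervals <- do.call(rbind, lapply(seq_len(nrow(m)), function(j) {
      wav <- read_wav_pcm16(m$path[j])
      count_interval(wav$samples, wav$fs, m$start_utc[j], m$file_id[j],
                     threshold = config$detector_threshold)
    }))
    gate <- noise_gate_from_levels(intervals$noise_level_db)
    intervals$excluded <- intervals$noise_level_db > gate
    intervals$n_calls[intervals$excluded] <- NA_integer_
    res$intervals <- intervals
    res$cab_log <- synth$log
    res$cab_per_hour <- cab(intervals)
    utils::write.csv(intervals, file.path(config$outdir, "count_intervals.csv"),
                     row.names = FALSE)
    say(sprintf("CAB = %.0f calls/h over %d usable intervals",
                res$cab_per_hour,
                sum(!intervals$censored & !intervals$excluded)))
  }

  if ("dao" %in% stages) {
    say("screening daily acoustic occurrence ...")
    m <- res$index_manifest
    day <- as.Date(m$start_utc, tz = "UTC")
    dao <- do.call(rbind, lapply(split(m, day), daily_occurrence,
                                 threshold = config$detector_threshold))
    rownames(dao) <- NULL
    res$dao <- dao
    utils::write.csv(dao, file.path(config$outdir, "dao.csv"),
                     row.names = FALSE)
    say(sprintf("acoustic occurrence on %.0f%% of days",
                100 * mean(dao$present)))
  }

  if ("env" %in% stages) {
    say("ADCP backscatter and sea-ice averaging ...")
    adcp <- synthesize_adcp(config$adcp$days, config$adcp$dvm_amplitude,
                            seed = config$adcp$seed)
    prof <- mvbs(adcp)
    res$mvbs <- prof
    res$migration <- migration_amplitude(prof)
    utils::write.csv(res$migration, file.path(config$outdir, "migration.csv"),
                     row.names = FALSE)
    ice <- synthesize_ice_field(config$days,
                                config$ice$winter_peak_fraction,
                                site = config$site,
                                seed = config$ice$seed)
    res$ice <- ice_radius_average(ice, config$site)
    res$ice$ice_pct_smoothed <- running_mean(
      as.POSIXct(paste(res$ice$date, "12:00:00"), tz = "UTC"),
      res$ice$ice_pct, 14)
    utils::write.csv(res$ice, file.path(config$outdir, "ice_series.csv"),
                     row.names = FALSE)
  }

  if ("diel" %in% stages) {
    say("diel light-regime test ...")
    iv <- assign_light_period(res$intervals, config$site[1], config$site[2])
    use <- !iv$censored & !iv$excluded & !is.na(iv$n_calls)
    grp <- droplevels(iv$light_period[use])  # regimes present in the window
    res$intervals_light <- iv
    if (nlevels(grp) >= 2L) {
      res$diel <- kruskal_wallis(iv$n_calls[use], grp)
      say(sprintf("Kruskal-Wallis H = %.2f (df = %d, p = %.2f, critical %.2f)",
                  res$diel$H, res$diel$df, res$diel$p,
                  res$diel$critical_value))
    } else {
      say("only one light regime in the analysed window; diel test skipped")
    }
  }

  invisible(res)
}
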