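#' Call template
#'
#' Parametric description of one synthesised sound. Kinds: `fin20` (the
#' ~1 s pulsed downsweep from 28 to 15 Hz), `fin_hf` (the simultaneous
#' higher-frequency component near 86 Hz), `zcall` (Antarctic blue whale
#' surrogate: a tone near 27 Hz followed by a step/downsweep to ~19 Hz) and
#' `chorus` (band-limited 15-30 Hz noise sustained over a minute or more).
#'
#' @param kind one of `"fin20"`, `"fin_hf"`, `"zcall"`, `"chorus"`
#' @param f_start,f_end trajectory endpoints, Hz
#' @param duration seconds
#' @param source_level_db nominal band source level, dB re 1 uPa^2 m^2
#' @return object of class `call_template`
#' @export
call_template <- function(kind = c("fin20", "fin_hf", "zcall", "chorus"),
                          f_start = NULL, f_end = NULL, duration = NULL,
                          source_level_db = 180) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
                     fin20  = list(f_start = 28, f_end = 15, duration = 1),
                     fin_hf = list(f_start = 86, f_end = 86, duration = 1),
                     zcall  = list(f_start = 27, f_end = 19, duration = 3),
                     chorus = list(f_start = 30, f_end = 15, duration = 60))
  f_start <- if (is.null(f_start)) defaults$f_start else f_start
  f_end <- if (is.null(f_end)) defaults$f_end else f_end
  duration <- if (is.null(duration)) defaults$duration else duration
  if (duration <= 0) stop("duration must be positive")
  if (kind == "fin20" && !(f_start > f_end))
    stop("fin20 is a downsweep: f_start must exceed f_end")
  if (kind == "fin_hf") {
    fc <- (f_start + f_end) / 2
    if (fc < 84 || fc > 90)
      stop("fin_hf centre frequency must lie within 84-90 Hz")
  }
  structure(list(kind = kind, f_start = f_start, f_end = f_end,
                 duration = duration, source_level_db = source_level_db),
            class = "call_template")
}

#' Tukey (tapered cosine) window
#' @param n window length in samples
#' @param alpha total tapered fraction (default 0.2: 10% each end)
#' @return numeric window
#' @export
tukey_window <- function(n, alpha = 0.2) {
  if (alpha <= 0) return(rep(1, n))
  w <- rep(1, n)
  edge <- floor(alpha * (n - 1) / 2)
  if (edge > 0) {
    i <- 0:edge
    ramp <- 0.5 * (1 + cos(pi * (2 * i / (alpha * (n - 1)) - 1)))
    w[i + 1L] <- ramp
    w[n - i] <- ramp
  }
  w
}

#' Synthesise one call waveform
#'
#' Amplitude is set so the in-band mean-square over the call duration equals
#' `10^(snr_db/10) * noise_density * bandwidth`, i.e. `snr_db` is the band
#' SNR against an ambient floor of spectral density `noise_density`
#' (default: the density of unit-variance white noise, `1/(fs/2)`). With a
#' zero ambient floor in the receiving file and finite `snr_db`, the result
#' is the pure signal. Envelopes are Tukey-tapered (10% each end) to limit
#' spectral splatter into the bracing noise bands.
#'
#' @param template a [call_template()]
#' @param fs sampling rate, Hz; must exceed twice the highest template
#'   frequency
#' @param snr_db band SNR in dB relative to `noise_density`
#' @param noise_density reference one-sided noise density (linear units^2/Hz)
#' @return numeric waveform of `round(duration * fs)` samples
#' @export
synthesize_pulse <- function(template, fs, snr_db = 10,
                             noise_density = 1 / (fs / 2)) {
  stopifnot(inherits(template, "call_template"))
  f_hi <- max(template$f_start, template$f_end)
  if (fs <= 2 * f_hi)
    stop("sample rate ", fs, " Hz is below Nyquist for ", f_hi, " Hz")
  n <- as.integer(round(template$duration * fs))
  t <- (seq_len(n) - 1L) / fs
  band <- switch(template$kind,
                 fin20  = sort(c(template$f_end, template$f_start)),
                 fin_hf = (template$f_start + template$f_end) / 2 + c(-2, 2),
                 zcall  = sort(c(template$f_end, template$f_start)),
                 chorus = c(15, 30))
  core <- switch(
    template$kind,
    fin20 = {
      f0 <- template$f_start
      k <- (template$f_end - f0) / template$duration
      sin(2 * pi * (f0 * t + 0.5 * k * t^2))
    },
    fin_hf = sin(2 * pi * ((template$f_start + template$f_end) / 2) * t),
    zcall = {
      # bi-tonal surrogate: tone, downsweep, short terminal tone
      d <- template$duration
      t1 <- 0.5 * d
      t2 <- 0.85 * d
      f0 <- template$f_start
      f1 <- template$f_end
      inst <- ifelse(t < t1, f0,
                     ifelse(t < t2, f0 + (f1 - f0) * (t - t1) / (t2 - t1), f1))
      phase <- 2 * pi * cumsum(inst) / fs
      sin(phase)
    },
    chorus = bandlimited_noise(n, fs, c(15, 30)))
  x <- core * tukey_window(n, 0.2)
  target_ms <- 10^(snr_db / 10) * noise_density * diff(band)
  x * sqrt(target_ms / mean(x^2))
}

bandlimited_noise <- function(n, fs, band) {
  # exact band-limited Gaussian noise: white noise masked in the frequency
  # domain, so nothing bleeds into the bracing noise bands of a FIN index
  z <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency of each bin
  z[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(z, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Seasonal call-activity profile
#'
#' Expected number of 20-Hz pulses per 10-minute interval as a function of
#' day of year: a Gaussian-shaped season windowed to `[onset_day,
#' offset_day]` plus a small year-round background rate. The defaults place
#' the onset on 1 March (day 60), the peak on 12 May (day 132, 84 calls per
#' 10 min) and the offset in late July, after which calling vanishes into
#' the background rate - the seasonal shape the monitoring data exhibit.
#'
#' @param peak_day day of year of maximum activity
#' @param peak_rate expected calls per 10-min interval at the peak
#' @param sd_days Gaussian width of the season, days
#' @param onset_day,offset_day season window (profile is `background`
#'   outside)
#' @param background year-round background rate, calls per 10 min
#' @return object of class `seasonal_profile`
#' @export
seasonal_profile <- function(peak_day = 132, peak_rate = 84, sd_days = 28,
                             onset_day = 60, offset_day = 198,
                             background = 0.02) {
  stopifnot(peak_rate >= 0, sd_days > 0, onset_day <= peak_day,
            peak_day <= offset_day, background >= 0)
  structure(list(peak_day = peak_day, peak_rate = peak_rate,
                 sd_days = sd_days, onset_day = onset_day,
                 offset_day = offset_day, background = background),
            class = "seasonal_profile")
}

#' Evaluate a seasonal profile
#' @param profile a [seasonal_profile()]
#' @param day day of year (1-366) or POSIXct/Date
#' @return expected calls per 10-min interval
#' @export
profile_rate <- function(profile, day) {
  stopifnot(inherits(profile, "seasonal_profile"))
  if (inherits(day, "POSIXct") || inherits(day, "Date"))
    day <- as.integer(format(as.Date(day, tz = "UTC"), "%j"))
  in_season <- day >= profile$onset_day & day <= profile$offset_day
  rate <- profile$peak_rate *
    exp(-(day - profile$peak_day)^2 / (2 * profile$sd_days^2))
  ifelse(in_season, rate + profile$background, profile$background)
}

#' Null seasonal profile (no calling)
#' @return a [seasonal_profile()] with zero rate everywhere
#' @export
empty_profile <- function() {
  seasonal_profile(peak_rate = 0, background = 0)
}

#' Recording scenario configuration
#'
#' Describes one synthetic deployment. `aural_like` emulates a duty-cycled
#' recorder (5 min every hour, 5-min files, 32768 Hz); `sonovault_like`
#' emulates a continuous recorder (10-min files, 5333 Hz). `sample_rate` and
#' `file_duration_s` may be overridden to run reduced-size scenarios with the
#' same statistical structure.
#'
#' Chorus model: distant callers are drawn per file as
#' `Poisson(distant_ratio * rate10)` where `rate10` is the profile's expected
#' calls per 10 min; they contribute sustained band-limited noise in the
#' 15-30 Hz band and (for the accompanying higher-frequency component) in
#' the 84.5-89.5 Hz band, with in-band density `chorus_gain * N_distant`
#' times the ambient density. The gain default puts the band SNR in the
#' chorus-dominated regime across the season so that band SNR tracks call
#' abundance linearly (the source-counting level relation); the absolute
#' peak index value of any one deployment is not a generator target.
#'
#' @param recorder `"aural_like"` or `"sonovault_like"`
#' @param sample_rate Hz; defaults to 32768 (aural) / 5333 (sonovault)
#' @param file_duration_s stored file length; defaults 300 / 600 s
#' @param duty `(record_minutes, period_minutes)`; defaults `c(5, 60)` /
#'   continuous
#' @param start,end UTC deployment limits
#' @param noise_sd ambient white-noise standard deviation, counts
#' @param calibration a [calibration_spec()]
#' @param snr_range per-event band SNR range (dB), sampled uniformly
#' @param hf_component logical: accompany each fin20 pulse with an 86 Hz
#'   component
#' @param hf_freq HF-component frequency, Hz
#' @param hf_snr_offset_db HF-component SNR relative to its pulse
#' @param distant_ratio distant-to-counted caller ratio for the chorus model
#' @param chorus_gain in-band chorus density per distant caller, in units of
#'   ambient density
#' @param zcall_rate_per_10min expected blue whale Z-calls per 10 min
#' @param storm_schedule data.frame (`start` POSIXct, `duration_s`,
#'   `excess_db`) of broadband noise transients
#' @param simulate_gaps also draw (unrecorded) events in duty-cycle gaps
#' @param seed RNG seed
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(recorder = c("aural_like", "sonovault_like"),
                            sample_rate = NULL, file_duration_s = NULL,
                            duty = NULL,
                            start = as.POSIXct("2013-01-16 00:00:00", tz = "UTC"),
                            end = as.POSIXct("2013-01-17 00:00:00", tz = "UTC"),
                            noise_sd = 200, calibration = calibration_spec(),
                            snr_range = c(10, 20), hf_component = TRUE,
                            hf_freq = 86, hf_snr_offset_db = -3,
                            distant_ratio = 1, chorus_gain = 2.4,
                            zcall_rate_per_10min = 0,
                            storm_schedule = NULL, simulate_gaps = FALSE,
                            seed = 1L) {
  recorder <- match.arg(recorder)
  if (is.null(sample_rate))
    sample_rate <- if (recorder == "aural_like") 32768 else 5333
  if (is.null(file_duration_s))
    file_duration_s <- if (recorder == "aural_like") 300 else 600
  if (is.null(duty))
    duty <- if (recorder == "aural_like") c(5, 60) else
      c(file_duration_s / 60, file_duration_s / 60)
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(end > start)) stop("scenario end must be after start")
  if (duty[1] > duty[2]) stop("duty record must not exceed period")
  structure(list(recorder = recorder, sample_rate = sample_rate,
                 file_duration_s = file_duration_s, duty = duty,
                 start = start, end = end, noise_sd = noise_sd,
                 calibration = calibration, snr_range = snr_range,
                 hf_component = hf_component, hf_freq = hf_freq,
                 hf_snr_offset_db = hf_snr_offset_db,
                 distant_ratio = distant_ratio, chorus_gain = chorus_gain,
                 zcall_rate_per_10min = zcall_rate_per_10min,
                 storm_schedule = storm_schedule,
                 simulate_gaps = simulate_gaps, seed = as.integer(seed)),
            class = "scenario_config")
}

add_events <- function(x, fs, events, noise_density) {
  n <- length(x)
  for (i in seq_len(nrow(events))) {
    tmpl <- call_template(events$kind[i])
    nd_i <- if (length(noise_density) > 1L)
      noise_density[[events$kind[i]]] else noise_density
    w <- synthesize_pulse(tmpl, fs, events$snr_db[i], nd_i)
    s <- events$sample_index[i]
    e <- min(n, s + length(w) - 1L)
    x[s:e] <- x[s:e] + w[seq_len(e - s + 1L)]
  }
  x
}

#' Synthesise a duty-cycled recording set with ground truth
#'
#' Writes one 16-bit PCM WAV file per scheduled recording interval and
#' returns both the file manifest and a ground-truth event log. Per-interval
#' fin whale call counts are Poisson draws from the seasonal profile; each
#' pulse may carry an 86 Hz component; Z-calls, a rate-proportional chorus
#' and scheduled storm transients are injected per the configuration. The
#' run is fully determined by `config` (including its seed).
#'
#' @param config a [scenario_config()]
#' @param profile a [seasonal_profile()]
#' @param outdir directory for the WAV files (created if needed)
#' @return list with `manifest` (file_id, path, start_utc, fs, n_samples)
#'   and `log` (event_time_utc, kind, file_id, sample_index, snr_db,
#'   recorded)
#' @export
synthesize_recording_set <- function(config, profile, outdir = tempfile("synth")) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(profile, "seasonal_profile"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  schedule <- recording_schedule(config$start, config$end,
                                 config$file_duration_s, config$duty)
  files <- enumerate_files(schedule)
  fs <- config$sample_rate
  n <- as.integer(round(config$file_duration_s * fs))
  nd <- config$noise_sd^2 / (fs / 2)  # ambient one-sided density, counts^2/Hz
  file_min <- config$file_duration_s / 60
  set.seed(config$seed)
  logs <- vector("list", nrow(files))
  paths <- character(nrow(files))
  # chorus bands sit clear of the FIN noise bands: with 2-Hz analysis bins
  # the Welch main lobe spans +/-4 Hz, so chorus edges are kept >= 3.5 Hz
  # away from the bracing noise bands
  hf_centre_band <- config$hf_freq + 1 + c(-1.5, 1.5)
  lf_chorus_band <- c(16, 29)
  for (j in seq_len(nrow(files))) {
    t0 <- files$start_utc[j]
    rate10 <- profile_rate(profile, t0)
    x <- stats::rnorm(n, sd = config$noise_sd)
    # storm transients: broadband excess noise over the overlap
    if (!is.null(config$storm_schedule)) {
      for (k in seq_len(nrow(config$storm_schedule))) {
        st <- as.POSIXct(config$storm_schedule$start[k], tz = "UTC")
        en <- st + config$storm_schedule$duration_s[k]
        o1 <- max(0, as.numeric(st - t0, units = "secs"))
        o2 <- min(config$file_duration_s, as.numeric(en - t0, units = "secs"))
        if (o2 > o1) {
          idx <- (floor(o1 * fs) + 1L):floor(o2 * fs)
          extra <- config$noise_sd *
            10^(config$storm_schedule$excess_db[k] / 20)
          x[idx] <- x[idx] + stats::rnorm(length(idx), sd = extra)
        }
      }
    }
    # chorus of distant callers, proportional to the seasonal rate
    n_distant <- stats::rpois(1L, config$distant_ratio * rate10)
    dens <- config$chorus_gain * n_distant * nd
    if (n_distant > 0) {
      lf <- bandlimited_noise(n, fs, lf_chorus_band) *
        sqrt(dens * diff(lf_chorus_band))
      x <- x + lf
      if (config$hf_component) {
        hf <- bandlimited_noise(n, fs, hf_centre_band) *
          sqrt(dens * diff(hf_centre_band))
        x <- x + hf
      }
    }
    # countable (individually recognisable) events must stand out of the
    # current in-band background, so event SNR references ambient + chorus
    bg <- list(fin20 = nd + dens, zcall = nd + dens,
               fin_hf = nd + if (config$hf_component) dens else 0)
    # countable events
    n_calls <- stats::rpois(1L, rate10 * file_min / 10)
    n_z <- stats::rpois(1L, config$zcall_rate_per_10min * file_min / 10)
    ev <- data.frame(kind = c(rep("fin20", n_calls), rep("zcall", n_z)),
                     snr_db = stats::runif(n_calls + n_z,
                                           config$snr_range[1],
                                           config$snr_range[2]))
    if (nrow(ev) > 0L) {
      dur <- vapply(ev$kind, function(k) call_template(k)$duration, 1)
      # 20-Hz pulses come in regular sequences (song): spread the Poisson
      # count quasi-periodically over the file instead of i.i.d.-uniform,
      # so pulses of one bout do not overlap
      ne <- nrow(ev)
      u <- (sample.int(ne) - stats::runif(ne, 0.15, 0.85)) / ne
      ev$sample_index <- 1L + floor(u * pmax(1, n - ceiling(dur * fs)))
      x <- add_events(x, fs, ev, bg)
      if (config$hf_component && n_calls > 0L) {
        hf_ev <- ev[ev$kind == "fin20", , drop = FALSE]
        hf_ev$kind <- "fin_hf"
        hf_ev$snr_db <- hf_ev$snr_db + config$hf_snr_offset_db
        x <- add_events(x, fs, hf_ev, bg)
      }
      ev$event_time_utc <- t0 + (ev$sample_index - 1L) / fs
      ev$file_id <- files$file_id[j]
      ev$recorded <- TRUE
      logs[[j]] <- ev
    }
    # events emitted during the duty-cycle gap of this period (unrecorded)
    if (config$simulate_gaps && config$duty[1] < config$duty[2]) {
      gap_min <- config$duty[2] - config$duty[1]
      n_gap <- stats::rpois(1L, rate10 * gap_min / 10)
      if (n_gap > 0L) {
        gt <- t0 + config$file_duration_s +
          stats::runif(n_gap) * gap_min * 60
        logs[[j]] <- rbind(logs[[j]],
                           data.frame(kind = "fin20",
                                      snr_db = stats::runif(n_gap,
                                                            config$snr_range[1],
                                                            config$snr_range[2]),
                                      sample_index = NA_integer_,
                                      event_time_utc = gt,
                                      file_id = NA_character_,
                                      recorded = FALSE))
      }
    }
    paths[j] <- file.path(outdir, files$file_id[j])
    write_wav_pcm16(x, fs, paths[j])
  }
  log <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  if (is.null(log))
    log <- data.frame(kind = character(), snr_db = numeric(),
                      sample_index = integer(),
                      event_time_utc = as.POSIXct(character(), tz = "UTC"),
                      file_id = character(), recorded = logical())
  log <- log[order(log$event_time_utc),
             c("event_time_utc", "kind", "file_id", "sample_index",
               "snr_db", "recorded")]
  rownames(log) <- NULL
  manifest <- data.frame(file_id = files$file_id, path = paths,
                         start_utc = files$start_utc, fs = fs,
                         n_samples = n)
  list(manifest = manifest, log = log, outdir = outdir)
}

#' Synthesise ADCP ensembles with a diel vertical migration signal
#'
#' Upward-looking profiler emulation: ensembles every 225 min (45 pings at
#' 5-min interval), echo intensity on the 0-255 count scale, a Gaussian
#' scattering layer whose centre depth oscillates with a 24-h period
#' (deepest at local noon) and the stated migration amplitude.
#'
#' @param days number of days to simulate
#' @param dvm_amplitude noon-minus-midnight layer-depth amplitude, m
#' @param seed RNG seed
#' @param start first ensemble time (UTC)
#' @param instrument_depth m
#' @param bin_size bin length along the beam, m (first bin 24.52 m)
#' @param mid_depth mean layer-centre depth, m
#' @param layer_width Gaussian layer width, m
#' @param layer_gain layer peak excess, counts
#' @param noise_sd count noise s.d.
#' @param utc_offset_s local-time offset used for the diel phase (default
#'   the deployment's UTC - 3 h 40 min)
#' @return data.frame: `time_utc`, `ensemble`, `Tx`, `R` (range along beam,
#'   m), `depth` (m), `E` (counts); ensemble cadence in attribute
#'   `cadence_min`
#' @export
synthesize_adcp <- function(days, dvm_amplitude = 100, seed = 1L,
                            start = as.POSIXct("2013-01-16 00:00:00", tz = "UTC"),
                            instrument_depth = 314, bin_size = 16,
                            mid_depth = 110, layer_width = 25,
                            layer_gain = 120, noise_sd = 4,
                            utc_offset_s = -13200) {
  stopifnot(dvm_amplitude >= 0, days > 0)
  set.seed(as.integer(seed))
  cadence_s <- 225 * 60
  times <- seq(from = start, by = cadence_s,
               length.out = floor(days * 86400 / cadence_s))
  R <- c(24.52, 24.52 + bin_size * seq_len(16L))
  depth <- instrument_depth - R
  keep <- depth > 5
  R <- R[keep]
  depth <- depth[keep]
  out <- vector("list", length(times))
  for (i in seq_along(times)) {
    lt <- times[i] + utc_offset_s
    hour <- as.numeric(format(lt, "%H")) + as.numeric(format(lt, "%M")) / 60
    centre <- mid_depth + (dvm_amplitude / 2) * cos(2 * pi * (hour - 12) / 24)
    E <- 60 + layer_gain * exp(-(depth - centre)^2 / (2 * layer_width^2)) +
      stats::rnorm(length(depth), sd = noise_sd)
    E <- pmin(255, pmax(0, round(E)))
    out[[i]] <- data.frame(time_utc = times[i], ensemble = i,
                           Tx = 0.5 + 1.5 * sin(2 * pi * (i / length(times))),
                           R = R, depth = depth, E = E)
  }
  res <- do.call(rbind, out)
  attr(res, "cadence_min") <- cadence_s / 60
  attr(res, "truth") <- list(dvm_amplitude = dvm_amplitude,
                             mid_depth = mid_depth)
  res
}

#' Synthesise a daily gridded sea-ice concentration field
#'
#' Square grid of `grid_spacing`-km pixels centred on the site, daily fields
#' with an austral-winter (peak ~1 September) seasonal envelope scaled by
#' `winter_peak_fraction`, a mild southeastward spatial gradient and seeded
#' pixel noise; concentrations clipped to [0, 100] %.
#'
#' @param days number of daily fields
#' @param winter_peak_fraction 0-1 scaling of the winter maximum
#' @param grid_spacing pixel size, km (default 6.25)
#' @param start_date first day
#' @param site `c(lat, lon)` of the recording site, degrees
#' @param half_extent_km grid half-width, km
#' @param peak_day day of year of the ice maximum
#' @param sd_days seasonal envelope width, days
#' @param noise_sd pixel noise s.d., percentage points
#' @param seed RNG seed
#' @return object of class `ice_field`: `dates`, `lat`/`lon` pixel-centre
#'   matrices and `conc` array (nx, ny, days) in %
#' @export
synthesize_ice_field <- function(days, winter_peak_fraction = 0.6,
                                 grid_spacing = 6.25,
                                 start_date = as.Date("2013-01-16"),
                                 site = c(-61.0147, -55.9755),
                                 half_extent_km = 62.5,
                                 peak_day = 244, sd_days = 35,
                                 noise_sd = 3, seed = 1L) {
  stopifnot(winter_peak_fraction >= 0, winter_peak_fraction <= 1)
  set.seed(as.integer(seed))
  km <- seq(-half_extent_km, half_extent_km, by = grid_spacing)
  dx <- outer(km, rep(1, length(km)))   # east offsets, km
  dy <- outer(rep(1, length(km)), km)   # north offsets, km
  lat <- site[1] + dy / 110.574
  lon <- site[2] + dx / (111.320 * cos(site[1] * pi / 180))
  dates <- start_date + seq_len(days) - 1L
  doy <- as.integer(format(dates, "%j"))
  seasonal <- exp(-(doy - peak_day)^2 / (2 * sd_days^2))
  # more ice towards the southeast of the site
  spatial <- 1 + 0.3 * (dx - dy) / (2 * half_extent_km)
  conc <- array(0, dim = c(length(km), length(km), days))
  for (d in seq_len(days)) {
    f <- 100 * winter_peak_fraction * seasonal[d] * spatial
    if (winter_peak_fraction > 0)
      f <- f + stats::rnorm(length(f), sd = noise_sd * seasonal[d])
    conc[, , d] <- pmin(100, pmax(0, f))
  }
  structure(list(dates = dates, lat = lat, lon = lon, conc = conc,
                 site = site, grid_spacing = grid_spacing),
            class = "ice_field")
}
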