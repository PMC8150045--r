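test_that("synthesised downsweep hits its frequency endpoints", {
  fs <- 512
  w <- synthesize_pulse(call_template("fin20"), fs, snr_db = 40)
  expect_length(w, fs)
  # instantaneous frequency via the analytic (Hilbert) phase of the clean
  # chirp, fitted over the untapered interior and extrapolated to 0 and 1 s
  n <- length(w)
  z <- fft(w)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  analytic <- fft(z * h, inverse = TRUE) / n
  phase <- cumsum(c(0, Arg(analytic[-1] / analytic[-n])))  # unwrapped
  inst_f <- diff(phase) * fs / (2 * pi)
  t_mid <- (seq_len(n - 1) - 0.5) / fs
  interior <- t_mid > 0.15 & t_mid < 0.85
  fit <- lm(inst_f[interior] ~ t_mid[interior])
  f_start_hat <- unname(coef(fit)[1])
  f_end_hat <- unname(coef(fit)[1] + coef(fit)[2])
  expect_lt(abs(f_start_hat - 28), 0.5)
  expect_lt(abs(f_end_hat - 15), 0.5)
  # energy concentrated in the 15-30 Hz band when no noise is added
  p <- welch_psd(c(w, numeric(fs)), psd_config(256, "hann", 0.5, fs))
  inband <- sum(p$density[p$freq >= 13 & p$freq <= 30])
  expect_gt(inband / sum(p$density), 0.9)
})

test_that("HF component synthesis peaks at 86 Hz at 1-Hz resolution", {
  fs <- 512
  w <- synthesize_pulse(call_template("fin_hf"), fs, snr_db = 30)
  p <- welch_psd(c(w, numeric(fs)), psd_config(512, "hann", 0.5, fs))
  expect_equal(p$freq[which.max(p$density)], 86)
})

test_that("pulse SNR scaling sets the in-band mean square", {
  fs <- 500
  nd <- 1 / (fs / 2)
  for (snr in c(0, 10, 20)) {
    w <- synthesize_pulse(call_template("fin20"), fs, snr, nd)
    target <- 10^(snr / 10) * nd * 13  # 15-28 Hz band width
    expect_equal(mean(w^2), target, tolerance = 1e-9)
  }
  expect_error(synthesize_pulse(call_template("fin20"), 40, 10), "Nyquist")
})

test_that("call templates enforce their structural invariants", {
  expect_error(call_template("fin20", f_start = 15, f_end = 28), "downsweep")
  expect_error(call_template("fin_hf", f_start = 95, f_end = 95), "84-90")
  expect_error(call_template("fin20", duration = 0), "positive")
  z <- call_template("zcall")
  expect_gt(z$f_start, z$f_end)
})

test_that("recording-set synthesis follows the duty-cycle schedule", {
  prof <- seasonal_profile()
  cfg <- scenario_config("aural_like", sample_rate = 256, file_duration_s = 10,
                         duty = c(10 / 60, 60), seed = 2,
                         start = utc("2013-05-01"), end = utc("2013-05-02"))
  synth <- synthesize_recording_set(cfg, prof, tempfile())
  expect_equal(nrow(synth$manifest), 24)
  expect_true(all(file.exists(synth$manifest$path)))
  # empty profile -> empty ground-truth log
  cfg0 <- scenario_config("aural_like", sample_rate = 256, file_duration_s = 10,
                          duty = c(10 / 60, 60), seed = 2, distant_ratio = 0,
                          start = utc("2013-05-01"), end = utc("2013-05-02"))
  synth0 <- synthesize_recording_set(cfg0, empty_profile(), tempfile())
  expect_equal(nrow(synth0$log), 0)
  expect_error(scenario_config(start = utc("2013-01-02"),
                               end = utc("2013-01-01")), "after start")
})

test_that("identical configurations produce byte-identical WAV output", {
  prof <- seasonal_profile()
  cfg <- scenario_config("sonovault_like", sample_rate = 500,
                         file_duration_s = 30, duty = c(0.5, 360), seed = 11,
                         start = utc("2013-05-01"), end = utc("2013-05-03"))
  a <- synthesize_recording_set(cfg, prof, tempfile())
  b <- synthesize_recording_set(cfg, prof, tempfile())
  expect_equal(a$log, b$log)
  for (j in seq_len(nrow(a$manifest)))
    expect_identical(readBin(a$manifest$path[j], raw(), 1e6),
                     readBin(b$manifest$path[j], raw(), 1e6))
})

test_that("per-interval call counts have the Poisson structure of the profile", {
  # fixed-rate profile: flat season covering the whole window
  prof <- seasonal_profile(peak_day = 100, peak_rate = 6, sd_days = 1e6,
                           onset_day = 1, offset_day = 366, background = 0)
  cfg <- scenario_config("sonovault_like", sample_rate = 128,
                         file_duration_s = 600, duty = c(10, 10), seed = 13,
                         distant_ratio = 0, hf_component = FALSE,
                         start = utc("2013-04-01"),
                         end = utc("2013-04-01") + 1050 * 600)
  synth <- synthesize_recording_set(cfg, prof, tempfile())
  n_int <- nrow(synth$manifest)
  expect_gte(n_int, 1000)
  counts <- table(factor(synth$log$file_id, levels = synth$manifest$file_id))
  lambda <- profile_rate(prof, utc("2013-04-15"))
  se <- sqrt(lambda / n_int)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("ground-truth events land inside their files, gap events are flagged", {
  prof <- seasonal_profile(peak_day = 130, peak_rate = 30)
  cfg <- scenario_config("aural_like", sample_rate = 256, file_duration_s = 60,
                         duty = c(1, 10), seed = 5, simulate_gaps = TRUE,
                         start = utc("2013-05-10"),
                         end = utc("2013-05-10 06:00:00"))
  synth <- synthesize_recording_set(cfg, prof, tempfile())
  rec <- synth$log[synth$log$recorded, ]
  expect_true(all(rec$sample_index >= 1 &
                    rec$sample_index <= 60 * 256))
  expect_true(all(rec$file_id %in% synth$manifest$file_id))
  gaps <- synth$log[!synth$log$recorded, ]
  expect_gt(nrow(gaps), 0)
  # unrecorded events fall in duty-cycle gaps: not within any recorded minute
  starts <- synth$manifest$start_utc
  infile <- vapply(gaps$event_time_utc, function(tt)
    any(tt >= starts & tt < starts + 60), logical(1))
  expect_false(any(infile))
})

test_that("ADCP synthesis has the deployment cadence and count range", {
  adcp <- synthesize_adcp(5, dvm_amplitude = 80, seed = 2)
  expect_equal(attr(adcp, "cadence_min"), 225)
  tt <- unique(adcp$time_utc)
  expect_equal(as.numeric(diff(tt)[1], units = "mins"), 225)
  expect_equal(length(tt), 32)  # 5 days / 3.75 h
  expect_true(all(adcp$E >= 0 & adcp$E <= 255))
  expect_true(all(diff(unique(adcp$R)) > 0))
})

test_that("ice fields are bounded, seasonal and deterministic", {
  ice0 <- synthesize_ice_field(10, winter_peak_fraction = 0, seed = 1)
  expect_true(all(ice0$conc == 0))
  ice <- synthesize_ice_field(40, winter_peak_fraction = 0.8, seed = 4,
                              start_date = as.Date("2013-08-15"))
  expect_true(all(ice$conc >= 0 & ice$conc <= 100))
  expect_gt(max(ice$conc), 10)
  ice_b <- synthesize_ice_field(40, winter_peak_fraction = 0.8, seed = 4,
                                start_date = as.Date("2013-08-15"))
  expect_identical(ice$conc, ice_b$conc)
})
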