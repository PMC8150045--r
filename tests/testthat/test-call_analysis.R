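test_that("detector recovers seeded pulses and stays silent on noise", {
  f <- pulse_file(snr_db = 12, n_pulses = 8, seed = 21)
  d <- detect_pulses(f$x, f$fs)
  expect_equal(nrow(d), 8)
  expect_equal(match_detections(d$time_s, f$t), 8)
  expect_true(all(d$class == "fin20"))
  # silence and pure noise yield empty detection lists
  set.seed(22)
  expect_equal(nrow(detect_pulses(rnorm(60 * 500), 500)), 0)
  expect_equal(nrow(detect_pulses(numeric(60 * 500), 500)), 0)
  expect_error(detect_pulses(rnorm(100), 500), "at least 2 s")
})

test_that("detector recall degrades towards low SNR, not high", {
  run <- function(snr) {
    matched <- 0L
    for (seed in 1:6) {
      f <- pulse_file(snr_db = snr, n_pulses = 8, seed = 30 + seed)
      matched <- matched + match_detections(detect_pulses(f$x, f$fs)$time_s, f$t)
    }
    matched / 48
  }
  expect_gt(run(18), run(4))
})

test_that("Z-calls are never logged as fin whale pulses", {
  fs <- 500
  set.seed(23)
  x <- rnorm(60 * fs)
  nd <- 1 / (fs / 2)
  for (s in seq(5 * fs, 50 * fs, by = 9 * fs)) {
    w <- synthesize_pulse(call_template("zcall"), fs, 15, nd)
    x[s:(s + length(w) - 1)] <- x[s:(s + length(w) - 1)] + w
  }
  expect_equal(nrow(detect_pulses(x, fs)), 0)
  cand <- detect_pulses(x, fs, keep_all = TRUE)
  expect_gt(nrow(cand), 0)
  expect_false(any(cand$class == "fin20"))
  expect_gte(mean(cand$class == "zcall"), 0.5)
})

test_that("ridge classification applies the discrimination rules", {
  hop <- 0.067
  sweep <- data.frame(t = seq(0, 1, by = hop))
  sweep$f <- 28 - 13 * sweep$t
  expect_equal(classify_event(sweep), "fin20")
  zt <- seq(0, 2.5, by = hop)
  zr <- data.frame(t = zt, f = ifelse(zt < 2, 27, 19))
  expect_equal(classify_event(zr), "zcall")
  # unresolvable ridge within a sustained band -> chorus
  none <- data.frame(t = numeric(), f = numeric())
  expect_equal(classify_event(none, band_elevation_s = 120), "chorus")
  expect_equal(classify_event(none), "other")
  # an upsweep is not a 20-Hz pulse
  up <- data.frame(t = sweep$t, f = rev(sweep$f))
  expect_equal(classify_event(up), "other")
})

test_that("sustained 15-30 Hz bands are flagged as chorus, short ones not", {
  fs <- 500
  set.seed(24)
  n <- 180 * fs
  x <- rnorm(n)
  x[1:(120 * fs)] <- x[1:(120 * fs)] +
    3 * synthesize_pulse(call_template("chorus", duration = 120), fs, 10)
  ch <- detect_chorus(x, fs)
  expect_equal(nrow(ch), 1)
  expect_lt(ch$start_s[1], 5)
  expect_gt(ch$end_s[1], 110)
  expect_equal(nrow(detect_chorus(rnorm(n), fs)), 0)
})

test_that("interval counting censors merged calls and gates noisy files", {
  f <- pulse_file(snr_db = 14, n_pulses = 6, seed = 25)
  iv <- count_interval(f$x, f$fs, utc("2013-05-01 03:00:00"), "a.wav",
                       censor_limit = 4)
  expect_true(iv$censored)
  expect_equal(iv$n_calls, 4)  # reported as the lower bound
  iv2 <- count_interval(f$x, f$fs, utc("2013-05-01 03:00:00"), "a.wav")
  expect_false(iv2$censored)
  expect_equal(iv2$n_calls, 6)
  # a storm-level file is excluded and its count withheld
  set.seed(26)
  storm <- rnorm(60 * 500, sd = 30)
  iv3 <- count_interval(storm, 500, utc("2013-08-01"), "s.wav",
                        noise_gate_db = band_level_db(f$x, f$fs) + 3)
  expect_true(iv3$excluded)
  expect_true(is.na(iv3$n_calls))
  # the out-of-band gate does not exclude a chorus-rich file
  chor <- f$x + 10 * synthesize_pulse(call_template("chorus", duration = 60),
                                      500, 10)
  expect_lt(band_level_db(chor, 500) - band_level_db(f$x, f$fs), 1)
})

test_that("call abundance pools counted minutes and skips unusable files", {
  iv <- data.frame(file_id = letters[1:5],
                   start_utc = utc("2013-05-12") + 0:4 * 4200,
                   duration_s = 600,
                   n_calls = c(50, 40, 100, NA, 10),
                   censored = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                   excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(cab(iv), (50 + 40 + 10) / 30 * 60)
  expect_equal(round(cab(data.frame(file_id = "x", start_utc = utc("2013-05-12"),
                                    duration_s = 60000, n_calls = 4301,
                                    censored = FALSE, excluded = FALSE))), 258)
  expect_equal(cab(iv[5, ]), 60)  # 10 calls in 10 min
  # invariant under reordering
  expect_equal(cab(iv[sample(5), ]), cab(iv))
  allbad <- iv[3:4, ]
  expect_error(cab(allbad), "no usable")
})

test_that("daily occurrence stops at the first pulse and ignores chorus", {
  fs <- 500
  dir <- tempfile("dao")
  dir.create(dir)
  set.seed(27)
  reads <- new.env()
  reads$n <- 0L
  counting_reader <- function(path) {
    reads$n <- reads$n + 1L
    read_wav_pcm16(path)
  }
  paths <- file.path(dir, sprintf("f%d.wav", 1:5))
  for (j in 1:5) {
    x <- rnorm(30 * fs)
    if (j == 3) {
      f <- pulse_file(snr_db = 15, n_pulses = 3, dur_s = 30, seed = 40)
      x <- f$x
    }
    write_wav_pcm16(x * 100, fs, paths[j])
  }
  man <- data.frame(path = paths, start_utc = utc("2013-05-02") + 0:4 * 3600)
  res <- daily_occurrence(man, reader = counting_reader)
  expect_true(res$present)
  expect_equal(res$files_scanned, 3)
  expect_equal(reads$n, 3L)  # files 4 and 5 never read (lazy contract)
  expect_equal(as.Date(res$date), as.Date("2013-05-02"))
  # chorus-only day stays absent
  for (j in 1:5) {
    set.seed(50 + j)
    ch <- rnorm(30 * fs) + 8 * synthesize_pulse(
      call_template("chorus", duration = 30), fs, 10)
    write_wav_pcm16(ch * 100, fs, paths[j])
  }
  res2 <- daily_occurrence(man)
  expect_false(res2$present)
  expect_true(is.na(res2$first_detection_utc))
  expect_equal(res2$files_scanned, 5)
})

test_that("detector performance accounting matches a hand count", {
  cfg <- scenario_config("sonovault_like", sample_rate = 500,
                         file_duration_s = 60, duty = c(1, 30),
                         distant_ratio = 0, seed = 28,
                         start = utc("2013-05-01"),
                         end = utc("2013-05-01 10:00:00"))
  synth <- synthesize_recording_set(cfg, seasonal_profile(), tempfile())
  perf <- detector_performance(synth$manifest, synth$log)
  expect_equal(perf$n_truth,
               sum(synth$log$kind == "fin20" & synth$log$recorded))
  expect_lte(perf$n_matched, perf$n_detected)
  expect_lte(perf$n_matched, perf$n_truth)
  expect_gt(perf$recall, 0.8)
  expect_gt(perf$precision, 0.8)
})
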