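test_that("Welch density is flat for white noise and normalised per Hz", {
  set.seed(4)
  fs <- 1024
  x <- rnorm(2^17, sd = 3)
  p <- welch_psd(x, psd_config(1024, "hann", 0.5, fs))
  band <- p$freq >= 10 & p$freq <= 100
  # unit-variance white noise has one-sided density 1/(fs/2)
  expected <- 9 / (fs / 2)
  expect_lt(max(abs(10 * log10(p$density[band] / expected))), 1)
})

test_that("Welch estimate satisfies Parseval and locates a pure tone", {
  set.seed(5)
  fs <- 1024
  x <- rnorm(2^16)
  cfg <- psd_config(512, "hamming", 0.5, fs)
  p <- welch_psd(x, cfg)
  df <- fft_resolution(cfg)
  expect_equal(sum(p$density) * df, var(x), tolerance = 0.05)
  t <- (0:(2^15 - 1)) / fs
  tone <- sin(2 * pi * 86 * t)
  p2 <- welch_psd(tone, psd_config(512, "hann", 0.5, fs))  # 2 Hz bins
  expect_equal(p2$freq[which.max(p2$density)], 86)
  expect_error(welch_psd(rnorm(100), cfg), "shorter")
})

test_that("Welch variance shrinks as more segments are averaged", {
  fs <- 512
  spread <- function(nseg) {
    vapply(1:12, function(s) {
      set.seed(s)
      p <- welch_psd(rnorm(nseg * 256), psd_config(256, "hann", 0, fs))
      mean(p$density[p$freq >= 50 & p$freq <= 200])
    }, numeric(1))
  }
  expect_lt(sd(spread(64)), sd(spread(4)))
})

test_that("FFT resolution matches the analysis-chain configurations", {
  expect_equal(fft_resolution(psd_preset("lts_fin")), 2.0)
  expect_equal(round(fft_resolution(psd_preset("dao")), 1), 1.6)
  expect_equal(fft_resolution(psd_config(500, "hann", 0.5, 500)), 1.0)
})

test_that("quietest-window selection minimises broadband energy", {
  fs <- 500
  # constant amplitude: earliest offset wins the tie
  x <- rep(1, 30 * fs)
  expect_equal(quietest_window(x, fs)$offset_s, 0)
  # a loud 5-s transient is excluded from the selected window
  set.seed(6)
  y <- rnorm(30 * fs)
  y[(10 * fs):(15 * fs)] <- y[(10 * fs):(15 * fs)] * 20
  qw <- quietest_window(y, fs)
  expect_true(qw$offset_s + 10 <= 10 || qw$offset_s >= 15)
  expect_error(quietest_window(rnorm(fs), fs), "shorter")
})

test_that("quietest window equals the brute-force search over all hops", {
  fs <- 250
  brute <- function(x, w, h) {
    offs <- seq(0, length(x) - w, by = h)
    ms <- vapply(offs, function(o) mean(x[(o + 1):(o + w)]^2), numeric(1))
    offs[which.min(ms)]
  }
  for (seed in 1:50) {
    set.seed(seed)
    x <- rnorm(20 * fs) * (1 + 0.5 * sin(2 * pi * seq_len(20 * fs) / (7 * fs)))
    qw <- quietest_window(x, fs, window_s = 10, hop_s = 1)
    expect_equal(qw$offset_samples, brute(x, 10 * fs, fs))
  }
})

test_that("quietest-window choice ignores loud energy outside the window", {
  fs <- 250
  set.seed(7)
  x <- rnorm(25 * fs)
  base <- quietest_window(x, fs)
  y <- x
  out <- setdiff(seq_along(x), (base$offset_samples + 1):(base$offset_samples + 10 * fs))
  y[out[1:fs]] <- y[out[1:fs]] + 50
  expect_equal(quietest_window(y, fs)$offset_samples, base$offset_samples)
})

test_that("LTS assembly yields one PSD column per selected readable file", {
  dir <- tempfile("lts")
  cfg <- scenario_config("aural_like", sample_rate = 512, file_duration_s = 15,
                         duty = c(0.25, 120), seed = 3,
                         start = utc("2013-05-01"), end = utc("2013-05-02"))
  synth <- synthesize_recording_set(cfg, seasonal_profile(), dir)
  pcfg <- psd_config(256, "hamming", 0.5, 512)
  lts <- build_lts(synth$manifest, pcfg, window_s = 10)
  expect_equal(ncol(lts$density), nrow(synth$manifest))
  expect_equal(length(lts$freq), 129)
  # all-files and every-second-file schemes agree at shared timestamps
  lts2 <- build_lts(synth$manifest, pcfg, subsampling_scheme(2, 1),
                    window_s = 10)
  shared <- match(lts2$time, lts$time)
  expect_equal(lts2$density, lts$density[, shared])
  # unreadable file becomes an NA gap column, not an interpolation
  m <- synth$manifest
  m$path[3] <- file.path(dir, "missing.wav")
  expect_warning(lts3 <- build_lts(m, pcfg, window_s = 10), "skipping")
  expect_true(all(is.na(lts3$density[, 3])))
  expect_equal(lts3$density[, -3], lts$density[, -3])
})
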