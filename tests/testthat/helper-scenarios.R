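# shared fixture builders; everything is generated in code at test time

utc <- function(x) as.POSIXct(x, tz = "UTC")

# a one-day continuous 500 Hz scenario with 60-s files (reduced-size
# SonoVault emulation), rate taken from the seasonal profile at `date`
day_scenario <- function(date = "2013-05-01", seed = 1, hours = 24,
                         distant_ratio = 1, zcall_rate = 0) {
  scenario_config("sonovault_like", sample_rate = 500, file_duration_s = 60,
                  duty = c(1, 10),
                  start = utc(paste(date, "00:00:00")),
                  end = utc(paste(date, "00:00:00")) + hours * 3600,
                  distant_ratio = distant_ratio,
                  zcall_rate_per_10min = zcall_rate, seed = seed)
}

# white noise with quasi-regular fin20 pulses at a fixed band SNR;
# returns the series and true start times (seconds)
pulse_file <- function(fs = 500, dur_s = 60, n_pulses = 8, snr_db = 12,
                       seed = 1) {
  set.seed(seed)
  n <- dur_s * fs
  x <- stats::rnorm(n)
  nd <- 1 / (fs / 2)
  starts <- sort(sample(seq(2 * fs, n - 3 * fs, by = 2 * fs), n_pulses))
  for (s in starts) {
    w <- synthesize_pulse(call_template("fin20"), fs, snr_db, nd)
    x[s:(s + length(w) - 1L)] <- x[s:(s + length(w) - 1L)] + w
  }
  list(x = x, t = (starts - 1) / fs, fs = fs)
}

match_detections <- function(det_times, truth_times, tol = 0.5) {
  used <- rep(FALSE, length(truth_times))
  matched <- 0L
  for (tt in det_times) {
    if (!length(truth_times)) break
    d <- abs(truth_times - tt)
    d[used] <- Inf
    i <- which.min(d)
    if (d[i] <= tol) {
      used[i] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

# spectrogram ridge frequency of a waveform at a given time (s)
ridge_freq_at <- function(x, fs, at_s, nfft = fs, band = c(5, 100)) {
  i0 <- round(at_s * fs) + 1L
  seg <- x[i0:(i0 + nfft - 1L)]
  p <- welch_psd(seg, psd_config(nfft, "hann", 0.5, fs))
  sel <- p$freq >= band[1] & p$freq <= band[2]
  p$freq[sel][which.max(p$density[sel])]
}
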