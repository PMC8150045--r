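#' Welch PSD configuration
#'
#' Analysis presets follow the deployed processing chains: the long-term
#' spectrogram / FIN chain uses a 2^14-point Hamming window with 50% overlap
#' at 32768 Hz (2.0 Hz resolution); daily-occurrence screening uses a
#' 20000-point Hann window (1.6 Hz); call-abundance spectrograms use a
#' 334-point Hann window with 90% overlap on 500 Hz decimated audio.
#'
#' @param nfft segment/FFT length in samples (no zero padding)
#' @param window `"hann"` or `"hamming"`
#' @param overlap fractional overlap in `[0, 1)`
#' @param fs sampling rate, Hz
#' @return object of class `psd_config`
#' @export
psd_config <- function(nfft, window = c("hann", "hamming"),
                       overlap = 0.5, fs) {
  window <- match.arg(window)
  stopifnot(nfft >= 2, overlap >= 0, overlap < 1, fs > 0)
  structure(list(nfft = as.integer(nfft), window = window,
                 overlap = overlap, fs = fs),
            class = "psd_config")
}

#' Named PSD presets for the three analysis chains
#'
#' @param name one of `"lts_fin"`, `"dao"`, `"cab"`
#' @return a [psd_config()]
#' @export
psd_preset <- function(name = c("lts_fin", "dao", "cab")) {
  switch(match.arg(name),
         lts_fin = psd_config(16384L, "hamming", 0.5, 32768),
         dao     = psd_config(20000L, "hann", 0.5, 32768),
         cab     = psd_config(334L, "hann", 0.9, 500))
}

#' Frequency resolution of a PSD configuration
#' @param cfg a [psd_config()]
#' @return `fs / nfft` in Hz
#' @export
fft_resolution <- function(cfg) {
  stopifnot(inherits(cfg, "psd_config"))
  cfg$fs / cfg$nfft
}

spectral_window <- function(type, n) {
  i <- seq_len(n) - 1L
  switch(type,
         hann = 0.5 - 0.5 * cos(2 * pi * i / (n - 1L)),
         hamming = 0.54 - 0.46 * cos(2 * pi * i / (n - 1L)),
         stop("unknown window type: ", type))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with one-sided density scaling: a
#' unit-variance white input yields a flat density of `1/(fs/2)` in linear
#' units, and `sum(density * df)` recovers the segment variance. Detrending
#' is mean removal only.
#'
#' @param x calibrated pressure (or count) series
#' @param cfg a [psd_config()]; `cfg$fs` must match the series
#' @param timestamp optional POSIXct tag carried through to the record
#' @return object of class `psd_record` with `freq` (Hz), `density`
#'   (linear units^2/Hz) and `density_db` accessor via [psd_db()]
#' @export
welch_psd <- function(x, cfg, timestamp = NULL) {
  stopifnot(inherits(cfg, "psd_config"))
  n <- cfg$nfft
  if (length(x) < n)
    stop("segment shorter than one analysis window (", n, " samples)")
  x <- x - mean(x)
  w <- spectral_window(cfg$window, n)
  step <- max(1L, as.integer(round(n * (1 - cfg$overlap))))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  nbin <- n %/% 2L + 1L
  acc <- numeric(nbin)
  for (s in starts) {
    seg <- x[s:(s + n - 1L)] * w
    sp <- stats::fft(seg)[seq_len(nbin)]
    acc <- acc + Re(sp * Conj(sp))
  }
  pxx <- acc / (length(starts) * cfg$fs * sum(w^2))
  # one-sided: double everything except DC and (for even n) Nyquist
  dbl <- rep(2, nbin)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[nbin] <- 1
  pxx <- pxx * dbl
  structure(list(freq = (seq_len(nbin) - 1L) * cfg$fs / n,
                 density = pxx, fs = cfg$fs, nfft = n,
                 n_segments = length(starts), timestamp = timestamp),
            class = "psd_record")
}

#' PSD in decibels
#' @param psd a `psd_record`
#' @param ref reference level (1 uPa^2/Hz for calibrated input)
#' @return density in dB re `ref`
#' @export
psd_db <- function(psd, ref = 1) {
  stopifnot(inherits(psd, "psd_record"))
  10 * log10(psd$density / ref)
}

#' Select the quietest window of a file
#'
#' Scans `window_s`-long windows at `hop_s` spacing and returns the one
#' minimising broadband mean-square amplitude (ties broken by the earliest
#' offset). Used to build long-term spectrograms that suppress transient
#' mooring noise such as flow or shackle strum.
#'
#' @param x sample series
#' @param fs sampling rate, Hz
#' @param window_s window length, seconds (default 10)
#' @param hop_s hop between candidate offsets, seconds (default 1)
#' @return list with `offset_s`, `offset_samples` (0-based), `segment`,
#'   `mean_square`
#' @export
quietest_window <- function(x, fs, window_s = 10, hop_s = 1) {
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  h <- max(1L, as.integer(round(hop_s * fs)))
  if (n < w) stop("file shorter than the analysis window")
  cs <- c(0, cumsum(x^2))
  offsets <- seq(0L, n - w, by = h)
  energy <- cs[offsets + w + 1L] - cs[offsets + 1L]
  best <- offsets[which.min(energy)]  # which.min takes the earliest tie
  list(offset_s = best / fs, offset_samples = best,
       segment = x[(best + 1L):(best + w)],
       mean_square = min(energy) / w)
}

#' Build a long-term spectrogram (LTS)
#'
#' One Welch PSD per selected file, computed on that file's quietest
#' `window_s` seconds. Files that cannot be read yield an all-NA column
#' (gap marker), never interpolation.
#'
#' @param manifest data.frame with `path` and `start_utc` columns
#' @param cfg a [psd_config()]
#' @param scheme a [subsampling_scheme()] applied to the manifest
#' @param calib optional [calibration_spec()]; when supplied, counts are
#'   converted to uPa before spectral estimation
#' @param window_s quietest-window length in seconds
#' @return object of class `lts`: `time` (POSIXct), `freq` (Hz), `density`
#'   (linear, freq x time matrix)
#' @export
build_lts <- function(manifest, cfg, scheme = subsampling_scheme(),
                      calib = NULL, window_s = 10) {
  stopifnot(inherits(cfg, "psd_config"))
  sel <- apply_subsampling(manifest, scheme)
  nbin <- cfg$nfft %/% 2L + 1L
  dens <- matrix(NA_real_, nrow = nbin, ncol = nrow(sel))
  freq <- (seq_len(nbin) - 1L) * cfg$fs / cfg$nfft
  for (j in seq_len(nrow(sel))) {
    res <- tryCatch({
      # suppress base R's connection warning; the error is reported below
      wav <- suppressWarnings(read_wav_pcm16(sel$path[j]))
      x <- wav$samples
      if (!is.null(calib)) x <- counts_to_pressure(x, calib)
      qw <- quietest_window(x, wav$fs, window_s = window_s)
      welch_psd(qw$segment, cfg)$density
    }, error = function(e) {
      warning("skipping ", sel$path[j], ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) dens[, j] <- res
  }
  structure(list(time = sel$start_utc, freq = freq, density = dens),
            class = "lts")
}

#' @export
print.lts <- function(x, ...) {
  cat(sprintf("long-term spectrogram: %d files, %d frequency bins (%.3g-%.4g Hz)\n",
              ncol(x$density), length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}
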