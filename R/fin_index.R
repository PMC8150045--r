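#' Band set defining a FIN index
#'
#' A FIN index is the band SNR of a call band against the mean of two bracing
#' noise bands. Bands are closed frequency intervals; PSD bins whose centre
#' frequency falls inside the interval are averaged.
#'
#' @param signal,noise_low,noise_high length-2 numeric `[lo, hi]` in Hz
#' @param label band-set label
#' @return object of class `band_set`
#' @export
band_set <- function(signal, noise_low, noise_high, label = "") {
  stopifnot(length(signal) == 2, length(noise_low) == 2,
            length(noise_high) == 2)
  if (!(noise_low[2] <= signal[1] && signal[1] <= signal[2] &&
          signal[2] <= noise_high[1]))
    stop("bands must be ordered noise_low <= signal <= noise_high and non-overlapping")
  structure(list(signal = signal, noise_low = noise_low,
                 noise_high = noise_high, label = label),
            class = "band_set")
}

#' FIN band presets used across the monitoring literature
#'
#' `fin21` (8-10 / 20-22 / 30-32 Hz) and `fin86` (80-82 / 86-88 / 92-94 Hz)
#' are the band sets of this analysis; the remaining presets reproduce band
#' conventions from other deployments so that index values can be recomputed
#' under each convention.
#'
#' @param name preset name; see `names(fin_band_presets())`
#' @return a [band_set()], or the full named list when `name` is `NULL`
#' @export
fin_band_presets <- function(name = NULL) {
  presets <- list(
    fin21            = band_set(c(20, 22), c(8, 10), c(30, 32), "fin21"),
    fin86            = band_set(c(86, 88), c(80, 82), c(92, 94), "fin86"),
    antarctic_21_22  = band_set(c(21, 22), c(9, 10), c(33, 34), "antarctic_21_22"),
    juan_fernandez_16_22 = band_set(c(16, 22), c(10, 11), c(35, 36), "juan_fernandez_16_22"),
    arctic_19_28     = band_set(c(19, 28), c(13, 17), c(33, 37), "arctic_19_28"),
    north_atlantic_19_22 = band_set(c(19, 22), c(8, 13), c(40, 45), "north_atlantic_19_22"),
    california_22_23 = band_set(c(22, 23), c(10, 11), c(34, 35), "california_22_23"),
    antarctic_89_90  = band_set(c(89, 90), c(80, 81), c(98, 99), "antarctic_89_90"),
    juan_fernandez_84_86 = band_set(c(84, 86), c(70, 71), c(100, 101), "juan_fernandez_84_86"))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) stop("unknown band preset: ", name)
  presets[[name]]
}

#' Mean linear spectral density over a band
#'
#' Arithmetic mean of linear-unit density over PSD bins whose centre
#' frequencies lie in the closed interval `[lo, hi]`. With 2-Hz bins the
#' 86-88 Hz band therefore averages the 86 and 88 Hz bins.
#'
#' @param psd a `psd_record` (or list with `freq` and linear `density`)
#' @param band length-2 numeric `[lo, hi]` in Hz
#' @return mean linear density
#' @export
band_density <- function(psd, band) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  sel <- psd$freq >= band[1] - 1e-9 & psd$freq <= band[2] + 1e-9
  if (!any(sel)) stop("no PSD bins with centres inside [",
                      band[1], ", ", band[2], "] Hz")
  mean(psd$density[sel])
}

#' FIN band signal-to-noise ratio
#'
#' `10 log10( S_signal / (0.5 (S_noise_low + S_noise_high)) )` on linear
#' densities. Because any recorder calibration offset multiplies all three
#' band densities equally, the index is invariant under calibration error.
#'
#' @param psd a `psd_record`
#' @param bands a [band_set()]
#' @return SNR in dB; `Inf` (with a warning) if the noise densities are zero
#' @export
fin_snr <- function(psd, bands = fin_band_presets("fin86")) {
  stopifnot(inherits(bands, "band_set"))
  s <- band_density(psd, bands$signal)
  n <- 0.5 * (band_density(psd, bands$noise_low) +
                band_density(psd, bands$noise_high))
  if (n <= 0) {
    warning("zero noise-band density; FIN flagged infinite")
    return(Inf)
  }
  10 * log10(s / n)
}

#' FIN series from a long-term spectrogram
#'
#' @param lts an `lts` object from [build_lts()]
#' @param bands a [band_set()]
#' @param smooth_days running-mean window in days (see [running_mean()]);
#'   `NULL` disables smoothing
#' @return data.frame with `time`, `snr_db`, `snr_db_smoothed`
#' @export
fin_series <- function(lts, bands = fin_band_presets("fin86"),
                       smooth_days = 14) {
  stopifnot(inherits(lts, "lts"))
  snr <- vapply(seq_len(ncol(lts$density)), function(j) {
    d <- lts$density[, j]
    if (all(is.na(d))) return(NA_real_)
    fin_snr(list(freq = lts$freq, density = d), bands)
  }, numeric(1))
  sm <- if (is.null(smooth_days)) snr else
    running_mean(lts$time, snr, window_days = smooth_days)
  data.frame(time = lts$time, snr_db = snr, snr_db_smoothed = sm,
             band_label = bands$label)
}

#' Centred running mean over a time window
#'
#' For each sample, the arithmetic mean of all values whose timestamps lie
#' within +/- `window_days/2`; the window truncates at the series edges and
#' missing values are ignored.
#'
#' @param time POSIXct (or numeric days) timestamps, sorted
#' @param x values (may contain NA)
#' @param window_days full window width in days (default 14)
#' @return smoothed numeric vector
#' @export
running_mean <- function(time, x, window_days = 14) {
  t_num <- as.numeric(time) / 86400
  if (is.numeric(time) && !inherits(time, "POSIXct")) t_num <- as.numeric(time)
  if (is.unsorted(t_num)) stop("timestamps must be sorted")
  half <- window_days / 2
  # half-open window [t - half, t + half): an interior window at regular
  # sampling holds exactly window_days/dt samples
  lo <- findInterval(t_num - half, t_num, left.open = TRUE) + 1L
  hi <- findInterval(t_num + half, t_num, left.open = TRUE)
  ok <- !is.na(x)
  csum <- c(0, cumsum(ifelse(ok, x, 0)))
  cnt <- c(0, cumsum(as.numeric(ok)))
  num <- csum[hi + 1L] - csum[lo]
  den <- cnt[hi + 1L] - cnt[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Level difference implied by a call-count ratio
#'
#' `10 log10(n2 / n1)` dB: a tenfold increase in the number of (equal-level,
#' incoherent) acoustic sources raises the band level by 10 dB, the relation
#' used to compare call-abundance and FIN trends.
#'
#' @param n2,n1 positive call counts
#' @return level difference in dB
#' @export
count_ratio_to_db <- function(n2, n1) {
  if (any(c(n1, n2) <= 0)) stop("call counts must be positive")
  10 * log10(n2 / n1)
}
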