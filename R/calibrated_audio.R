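#' Hydrophone calibration specification
#'
#' Bundles the three gain terms that convert stored ADC counts to sound
#' pressure level: hydrophone sensitivity `S` (dB re 1 V/uPa, negative),
#' amplifier gain `G` (dB) and digital gain `M` (dB). The combined additive
#' constant is `-S - G - M`; with the defaults (S = -164, G = 22, M = 84,
#' the deployed AURAL configuration) it equals 58 dB.
#'
#' @param S hydrophone sensitivity, dB re 1 V/uPa
#' @param G amplifier gain, dB
#' @param M digital gain, dB
#' @return object of class `calibration_spec`
#' @export
calibration_spec <- function(S = -164, G = 22, M = 84) {
  stopifnot(is.finite(S), is.finite(G), is.finite(M))
  structure(list(S = S, G = G, M = M, constant = -S - G - M),
            class = "calibration_spec")
}

#' @export
print.calibration_spec <- function(x, ...) {
  cat(sprintf("calibration: S = %g dB, G = %g dB, M = %g dB; SPL = 20 log10(c) %+g dB\n",
              x$S, x$G, x$M, x$constant))
  invisible(x)
}

#' Convert count magnitude to sound pressure level
#'
#' SPL (dB re 1 uPa) = 20 log10(c) - S - G - M.
#'
#' @param c positive count magnitude
#' @param calib a [calibration_spec()]
#' @return SPL in dB re 1 uPa
#' @export
counts_to_spl <- function(c, calib = calibration_spec()) {
  stopifnot(inherits(calib, "calibration_spec"))
  if (any(!is.finite(c)) || any(c <= 0))
    stop("count magnitude must be positive and finite")
  20 * log10(c) + calib$constant
}

#' Inverse of [counts_to_spl()]
#' @param spl SPL in dB re 1 uPa
#' @param calib a [calibration_spec()]
#' @return count magnitude
#' @export
spl_to_counts <- function(spl, calib = calibration_spec()) {
  stopifnot(inherits(calib, "calibration_spec"))
  10^((spl - calib$constant) / 20)
}

#' Convert a count series to calibrated pressure
#'
#' Applies the calibration per sample, so spectral estimates computed on the
#' result are already in physical units (uPa^2/Hz). This commutes with linear
#' spectral estimation, which is why the constant is applied here rather than
#' to derived band metrics.
#'
#' @param counts numeric count series (signed)
#' @param calib a [calibration_spec()]
#' @return pressure series in uPa
#' @export
counts_to_pressure <- function(counts, calib = calibration_spec()) {
  stopifnot(inherits(calib, "calibration_spec"))
  counts * 10^(calib$constant / 20)
}

#' Recording schedule
#'
#' @param start,end POSIXct UTC deployment limits (`end` exclusive)
#' @param file_duration_s duration of one stored file, seconds
#' @param duty length-2 numeric `(record_minutes, period_minutes)`; continuous
#'   recording is `record == period`
#' @return object of class `recording_schedule`
#' @export
recording_schedule <- function(start, end, file_duration_s,
                               duty = c(5, 60)) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (!(end > start)) stop("schedule end must be after start")
  if (duty[1] > duty[2]) stop("duty record minutes must not exceed period minutes")
  stopifnot(file_duration_s > 0)
  structure(list(start = start, end = end,
                 file_duration_s = as.numeric(file_duration_s),
                 duty = as.numeric(duty)),
            class = "recording_schedule")
}

#' Enumerate recorded files under a duty-cycled schedule
#'
#' One row per stored file. Each duty period of `duty[2]` minutes contributes
#' `record_minutes / file_duration` files starting at the period onset;
#' recording windows never overlap and the gap within each period equals
#' `period - record` minutes.
#'
#' @param schedule a [recording_schedule()]
#' @return data.frame with `file_id`, `start_utc`, `duration_s`
#' @export
enumerate_files <- function(schedule) {
  stopifnot(inherits(schedule, "recording_schedule"))
  period_s <- schedule$duty[2] * 60
  record_s <- schedule$duty[1] * 60
  fdur <- schedule$file_duration_s
  n_per_period <- max(1L, floor(record_s / fdur + 1e-9))
  period_starts <- seq(from = schedule$start, to = schedule$end - 1e-3,
                       by = period_s)
  starts <- rep(period_starts, each = n_per_period) +
    rep((seq_len(n_per_period) - 1L) * fdur, times = length(period_starts))
  starts <- starts[starts < schedule$end]
  data.frame(file_id = sprintf("%s.wav", format(starts, "%Y%m%d_%H%M%S")),
             start_utc = starts,
             duration_s = fdur)
}

#' Duty fraction of a schedule
#' @param schedule a [recording_schedule()]
#' @return fraction of elapsed time recorded
#' @export
duty_fraction <- function(schedule) {
  stopifnot(inherits(schedule, "recording_schedule"))
  schedule$duty[1] / schedule$duty[2]
}

#' Analysis subsampling scheme
#'
#' Deterministic stride selection used to keep manual-analysis-equivalent
#' workloads bounded: every `file_stride`-th file of every `day_stride`-th
#' day, anchored at the first available file and day.
#'
#' @param file_stride positive integer stride over files within a day
#' @param day_stride positive integer stride over calendar days
#' @param label free-text label
#' @return object of class `subsampling_scheme`
#' @export
subsampling_scheme <- function(file_stride = 1L, day_stride = 1L,
                               label = sprintf("1-in-%d files, 1-in-%d days",
                                               file_stride, day_stride)) {
  stopifnot(file_stride >= 1L, day_stride >= 1L)
  structure(list(file_stride = as.integer(file_stride),
                 day_stride = as.integer(day_stride), label = label),
            class = "subsampling_scheme")
}

#' Apply a subsampling scheme to a time-ordered file manifest
#'
#' @param files data.frame with a `start_utc` POSIXct column, time-ordered
#' @param scheme a [subsampling_scheme()]
#' @return the selected rows of `files`
#' @export
apply_subsampling <- function(files, scheme) {
  stopifnot(inherits(scheme, "subsampling_scheme"),
            !is.unsorted(as.numeric(files$start_utc)))
  if (nrow(files) == 0L) return(files)
  day <- as.Date(files$start_utc, tz = "UTC")
  days <- sort(unique(day))
  keep_days <- days[(seq_along(days) - 1L) %% scheme$day_stride == 0L]
  out <- files[day %in% keep_days, , drop = FALSE]
  day2 <- as.Date(out$start_utc, tz = "UTC")
  idx_in_day <- stats::ave(seq_len(nrow(out)), as.character(day2),
                           FUN = seq_along)
  out[(idx_in_day - 1L) %% scheme$file_stride == 0L, , drop = FALSE]
}

#' Count calendar days between two dates
#'
#' End-exclusive, leap-aware difference in whole days.
#'
#' @param start_date,end_date `Date` or coercible
#' @return integer number of days
#' @export
recorded_day_count <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date < start_date) stop("end date before start date")
  as.integer(end_date - start_date)
}
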