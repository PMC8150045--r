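#' Short-time Fourier transform (power)
#'
#' Hann-windowed one-sided power spectrogram used by the pulse detector.
#'
#' @param x sample series
#' @param fs sampling rate, Hz
#' @param nfft window/FFT length, samples
#' @param overlap fractional overlap
#' @return list `P` (linear power, freq x frames), `f` (Hz), `t` (frame
#'   start times, s), `hop_s`
#' @export
stft_power <- function(x, fs, nfft, overlap = 0.9) {
  stopifnot(length(x) >= nfft)
  w <- spectral_window("hann", nfft)
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, length(x) - nfft + 1L, by = step)
  nbin <- nfft %/% 2L + 1L
  segs <- matrix(x[outer(seq_len(nfft) - 1L, starts, "+")], nrow = nfft)
  segs <- (segs - rep(colMeans(segs), each = nfft)) * w
  sp <- stats::mvfft(segs)[seq_len(nbin), , drop = FALSE]
  list(P = Re(sp * Conj(sp)), f = (seq_len(nbin) - 1L) * fs / nfft,
       t = (starts - 1L) / fs, hop_s = step / fs)
}

downsweep_kernel <- function(f, hop_s, f_start = 28, f_end = 15,
                             duration = 1, width_hz = 2) {
  nt <- max(2L, as.integer(round(duration / hop_s)))
  traj <- seq(f_start, f_end, length.out = nt)
  rows <- which(f >= f_end - 3 & f <= f_start + 3)
  K <- outer(f[rows], traj, function(fi, ft)
    exp(-(fi - ft)^2 / (2 * width_hz^2)))
  K <- K / sum(K)
  list(K = K, rows = rows, nt = nt)
}

#' Detect fin whale 20-Hz pulses
#'
#' Automated stand-in for manual spectrogram screening: the dB spectrogram
#' is normalised by per-frequency medians (stationary noise) and per-frame
#' medians over the low-frequency band (broadband transients and chorus),
#' then cross-correlated with a 28-to-15 Hz, 1-s downsweep kernel. The
#' score at each frame is the kernel-weighted mean dB excess along the
#' ridge; local maxima above `threshold` separated by at least
#' `min_separation_s` become candidate events, which are then classified by
#' their spectro-temporal ridge ([classify_event()]). Detector performance
#' is characterised on synthetic ground truth, not asserted to replicate
#' analyst judgement.
#'
#' @param x sample series (counts or pressure; the score is scale-free)
#' @param fs sampling rate, Hz
#' @param threshold detection threshold, dB ridge excess (default 7)
#' @param min_separation_s minimum event separation, s
#' @param overlap STFT overlap (default 0.9)
#' @param keep_all keep non-fin20 candidates in the output
#' @return data.frame `time_s` (event start), `score`, `f_start`, `f_end`,
#'   `duration_s`, `class`
#' @export
detect_pulses <- function(x, fs, threshold = 7, min_separation_s = 0.5,
                          overlap = 0.9, keep_all = FALSE) {
  if (length(x) < 2 * fs) stop("segment must be at least 2 s long")
  nfft <- stats::nextn(as.integer(round(fs / 1.5)), c(2, 3, 5))  # ~1.5 Hz resolution, FFT-friendly length
  sp <- stft_power(x, fs, nfft, overlap)
  Z <- 10 * log10(sp$P + .Machine$double.xmin)
  Z <- Z - apply(Z, 1L, stats::median)
  lf <- which(sp$f >= 10 & sp$f <= 35)
  Z[lf, ] <- sweep(Z[lf, , drop = FALSE], 2L,
                   apply(Z[lf, , drop = FALSE], 2L, stats::median))
  ker <- downsweep_kernel(sp$f, sp$hop_s)
  nframe <- ncol(Z)
  if (nframe < ker$nt) return(empty_detections())
  score <- numeric(nframe - ker$nt + 1L)
  for (j in seq_len(ker$nt)) {
    part <- colSums(Z[ker$rows, , drop = FALSE] * ker$K[, j])
    score <- score + part[j:(j + length(score) - 1L)]
  }
  sep <- max(1L, as.integer(round(min_separation_s / sp$hop_s)))
  cand <- which(score > threshold)
  cand <- cand[vapply(cand, function(i) {
    lo <- max(1L, i - sep)
    hi <- min(length(score), i + sep)
    score[i] >= max(score[lo:hi])
  }, logical(1))]
  if (length(cand) > 1L) {  # collapse plateaus of equal maxima
    keep <- c(TRUE, diff(cand) > sep)
    cand <- cand[keep]
  }
  if (length(cand) == 0L) return(empty_detections())
  out <- lapply(cand, function(i) {
    ridge <- extract_ridge(Z, sp, i, window_s = 2.5)
    cls <- classify_event(ridge, window_s = nfft / fs)
    # frame times mark the window start; the event onset sits about half a
    # window later than the first ridge frame
    data.frame(time_s = (if (nrow(ridge)) ridge$t[1L] else sp$t[i]) +
                 nfft / (2 * fs),
               score = score[i],
               f_start = if (nrow(ridge)) ridge$f[1L] else NA_real_,
               f_end = if (nrow(ridge)) ridge$f[nrow(ridge)] else NA_real_,
               duration_s = if (nrow(ridge))
                 max(ridge$t) - min(ridge$t) else NA_real_,
               class = cls)
  })
  out <- do.call(rbind, out)
  if (!keep_all) out <- out[out$class == "fin20", , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(time_s = numeric(), score = numeric(), f_start = numeric(),
             f_end = numeric(), duration_s = numeric(), class = character())
}

extract_ridge <- function(Z, sp, start_frame, window_s = 2.5,
                          back_s = 2, band = c(10, 35), min_excess_db = 6,
                          jump_penalty = 3) {
  rows <- which(sp$f >= band[1] & sp$f <= band[2])
  first <- max(1L, start_frame - as.integer(round(back_s / sp$hop_s)))
  nfr <- min(ncol(Z), start_frame + as.integer(round(window_s / sp$hop_s)))
  frames <- first:nfr
  sub <- Z[rows, frames, drop = FALSE]
  nf <- length(frames)
  fr <- sp$f[rows]
  # Viterbi ridge: the path maximising summed excess minus a penalty of
  # `jump_penalty` dB per Hz of frequency jump between frames; this keeps
  # the trajectory continuous even where per-row noise floors differ (e.g.
  # a pulse sweeping out of a chorus band)
  pen <- jump_penalty * abs(outer(fr, fr, "-"))
  cost <- sub
  back <- matrix(1L, nrow = length(rows), ncol = nf)
  for (j in seq_len(nf)[-1L]) {
    step <- cost[, j - 1L] - pen  # step[s, r]: arrive at r from s
    best <- apply(step, 2L, which.max)
    back[, j] <- best
    cost[, j] <- sub[, j] + step[cbind(best, seq_along(rows))]
  }
  path <- integer(nf)
  path[nf] <- which.max(cost[, nf])
  for (j in rev(seq_len(nf - 1L))) path[j] <- back[path[j + 1L], j + 1L]
  excess <- sub[cbind(path, seq_len(nf))]
  # keep the contiguous above-threshold run around the strongest frame
  # near the trigger
  near <- which(frames >= start_frame &
                  frames <= start_frame + round(1.5 / sp$hop_s))
  if (length(near) == 0L) near <- seq_len(nf)
  seed <- near[which.max(excess[near])]
  if (excess[seed] < min_excess_db)
    return(data.frame(t = numeric(), f = numeric(), excess_db = numeric()))
  lo <- seed
  while (lo > 1L && excess[lo - 1L] >= min_excess_db) lo <- lo - 1L
  hi <- seed
  while (hi < nf && excess[hi + 1L] >= min_excess_db) hi <- hi + 1L
  idx <- lo:hi
  data.frame(t = sp$t[frames[idx]], f = fr[path[idx]],
             excess_db = excess[idx])
}

#' Classify a spectro-temporal ridge
#'
#' Rules mirroring the visual discrimination criteria. `fin20`: a
#' monotone-decreasing ridge within 15-30 Hz sweeping at least 8 Hz in at
#' most 2 s; because the measured ridge is trimmed by the envelope taper
#' and smeared by the STFT window, the sweep extent is assessed from the
#' excess-weighted slope over the ridge duration plus one window length,
#' and up to two resolution bins of upward jitter are tolerated. `zcall`:
#' a tonal segment (>= 1.2 s within the ridge, i.e. a nominal 1.5 s tone
#' after edge trimming) near 26-28 Hz preceding a downward step of several
#' Hz - the blue whale's bi-tonal signature. `chorus`: band energy
#' elevated for at least 60 s without a resolvable ridge. `other`
#' otherwise.
#'
#' @param ridge data.frame with `t` (s), `f` (Hz) and optionally
#'   `excess_db` (ridge excess used as fit weight) per frame
#' @param band_elevation_s duration of sustained 15-30 Hz band elevation
#'   containing the event (from [detect_chorus()]), used for the chorus rule
#' @param window_s STFT window length used to correct the measured sweep
#'   duration for spectral smear
#' @return one of `"fin20"`, `"zcall"`, `"chorus"`, `"other"`
#' @export
classify_event <- function(ridge, band_elevation_s = 0, window_s = 0.67) {
  if (nrow(ridge) < 4L)
    return(if (band_elevation_s >= 60) "chorus" else "other")
  f <- stats::runmed(ridge$f, if (nrow(ridge) >= 5L) 5L else 3L)
  t <- ridge$t
  n <- length(f)
  w <- if (is.null(ridge$excess_db)) rep(1, n) else
    pmax(ridge$excess_db - 5, 0.1)
  # tonal prefix: initial run confined to within ~2 resolution bins
  pre <- 1L
  while (pre < n && max(f[1:(pre + 1L)]) - min(f[1:(pre + 1L)]) <= 3.1)
    pre <- pre + 1L
  pre_dur <- t[pre] - t[1L]
  pre_f <- stats::median(f[1:pre])
  if (pre_dur >= 1.2 && pre_f >= 25 && pre_f <= 29 && pre < n &&
        min(f[pre:n]) <= pre_f - 4)
    return("zcall")
  dur <- t[n] - t[1L]
  tw <- sum(w * t) / sum(w)
  fw <- sum(w * f) / sum(w)
  slope <- sum(w * (t - tw) * (f - fw)) / sum(w * (t - tw)^2)
  sweep_est <- -slope * (dur + window_s)
  rise <- sum(pmax(diff(f), 0))  # cumulative upward jitter
  # gates allow for STFT smear: a true 1-s, 28-15 Hz sweep measures up to
  # ~0.7 s longer and ~4 Hz wider than its nominal extent
  if (slope <= -5.5 && sweep_est >= 8 && dur <= 2 + window_s &&
        rise <= 6 && all(f >= 10.5 & f <= 35.5))
    return("fin20")
  if (band_elevation_s >= 60) return("chorus")
  "other"
}

#' Detect sustained chorus bands
#'
#' Flags intervals where the mean 15-30 Hz level exceeds the 35-60 Hz
#' reference level by `excess_db` for at least `min_duration_s` - the
#' signature of many distant, unresolvable 20-Hz callers. Chorus is never
#' counted as individual calls nor as daily occurrence.
#'
#' @param x sample series
#' @param fs sampling rate, Hz
#' @param excess_db band excess threshold, dB (default 3)
#' @param min_duration_s minimum sustained duration, s (default 60)
#' @return data.frame `start_s`, `end_s` of chorus intervals
#' @export
detect_chorus <- function(x, fs, excess_db = 3, min_duration_s = 60) {
  nfft <- stats::nextn(as.integer(round(fs / 1.5)), c(2, 3, 5))
  sp <- stft_power(x, fs, nfft, overlap = 0.5)
  band <- colMeans(sp$P[sp$f >= 15 & sp$f <= 30, , drop = FALSE])
  ref <- colMeans(sp$P[sp$f >= 35 & sp$f <= 60, , drop = FALSE])
  hot <- 10 * log10(band / ref) > excess_db
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * sp$hop_s >= min_duration_s
  data.frame(start_s = sp$t[starts[keep]],
             end_s = sp$t[ends[keep]] + sp$hop_s)
}

#' Count 20-Hz pulses in one file
#'
#' @param x sample series (counts)
#' @param fs sampling rate, Hz
#' @param start_utc file start time
#' @param file_id file identifier
#' @param threshold detector threshold (see [detect_pulses()])
#' @param noise_gate_db ambient level (dB, from [band_level_db()] over
#'   `noise_band`) above which the file is excluded for excessive ambient
#'   noise; `NULL` disables the gate (set it from the deployment's file
#'   levels with [noise_gate_from_levels()])
#' @param noise_band band used to measure the ambient level; the default
#'   35-80 Hz sits outside both call bands, so storm/flow noise (broadband)
#'   raises it while a strong fin whale chorus does not
#' @param censor_limit counts above this are censored (calls merge and
#'   become uncountable); censored counts are recorded at the lower bound
#' @return one-row data.frame: `file_id`, `start_utc`, `duration_s`,
#'   `n_calls`, `censored`, `excluded`, `broadband_db`
#' @export
count_interval <- function(x, fs, start_utc, file_id = "",
                           threshold = 7, noise_gate_db = NULL,
                           noise_band = c(35, 80), censor_limit = 100) {
  level <- band_level_db(x, fs, noise_band)
  excluded <- !is.null(noise_gate_db) && level > noise_gate_db
  if (excluded) {
    n <- NA_integer_
    censored <- FALSE
  } else {
    det <- detect_pulses(x, fs, threshold = threshold)
    n <- nrow(det)
    censored <- n > censor_limit
    if (censored) n <- censor_limit  # reported as lower bound ">100"
  }
  data.frame(file_id = file_id, start_utc = start_utc,
             duration_s = length(x) / fs, n_calls = n,
             censored = censored, excluded = excluded,
             noise_level_db = level)
}

#' Band level of a sample series
#'
#' `10 log10` of the mean-square amplitude within a frequency band,
#' estimated by Welch averaging with 1-s Hann windows.
#'
#' @param x sample series
#' @param fs sampling rate, Hz
#' @param band length-2 `[lo, hi]`, Hz
#' @return level in dB (re 1 count^2 or 1 uPa^2, per the input units)
#' @export
band_level_db <- function(x, fs, band = c(35, 80)) {
  nfft <- min(length(x), stats::nextn(as.integer(fs), c(2, 3, 5)))
  p <- welch_psd(x, psd_config(nfft, "hann", 0.5, fs))
  10 * log10(band_density(p, band) * diff(band))
}

#' Broadband noise gate from deployment file levels
#' @param levels_db vector of per-file broadband levels, dB
#' @param quantile exclusion quantile (default 0.95)
#' @return gate level in dB
#' @export
noise_gate_from_levels <- function(levels_db, quantile = 0.95) {
  stats::quantile(levels_db, quantile, names = FALSE, na.rm = TRUE)
}

#' Call abundance (calls per hour)
#'
#' Total counted calls divided by total counted time, over intervals that
#' are neither censored nor excluded (both are omitted from numerator and
#' denominator, since censored counts are only lower bounds and excluded
#' files were never counted).
#'
#' @param intervals data.frame from [count_interval()] rows
#' @return calls per hour (unrounded; round for reporting)
#' @export
cab <- function(intervals) {
  use <- !intervals$censored & !intervals$excluded & !is.na(intervals$n_calls)
  if (!any(use)) stop("no usable (non-censored, non-excluded) intervals")
  sum(intervals$n_calls[use]) / sum(intervals$duration_s[use] / 60) * 60
}

#' Daily acoustic occurrence
#'
#' Scans a day's files in time order and stops at the first individually
#' recognisable 20-Hz pulse (files after it are never read). Chorus never
#' establishes presence.
#'
#' @param manifest data.frame with `path`, `start_utc` for one day,
#'   time-ordered
#' @param threshold detector threshold
#' @param reader function(path) returning list(samples, fs); defaults to
#'   [read_wav_pcm16()]
#' @return one-row data.frame: `date`, `present`, `first_detection_utc`,
#'   `files_scanned`
#' @export
daily_occurrence <- function(manifest, threshold = 7,
                             reader = read_wav_pcm16) {
  stopifnot(!is.unsorted(as.numeric(manifest$start_utc)))
  date <- as.Date(manifest$start_utc[1L], tz = "UTC")
  for (j in seq_len(nrow(manifest))) {
    wav <- reader(manifest$path[j])
    det <- detect_pulses(wav$samples, wav$fs, threshold = threshold)
    if (nrow(det) > 0L) {
      return(data.frame(date = date, present = TRUE,
                        first_detection_utc = manifest$start_utc[j] +
                          det$time_s[1L],
                        files_scanned = j))
    }
  }
  data.frame(date = date, present = FALSE,
             first_detection_utc = as.POSIXct(NA, tz = "UTC"),
             files_scanned = nrow(manifest))
}

#' Detector performance against a ground-truth log
#'
#' Matches detections to logged fin whale pulses within `tolerance_s` and
#' reports recall and precision over a recording set.
#'
#' @param manifest recording-set manifest (`path`, `file_id`, `start_utc`)
#' @param log ground-truth log from [synthesize_recording_set()]
#' @param threshold detector threshold
#' @param tolerance_s matching tolerance, s
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`,
#'   `n_matched`
#' @export
detector_performance <- function(manifest, log, threshold = 7,
                                 tolerance_s = 0.5) {
  n_truth <- 0L
  n_det <- 0L
  n_match <- 0L
  for (j in seq_len(nrow(manifest))) {
    wav <- read_wav_pcm16(manifest$path[j])
    det <- detect_pulses(wav$samples, wav$fs, threshold = threshold)
    truth <- log[log$recorded & log$kind == "fin20" &
                   log$file_id == manifest$file_id[j], , drop = FALSE]
    truth_t <- (truth$sample_index - 1L) / wav$fs
    n_truth <- n_truth + length(truth_t)
    n_det <- n_det + nrow(det)
    if (nrow(det) > 0L && length(truth_t) > 0L) {
      used <- rep(FALSE, length(truth_t))
      for (tt in det$time_s) {
        d <- abs(truth_t - tt)
        d[used] <- Inf
        i <- which.min(d)
        if (d[i] <= tolerance_s) {
          used[i] <- TRUE
          n_match <- n_match + 1L
        }
      }
    }
  }
  list(recall = if (n_truth) n_match / n_truth else NA_real_,
       precision = if (n_det) n_match / n_det else NA_real_,
       n_truth = n_truth, n_detected = n_det, n_matched = n_match)
}
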