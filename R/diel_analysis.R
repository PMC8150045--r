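#' Geometric solar altitude
#'
#' Low-precision solar-position algorithm (Astronomical Almanac style):
#' solar mean anomaly and ecliptic longitude give the declination and right
#' ascension, sidereal time gives the hour angle, and the altitude follows
#' from the standard spherical triangle. Accuracy is a few hundredths of a
#' degree over the satellite era - ample for classifying twilight bands.
#' No atmospheric refraction is applied (geometric altitude).
#'
#' @param time POSIXct (UTC)
#' @param lat,lon site coordinates, degrees (south/west negative)
#' @return altitude in degrees
#' @export
sun_altitude <- function(time, lat, lon) {
  stopifnot(is.finite(lat), is.finite(lon), abs(lat) <= 90)
  time <- as.POSIXct(time, tz = "UTC")
  d2r <- pi / 180
  # days since J2000.0
  n <- as.numeric(difftime(time, as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                           units = "days"))
  L <- (280.460 + 0.9856474 * n) %% 360       # mean longitude
  g <- ((357.528 + 0.9856003 * n) %% 360) * d2r  # mean anomaly
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * d2r  # ecliptic lon
  eps <- (23.439 - 0.0000004 * n) * d2r       # obliquity
  dec <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda))  # right ascension, rad
  gmst <- (280.46061837 + 360.98564736629 * n) %% 360  # deg
  ha <- ((gmst + lon - ra / d2r + 540) %% 360 - 180) * d2r  # hour angle
  alt <- asin(sin(lat * d2r) * sin(dec) +
                cos(lat * d2r) * cos(dec) * cos(ha))
  alt / d2r
}

#' Classify solar altitude into light regimes
#'
#' `light` above 0 degrees, `twilight` from 0 down to -12 (nautical
#' twilight; boundary values are assigned to twilight), `dark` below -12.
#'
#' @param altitude degrees
#' @return factor with levels `light`, `twilight`, `dark`
#' @export
classify_light <- function(altitude) {
  stopifnot(all(is.finite(altitude)))
  out <- ifelse(altitude > 0, "light",
                ifelse(altitude >= -12, "twilight", "dark"))
  factor(out, levels = c("light", "twilight", "dark"))
}

#' Local time at the recording site
#'
#' Fixed offset of UTC - 3 h 40 min (the true local time of meridian 56 W),
#' no daylight saving.
#'
#' @param utc POSIXct (UTC)
#' @param offset_s offset in seconds (default -13200)
#' @return POSIXct shifted by the offset (still labelled UTC)
#' @export
local_time <- function(utc, offset_s = -13200) {
  as.POSIXct(utc, tz = "UTC") + offset_s
}

#' Kruskal-Wallis test across light regimes
#'
#' Rank-based H statistic with tie correction (via [stats::kruskal.test()]),
#' chi-squared p-value with `k - 1` degrees of freedom, and the critical
#' value at the chosen alpha. Groups of identical constants give H = 0
#' under the tie-correction convention that a fully tied sample carries no
#' rank information (the tie-corrected statistic is reported as 0, not NaN).
#'
#' @param values numeric observations (e.g. per-file call abundances), or a
#'   list of group samples when `groups` is missing
#' @param groups group labels parallel to `values`
#' @param alpha significance level for the reported critical value
#' @return list with `H`, `df`, `p`, `critical_value`, `group_sizes`,
#'   `alpha`
#' @export
kruskal_wallis <- function(values, groups = NULL, alpha = 0.05) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (!is.factor(groups)) groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least two groups required")
  if (any(tabulate(groups, nlevels(groups)) == 0L))
    stop("each group must be nonempty")
  groups <- droplevels(groups)
  kt <- suppressWarnings(stats::kruskal.test(values, groups))
  H <- unname(kt$statistic)
  p <- unname(kt$p.value)
  if (!is.finite(H)) {  # all observations tied: no evidence of difference
    H <- 0
    p <- 1
  }
  df <- nlevels(groups) - 1L
  list(H = H, df = df, p = p,
       critical_value = stats::qchisq(1 - alpha, df),
       group_sizes = as.integer(table(groups)), alpha = alpha)
}

#' Assign light regimes to count intervals
#'
#' Each interval takes the regime of its midpoint (intervals spanning a
#' regime boundary are not split).
#'
#' @param intervals data.frame with `start_utc` and `duration_s` (default
#'   600 s when absent)
#' @param lat,lon site coordinates, degrees
#' @return `intervals` with a `light_period` factor column added
#' @export
assign_light_period <- function(intervals, lat = -61.0147, lon = -55.9755) {
  dur <- if (is.null(intervals$duration_s)) 600 else intervals$duration_s
  mid <- intervals$start_utc + dur / 2
  intervals$light_period <- classify_light(sun_altitude(mid, lat, lon))
  intervals
}
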