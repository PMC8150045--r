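#' ADCP constants for the Deines sonar equation
#'
#' Only the system constant `C` (-159.1 dB for the 76.8 kHz Workhorse
#' Longranger) is instrument-documented; the remaining defaults are
#' representative configuration values and should be replaced by the
#' deployment's own settings when known.
#'
#' @param C system constant, dB
#' @param L_DBM 10 log10 of transmit pulse length (m), dB
#' @param P_DBW 10 log10 of transmit power (W), dB
#' @param alpha sound absorption of seawater, dB/m
#' @param Kc counts-to-dB scale factor, dB/count
#' @param Er real-time reference level, counts
#' @return object of class `adcp_constants`
#' @export
adcp_constants <- function(C = -159.1, L_DBM = 12.0, P_DBW = 24.0,
                           alpha = 0.027, Kc = 0.45, Er = 40) {
  stopifnot(is.finite(C), is.finite(L_DBM), is.finite(P_DBW),
            alpha >= 0, Kc > 0, is.finite(Er))
  structure(list(C = C, L_DBM = L_DBM, P_DBW = P_DBW, alpha = alpha,
                 Kc = Kc, Er = Er),
            class = "adcp_constants")
}

#' Mean volume backscatter strength (Deines sonar equation)
#'
#' `MVBS = C + 10 log10((Tx + 273.16) R^2) - L_DBM - P_DBW + 2 alpha R +
#' Kc (E - Er)`, evaluated per bin. Bins whose depth falls outside
#' `depth_range` are dropped (the upper 50 m are unreliable due to side
#' lobes, bubbles and sea ice; the default analysis range is 50-200 m).
#'
#' @param ensemble data.frame with columns `E` (0-255 counts), `R` (range
#'   along beam, m), `Tx` (transducer temperature, degC) and either `depth`
#'   (m) or an `instrument_depth` attribute/argument; extra columns
#'   (`time_utc`, `ensemble`) are carried through
#' @param k an [adcp_constants()]
#' @param depth_range analysis depth window, m; `NULL` keeps all bins
#' @param instrument_depth used to derive `depth = instrument_depth - R`
#'   when no `depth` column is present
#' @return data.frame with the input columns plus `mvbs` (dB), restricted
#'   to `depth_range`
#' @export
mvbs <- function(ensemble, k = adcp_constants(), depth_range = c(50, 200),
                 instrument_depth = 314) {
  stopifnot(inherits(k, "adcp_constants"))
  if (any(ensemble$R <= 0)) stop("range along beam must be positive")
  if (any(ensemble$E < 0 | ensemble$E > 255))
    stop("echo intensity must lie in 0-255 counts")
  if (is.null(ensemble$depth))
    ensemble$depth <- instrument_depth - ensemble$R
  ensemble$mvbs <- k$C +
    10 * log10((ensemble$Tx + 273.16) * ensemble$R^2) -
    k$L_DBM - k$P_DBW + 2 * k$alpha * ensemble$R +
    k$Kc * (ensemble$E - k$Er)
  if (!is.null(depth_range))
    ensemble <- ensemble[ensemble$depth >= depth_range[1] &
                           ensemble$depth <= depth_range[2], , drop = FALSE]
  ensemble
}

#' Noon/midnight backscatter-maximum depths and migration amplitude
#'
#' For each calendar month, the mean depth of the per-ensemble MVBS maximum
#' over ensembles falling in the local noon window (10:00-14:00) and the
#' local midnight window (22:00-02:00 next day); the migration amplitude is
#' noon minus midnight (positive when the layer sits deeper at noon, i.e.
#' normal diel vertical migration; a pattern inversion yields a negative
#' amplitude).
#'
#' @param profiles output of [mvbs()] with `time_utc`, `ensemble`, `depth`,
#'   `mvbs`
#' @param utc_offset_s local-time offset, seconds (default UTC - 3 h 40 min)
#' @return data.frame per month: `month`, `noon_depth_m`, `midnight_depth_m`,
#'   `amplitude_m`, `n_noon`, `n_midnight` (NA where a window is empty)
#' @export
migration_amplitude <- function(profiles, utc_offset_s = -13200) {
  lt <- profiles$time_utc + utc_offset_s
  hour <- as.numeric(format(lt, "%H")) + as.numeric(format(lt, "%M")) / 60
  month <- format(lt, "%Y-%m")
  per_ens <- do.call(rbind, lapply(split(profiles, profiles$ensemble),
    function(d) {
      i <- which.max(d$mvbs)
      data.frame(month = month[match(d$ensemble[1], profiles$ensemble)],
                 hour = hour[match(d$ensemble[1], profiles$ensemble)],
                 max_depth = d$depth[i])
    }))
  noon <- per_ens$hour >= 10 & per_ens$hour <= 14
  midnight <- per_ens$hour >= 22 | per_ens$hour <= 2
  months <- sort(unique(per_ens$month))
  res <- lapply(months, function(m) {
    nd <- per_ens$max_depth[noon & per_ens$month == m]
    md <- per_ens$max_depth[midnight & per_ens$month == m]
    data.frame(month = m,
               noon_depth_m = if (length(nd)) mean(nd) else NA_real_,
               midnight_depth_m = if (length(md)) mean(md) else NA_real_,
               amplitude_m = if (length(nd) && length(md))
                 mean(nd) - mean(md) else NA_real_,
               n_noon = length(nd), n_midnight = length(md))
  })
  do.call(rbind, res)
}

#' Spatially averaged sea-ice concentration within a radius
#'
#' Unweighted mean over pixels whose centres lie within great-circle
#' distance `radius_km` of the site (sphere radius 6371.0 km, pixel
#' membership by centre point).
#'
#' @param field an `ice_field` from [synthesize_ice_field()] (or a list with
#'   `lat`, `lon`, `conc`, `dates`)
#' @param site `c(lat, lon)` degrees; defaults to the field's site
#' @param radius_km averaging radius (default 30 km, the modelled detection
#'   radius of the 20-Hz pulse)
#' @param days subset of `field$dates` to average; default all
#' @return data.frame `date`, `ice_pct`
#' @export
ice_radius_average <- function(field, site = NULL, radius_km = 30,
                               days = NULL) {
  if (is.null(site)) site <- field$site
  stopifnot(radius_km > 0)
  dist_m <- geosphere::distHaversine(cbind(as.vector(field$lon),
                                           as.vector(field$lat)),
                                     c(site[2], site[1]), r = 6371000)
  sel <- dist_m <= radius_km * 1000
  if (!any(sel)) stop("averaging disc lies outside the ice grid")
  if (is.null(days)) days <- field$dates
  idx <- match(days, field$dates)
  if (anyNA(idx)) stop("requested days not covered by the ice field")
  ice <- vapply(idx, function(d) mean(field$conc[, , d][sel]), numeric(1))
  data.frame(date = days, ice_pct = ice)
}

#' Planar disc area
#' @param radius_km radius in km
#' @return area in km^2 (`pi r^2`; the planar approximation is adequate at
#'   the tens-of-km scale of acoustic detection radii)
#' @export
disc_area <- function(radius_km) {
  stopifnot(radius_km > 0)
  pi * radius_km^2
}

#' Acoustic wavelength
#' @param frequency Hz
#' @param sound_speed m/s (default 1500)
#' @return wavelength in m
#' @export
acoustic_wavelength <- function(frequency, sound_speed = 1500) {
  stopifnot(frequency > 0)
  sound_speed / frequency
}
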