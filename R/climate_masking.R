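# Climate indices, PET and the analysis-domain mask

#' Reference-surface Penman-Monteith potential evapotranspiration
#'
#' FAO-56 reference-crop formulation (grass reference, fixed albedo and
#' surface resistance), with soil heat flux taken as zero at the daily step.
#' Because the daily forcings carry no humidity variable, actual vapour
#' pressure is derived from a supplied relative humidity.
#'
#' @param air_temperature mean air temperature, degrees C (> -40).
#' @param net_radiation net radiation, MJ m-2 day-1.
#' @param wind_speed wind speed at 2 m, m/s.
#' @param surface_pressure surface pressure, kPa (> 0).
#' @param rh relative humidity, percent.
#' @return potential evapotranspiration, mm/day, floored at zero. Vectorised
#'   over all arguments.
#' @export
pet_penman_monteith <- function(air_temperature, net_radiation, wind_speed,
                                surface_pressure, rh = 60) {
  check_finite(list(air_temperature = air_temperature,
                    net_radiation = net_radiation,
                    wind_speed = wind_speed,
                    surface_pressure = surface_pressure, rh = rh), "pet input")
  if (any(air_temperature <= -40)) stop("air_temperature must exceed -40 C", call. = FALSE)
  if (any(surface_pressure <= 0)) stop("surface_pressure must be > 0", call. = FALSE)
  t <- air_temperature
  es <- 0.6108 * exp(17.27 * t / (t + 237.3))    # saturation vapour pressure, kPa
  ea <- pmin(rh, 100) / 100 * es
  delta <- 4098 * es / (t + 237.3)^2             # slope of the es curve, kPa/C
  gamma <- 0.000665 * surface_pressure           # psychrometric constant, kPa/C
  rad_term <- 0.408 * delta * pmax(net_radiation, 0)
  aero_term <- gamma * 900 / (t + 273) * wind_speed * (es - ea)
  pet <- (rad_term + aero_term) / (delta + gamma * (1 + 0.34 * wind_speed))
  pmax(pet, 0)
}

#' Daily PET series for a forcing table
#'
#' @param forcings forcing tibble as produced by [generate_forcings()].
#' @param rh relative humidity, percent (scalar or daily vector).
#' @return numeric vector of PET, mm/day.
#' @export
pet_series <- function(forcings, rh = 60) {
  pet_penman_monteith(forcings$air_temperature, forcings$net_radiation,
                      forcings$wind_speed, forcings$surface_pressure, rh = rh)
}

#' Climate dryness index
#'
#' Fraction of months in which mean potential evapotranspiration strictly
#' exceeds mean precipitation (ties count as not exceeding). Values above 0.3
#' delimit the arid-to-moderately-humid analysis domain.
#'
#' @param pet_monthly monthly climatological mean PET, mm (>= 12 values).
#' @param p_monthly monthly climatological mean precipitation, mm, aligned
#'   with `pet_monthly`.
#' @return dryness fraction in \[0, 1\].
#' @export
dryness_index <- function(pet_monthly, p_monthly) {
  if (length(pet_monthly) != length(p_monthly)) {
    stop("pet_monthly and p_monthly must have the same length", call. = FALSE)
  }
  if (length(pet_monthly) < 12) stop("need at least 12 monthly values", call. = FALSE)
  mean(pet_monthly > p_monthly)
}

#' Vegetation mask from an NDVI record
#'
#' Pixels whose NDVI never reaches 0.25 are regarded as unvegetated and
#' dropped from the analysis domain; the comparison is a strict less-than on
#' the series maximum.
#'
#' @param ndvi monthly NDVI series (>= 12 values; NAs allowed).
#' @param threshold NDVI threshold, default 0.25.
#' @return `TRUE` if the pixel is vegetated (kept), `FALSE` if masked.
#' @export
vegetation_mask <- function(ndvi, threshold = 0.25) {
  if (all(is.na(ndvi))) stop("NDVI series is entirely missing", call. = FALSE)
  if (sum(!is.na(ndvi)) < 12) stop("need at least 12 NDVI months", call. = FALSE)
  !(max(ndvi, na.rm = TRUE) < threshold)
}

#' Climate indices and domain membership for one pixel
#'
#' @param forcings daily forcing tibble with a `date` column.
#' @param ndvi monthly NDVI series for the same pixel.
#' @param rh relative humidity used in the PET computation, percent.
#' @param dryness_min dryness index above which a pixel is in the domain.
#' @param ndvi_min NDVI threshold of [vegetation_mask()].
#' @return one-row tibble: `dryness`, `max_ndvi`, `in_domain`.
#' @export
climate_indices <- function(forcings, ndvi, rh = 60,
                            dryness_min = 0.3, ndvi_min = 0.25) {
  pet <- pet_series(forcings, rh = rh)
  mon <- format(forcings$date, "%Y-%m")
  pet_m <- tapply(pet, mon, mean)
  p_m <- tapply(forcings$precipitation, mon, mean)
  dry <- dryness_index(as.numeric(pet_m), as.numeric(p_m))
  veg <- vegetation_mask(ndvi, threshold = ndvi_min)
  tibble::tibble(dryness = dry, max_ndvi = max(ndvi, na.rm = TRUE),
                 in_domain = dry > dryness_min && veg)
}
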