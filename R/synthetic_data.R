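# Synthetic truth and satellite-like observations
#
# The generator produces, for each pixel, daily meteorological forcings, a
# water-balance truth run, a monthly greenness series whose anomalies are
# driven by the water stored over a hidden integration depth, and noisy
# observations mimicking the three satellite constraints: daily near-surface
# soil moisture (microwave-like, top 5 cm only), one monthly total-column
# storage value (gravimetry-like, the temporal mean of daily column totals)
# and an 8-day surface-water fraction. The generative structure is exactly
# the structure the storage-inference stage assumes, so depth recovery is
# well-posed when noise is small.

#' Configuration of the synthetic-data generator
#'
#' Defaults describe a six-year record over a dryland pixel ensemble with
#' seasonal, stochastic rainfall. `hidden_depth` assigns each pixel the depth
#' class whose storage anomalies drive its greenness; by default the five
#' classes of [depth_classes()] are recycled across pixels.
#'
#' @param n_pixels number of pixels.
#' @param n_years record length in whole calendar years (>= 3; the three-fold
#'   hindcast needs three segments).
#' @param seed integer root seed; every stochastic draw in the module derives
#'   from it via [spawn_seed()].
#' @param start_year first calendar year of the record.
#' @param hidden_depth character vector of depth classes (recycled over
#'   pixels), or `NULL` for the default cycle.
#' @param greenness_lag response lag of greenness to storage, months.
#' @param greenness_coupling NDVI units per mm of storage anomaly; `NULL`
#'   scales the coupling per pixel so the noiseless anomaly signal has
#'   standard deviation `signal_sd_target`.
#' @param signal_sd_target target NDVI anomaly signal sd used when
#'   `greenness_coupling` is `NULL`.
#' @param greenness_noise_sd greenness observation noise sd in NDVI units;
#'   `NULL` means `greenness_noise_frac` times the signal sd.
#' @param greenness_noise_frac noise sd as a fraction of the anomaly signal sd.
#' @param ndvi_base,ndvi_seasonal_amp level and amplitude of the NDVI
#'   seasonal cycle.
#' @param sd_near_surface,sd_column,sd_fraction base observation error sds for
#'   the three observation kinds (mm, mm, fraction). Per-record sds vary
#'   uniformly within +/-20% of the base to emulate spatio-temporally varying
#'   product uncertainties.
#' @param obs_gap_frac fraction of days with no near-surface observation.
#' @param sw_frac_scale e-folding scale (mm) of the saturating map from
#'   surface-water storage to observed water fraction.
#' @param p_wet,p_wet_amp mean and seasonal amplitude of the wet-day
#'   probability.
#' @param wet_mean,wet_shape mean (mm) and Gamma shape of wet-day rainfall.
#' @param temp_mean,temp_amp,temp_noise air temperature level, seasonal
#'   amplitude and day-to-day noise sd, degrees C.
#' @param rad_mean,rad_amp,rad_noise net radiation level, amplitude and noise
#'   sd, MJ m-2 day-1.
#' @param wind_mean mean wind speed, m/s.
#' @param pressure surface pressure, kPa.
#' @param rh relative humidity used for PET, percent.
#' @param season_phase day of year of the wet/warm season peak.
#' @param deterministic_forcing if `TRUE`, replace all stochastic forcing
#'   terms by their expectations (used for degenerate-case checks).
#' @param spinup_years years of spin-up simulated and discarded before the
#'   record starts.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pixels = 5, n_years = 6, seed = 1L,
                             start_year = 2010,
                             hidden_depth = NULL,
                             greenness_lag = 1,
                             greenness_coupling = NULL,
                             signal_sd_target = 0.08,
                             greenness_noise_sd = NULL,
                             greenness_noise_frac = 0.2,
                             ndvi_base = 0.30, ndvi_seasonal_amp = 0.10,
                             sd_near_surface = 1, sd_column = 10,
                             sd_fraction = 0.02,
                             obs_gap_frac = 0.1,
                             sw_frac_scale = 10,
                             p_wet = 0.15, p_wet_amp = 0.10,
                             wet_mean = 8, wet_shape = 0.8,
                             temp_mean = 22, temp_amp = 6, temp_noise = 1.5,
                             rad_mean = 14, rad_amp = 5, rad_noise = 1,
                             wind_mean = 2, pressure = 95, rh = 60,
                             season_phase = 30,
                             deterministic_forcing = FALSE,
                             spinup_years = 1) {
  if (n_years < 3) stop("n_years must be >= 3", call. = FALSE)
  sds <- c(sd_near_surface, sd_column, sd_fraction,
           greenness_noise_sd %||% 0, greenness_noise_frac)
  if (any(sds < 0)) stop("noise standard deviations must be >= 0", call. = FALSE)
  hidden_depth <- hidden_depth %||% depth_classes()
  if (!all(hidden_depth %in% depth_classes())) {
    stop("hidden_depth must be drawn from depth_classes()", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$hidden_depth <- rep_len(hidden_depth, n_pixels)
  structure(cfg, class = "synthetic_config")
}

# seasonal shape shared by all generated forcing variables
.season <- function(doy, phase) sin(2 * pi * (doy - phase) / 365.25)

.forcing_dates <- function(start_year, n_years) {
  seq(as.Date(sprintf("%d-01-01", start_year)),
      as.Date(sprintf("%d-12-31", start_year + n_years - 1)), by = "day")
}

.generate_forcings_dates <- function(config, dates, seed) {
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  s <- .season(doy, config$season_phase)
  withr::with_seed(seed, {
    p_wet_t <- pmin(pmax(config$p_wet + config$p_wet_amp * s, 0.01), 0.95)
    # wet-day intensity shares the occurrence seasonality: amplitude 5x the
    # wet-day probability amplitude (0.5 at the default p_wet_amp = 0.1),
    # and vanishes with it
    wet_mean_t <- pmax(config$wet_mean * (1 + 5 * config$p_wet_amp * s), 0.5)
    if (config$deterministic_forcing) {
      precip <- p_wet_t * wet_mean_t
      temp <- config$temp_mean + config$temp_amp * s
      rad <- pmax(config$rad_mean + config$rad_amp * s, 0.5)
      wind <- rep(config$wind_mean, n)
    } else {
      wet <- rbinom(n, 1, p_wet_t)
      amount <- rgamma(n, shape = config$wet_shape,
                       scale = wet_mean_t / config$wet_shape)
      precip <- wet * amount
      temp <- config$temp_mean + config$temp_amp * s + rnorm(n, 0, config$temp_noise)
      rad <- pmax(config$rad_mean + config$rad_amp * s +
                    rnorm(n, 0, config$rad_noise), 0.5)
      wind <- pmax(config$wind_mean + rnorm(n, 0, 0.5), 0.1)
    }
    tibble::tibble(date = dates, precipitation = precip,
                   air_temperature = temp, net_radiation = rad,
                   wind_speed = wind,
                   surface_pressure = rep(config$pressure, n),
                   snowfall_rate = rep(0, n))
  })
}

#' Generate daily meteorological forcings for one pixel
#'
#' Seasonal cycles plus stochastic precipitation: wet days are Bernoulli with
#' seasonally varying probability and wet amounts are Gamma-distributed with
#' seasonally varying mean. Fully reproducible from the configured seed.
#'
#' @param config a [synthetic_config()].
#' @param pixel pixel id (integer, 1-based).
#' @return a daily forcing tibble (see [run_simulation()] for columns).
#' @export
generate_forcings <- function(config, pixel = 1L) {
  dates <- .forcing_dates(config$start_year, config$n_years)
  .generate_forcings_dates(config, dates,
                           spawn_seed(config$seed, "forcing", pixel))
}

#' NDVI seasonal climatology of the generator
#'
#' @param config a [synthetic_config()].
#' @return numeric vector of 12 monthly NDVI values.
#' @export
ndvi_seasonal_cycle <- function(config) {
  m <- 1:12
  config$ndvi_base +
    config$ndvi_seasonal_amp * sin(2 * pi * (m - config$season_phase / 30.4) / 12)
}

#' Generate the truth twin for one pixel
#'
#' Runs the water-balance model on generated forcings (after a discarded
#' spin-up) and constructs monthly greenness as seasonal cycle plus a linear
#' response to the lagged monthly storage anomaly of the pixel's hidden depth
#' class, plus Gaussian noise, clipped to \[0, 1\].
#'
#' @param config a [synthetic_config()].
#' @param pixel pixel id.
#' @param params a [column_params()].
#' @return a list: `forcings`, `pet`, `states`, `fluxes` (analysis period
#'   only), `storage_monthly` (tibble of monthly-mean integrated storage per
#'   depth class), `greenness` (tibble `month`, `month_num`, `ndvi`),
#'   `hidden_class`, `coupling` (NDVI per mm), `noise_sd` (NDVI units).
#' @export
generate_truth <- function(config, pixel = 1L, params = column_params()) {
  forcings <- generate_forcings(config, pixel)
  spin_dates <- .forcing_dates(config$start_year - config$spinup_years,
                               config$spinup_years)
  spin <- .generate_forcings_dates(config, spin_dates,
                                   spawn_seed(config$seed, "spinup", pixel))
  all_f <- dplyr::bind_rows(spin, forcings)
  pet_all <- pet_series(all_f, rh = config$rh)
  init <- column_state(0, 0.4 * params$cap_top, 0.4 * params$cap_shallow,
                       0.4 * params$cap_deep, 150)
  sim <- run_simulation(init, all_f, pet_all, params)
  n_spin <- nrow(spin)
  states <- sim$states[-seq_len(n_spin), , drop = FALSE]   # row 1: end of spin-up
  fluxes <- sim$fluxes[-seq_len(n_spin), , drop = FALSE]
  pet <- pet_all[-seq_len(n_spin)]

  storage_monthly <- monthly_storage(integrate_storage(states))
  s_hidden <- storage_monthly[[config$hidden_depth[pixel]]]
  anom <- monthly_anomalies(s_hidden, storage_monthly$month_num)$anomalies

  lag <- config$greenness_lag
  signal <- if (lag > 0) c(rep(0, lag), head(anom, -lag)) else anom
  a <- config$greenness_coupling %||%
    (if (sd(signal) > 0) config$signal_sd_target / sd(signal) else 0)
  signal_sd <- sd(a * signal)
  noise_sd <- config$greenness_noise_sd %||%
    (config$greenness_noise_frac *
       (if (signal_sd > 0) signal_sd else config$signal_sd_target))
  clim12 <- ndvi_seasonal_cycle(config)
  noise <- withr::with_seed(spawn_seed(config$seed, "greenness", pixel),
                            rnorm(length(signal), 0, noise_sd))
  ndvi <- pmin(pmax(clim12[storage_monthly$month_num] + a * signal + noise, 0), 1)

  list(forcings = forcings, pet = pet, states = states, fluxes = fluxes,
       storage_monthly = storage_monthly,
       greenness = tibble::tibble(month = storage_monthly$month,
                                  month_num = storage_monthly$month_num,
                                  ndvi = ndvi),
       hidden_class = config$hidden_depth[pixel],
       coupling = a, noise_sd = noise_sd)
}

#' Bundle of the three observation kinds for one pixel
#'
#' Validates the observation-set invariants: positive error sds, fractions in
#' \[0, 1\], at most one column-total record per calendar month.
#'
#' @param near_surface tibble `date`, `value`, `sd` (mm).
#' @param column_total tibble `month` (first-of-month Date), `value`, `sd` (mm).
#' @param surface_fraction tibble `date`, `value` (fraction), `sd`.
#' @param sw_frac_scale saturation scale of the surface-fraction transform, mm.
#' @return an object of class `observation_set`.
#' @export
observation_set <- function(near_surface, column_total, surface_fraction,
                            sw_frac_scale = 10) {
  if (any(c(near_surface$sd, column_total$sd, surface_fraction$sd) <= 0)) {
    stop("observation error sds must be > 0", call. = FALSE)
  }
  if (any(surface_fraction$value < 0 | surface_fraction$value > 1)) {
    stop("surface-water fractions must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(column_total$month)) {
    stop("at most one column-total observation per month", call. = FALSE)
  }
  structure(list(near_surface = near_surface, column_total = column_total,
                 surface_fraction = surface_fraction,
                 sw_frac_scale = sw_frac_scale),
            class = "observation_set")
}

#' Simulate satellite-like observations from a truth trajectory
#'
#' Near-surface observations are the daily top-layer storage plus Gaussian
#' noise with configurable gaps; the column total is the calendar-month mean
#' of daily total storage plus noise, one record per complete month; the
#' surface-water fraction is a saturating transform of surface-water storage
#' plus noise every 8 days, clipped to \[0, 1\]. Per-record error sds vary
#' uniformly within +/-20% of the configured base sds.
#'
#' @param states truth states tibble from [generate_truth()] (first row is the
#'   initial condition and is not observed).
#' @param config a [synthetic_config()].
#' @param pixel pixel id (seeds the observation noise).
#' @return an [observation_set()].
#' @export
simulate_observations <- function(states, config, pixel = 1L) {
  days <- states[-1, , drop = FALSE]
  n <- nrow(days)
  withr::with_seed(spawn_seed(config$seed, "obs", pixel), {
    keep <- runif(n) >= config$obs_gap_frac
    sd_ns <- config$sd_near_surface * runif(sum(keep), 0.8, 1.2)
    near_surface <- tibble::tibble(
      date = days$date[keep],
      value = days$s_top[keep] + rnorm(sum(keep), 0, sd_ns),
      sd = sd_ns)

    mkey <- format(days$date, "%Y-%m")
    counts <- table(mkey)[unique(mkey)]
    full <- names(counts)[as.integer(counts) ==
                            days_in_month(as.Date(paste0(names(counts), "-01")))]
    if (length(full) < length(counts)) {
      warning(sprintf("dropping %d partial month(s) from column-total observations",
                      length(counts) - length(full)), call. = FALSE)
    }
    totals <- tapply(total_water_storage(days), mkey, mean)[full]
    sd_col <- config$sd_column * runif(length(full), 0.8, 1.2)
    column_total <- tibble::tibble(
      month = as.Date(paste0(full, "-01")),
      value = as.numeric(totals) + rnorm(length(full), 0, sd_col),
      sd = sd_col)

    idx8 <- seq(1, n, by = 8)
    sd_fr <- config$sd_fraction * runif(length(idx8), 0.8, 1.2)
    frac <- fraction_from_storage(days$surface_water[idx8], config$sw_frac_scale) +
      rnorm(length(idx8), 0, sd_fr)
    surface_fraction <- tibble::tibble(
      date = days$date[idx8],
      value = pmin(pmax(frac, 0), 1),
      sd = sd_fr)
  })
  observation_set(near_surface, column_total, surface_fraction,
                  sw_frac_scale = config$sw_frac_scale)
}

#' Degrade a forcing series to emulate model forcing error
#'
#' Applies a persistent multiplicative bias and month-block lognormal errors
#' to precipitation and additive noise to temperature, producing the imperfect
#' forcings a twin experiment drives the assimilation model with while the
#' truth used the originals.
#'
#' @param forcings daily forcing tibble.
#' @param precip_bias multiplicative precipitation bias.
#' @param precip_sd sd of the monthly lognormal precipitation factors.
#' @param temp_sd sd of the additive temperature error, degrees C.
#' @param seed integer seed.
#' @return a forcing tibble of the same shape.
#' @export
degrade_forcings <- function(forcings, precip_bias = 0.8, precip_sd = 0.4,
                             temp_sd = 1, seed = 1L) {
  months <- split_by_month(forcings$date)
  withr::with_seed(seed, {
    f <- exp(rnorm(length(months), 0, precip_sd) - precip_sd^2 / 2)
    fac <- rep(f, lengths(months))
    forcings$precipitation <- forcings$precipitation * precip_bias * fac
    forcings$air_temperature <- forcings$air_temperature +
      rnorm(nrow(forcings), 0, temp_sd)
  })
  forcings
}

# number of days in the calendar month of each first-of-month date
days_in_month <- function(first) {
  as.integer(seq_months(first, 1) - first)
}

# shift first-of-month dates by k months
seq_months <- function(first, k) {
  lt <- as.POSIXlt(first)
  lt$mon <- lt$mon + k
  as.Date(lt)
}
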