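# Assimilation of the three observation kinds into the water-balance model
#
# Surface-water fraction observations are nudged into the surface store with
# a high gain; daily near-surface and monthly column-total observations are
# assimilated jointly with a stochastic (perturbed-observation) ensemble
# Kalman smoother over fixed calendar-month windows. The smoother state
# vector holds the daily below-surface stores for every day of the window,
# so the single monthly observation updates all days through the ensemble
# cross-covariance.

#' Saturating map between surface-water storage and observed water fraction
#'
#' `fraction = 1 - exp(-storage / scale)`; the inverse caps the fraction just
#' below 1 so that saturated observations invert to a finite storage.
#'
#' @param storage surface-water storage, mm.
#' @param fraction observed water fraction in \[0, 1\].
#' @param scale e-folding scale, mm.
#' @return the mapped fraction or storage.
#' @export
fraction_from_storage <- function(storage, scale = 10) {
  1 - exp(-storage / scale)
}

#' @rdname fraction_from_storage
#' @export
storage_from_fraction <- function(fraction, scale = 10) {
  if (any(fraction < 0 | fraction > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  -scale * log(1 - pmin(fraction, 1 - 1e-4))
}

#' Nudge the surface-water store toward an observed water fraction
#'
#' Relaxation toward the storage implied by the observed fraction:
#' `sw <- (1 - gain) * sw + gain * inverse(fraction)`. Other stores are
#' untouched.
#'
#' @param state a [column_state()].
#' @param fraction observed water fraction in \[0, 1\].
#' @param gain nudging gain in \[0, 1\] (1 replaces the model value).
#' @param scale scale of [storage_from_fraction()].
#' @return the nudged `column_state`.
#' @export
nudge_surface_water <- function(state, fraction, gain = 0.9, scale = 10) {
  stopifnot(inherits(state, "column_state"))
  if (gain < 0 || gain > 1) stop("gain must lie in [0, 1]", call. = FALSE)
  target <- storage_from_fraction(fraction, scale)
  st <- unclass(state)
  st["surface_water"] <- (1 - gain) * st["surface_water"] + gain * target
  do.call(column_state, as.list(unname(st)))
}

# per-member perturbation draws: multiplicative lognormal on precipitation
# (mean 1), additive Gaussian on temperature, multiplicative truncated
# Gaussian on radiation (mean 1, floored at 0)
.perturb_factors <- function(n_members, sd_precip, sd_temp, sd_rad, seed) {
  withr::with_seed(seed, list(
    precip = if (sd_precip > 0)
      exp(rnorm(n_members, -sd_precip^2 / 2, sd_precip)) else rep(1, n_members),
    temp = rnorm(n_members, 0, sd_temp),
    rad = pmax(rnorm(n_members, 1, sd_rad), 0)))
}

#' Perturb a forcing sequence into an ensemble
#'
#' Each member gets one multiplicative lognormal precipitation factor (unit
#' mean), one additive temperature offset and one multiplicative radiation
#' factor (unit mean, floored at zero), held constant over the sequence.
#'
#' @param forcings daily forcing tibble.
#' @param n_members ensemble size (>= 2).
#' @param sd_precip lognormal sd of the precipitation factor.
#' @param sd_temp sd of the temperature offset, degrees C.
#' @param sd_rad sd of the radiation factor.
#' @param seed integer seed.
#' @return list of `n_members` forcing tibbles.
#' @export
perturb_forcings <- function(forcings, n_members, sd_precip = 0.3,
                             sd_temp = 1, sd_rad = 0.1, seed = 1L) {
  if (n_members < 2) stop("n_members must be >= 2", call. = FALSE)
  f <- .perturb_factors(n_members, sd_precip, sd_temp, sd_rad, seed)
  lapply(seq_len(n_members), function(m) {
    fm <- forcings
    fm$precipitation <- fm$precipitation * f$precip[m]
    fm$air_temperature <- fm$air_temperature + f$temp[m]
    fm$net_radiation <- fm$net_radiation * f$rad[m]
    fm
  })
}

#' Ensemble of daily column states over one assimilation window
#'
#' @param dates Date vector of the window days (one calendar month).
#' @param states numeric array `(n_days, n_members, 4)`, the below-surface
#'   stores `s_top`, `s_shallow`, `s_deep`, `groundwater`.
#' @param surface_water matrix `(n_days, n_members)` of surface-water storage
#'   (carried alongside; not part of the smoother state vector but included
#'   in the column-total prediction).
#' @return an object of class `ensemble_window`.
#' @export
ensemble_window <- function(dates, states, surface_water) {
  stopifnot(length(dim(states)) == 3, dim(states)[3] == 4)
  if (dim(states)[2] < 2) stop("need at least 2 ensemble members", call. = FALSE)
  if (dim(states)[1] != length(dates) ||
      !all(dim(surface_water) == dim(states)[1:2])) {
    stop("window members must all span the same days", call. = FALSE)
  }
  structure(list(dates = dates, states = states, surface_water = surface_water),
            class = "ensemble_window")
}

# observations of an observation_set falling in the window
.window_obs <- function(window, observations) {
  ns <- observations$near_surface
  ns <- ns[ns$date %in% window$dates, , drop = FALSE]
  ct <- observations$column_total
  ct <- ct[ct$month == month_floor(window$dates[1]), , drop = FALSE]
  bad_ns <- observations$near_surface$date >= window$dates[1] &
    observations$near_surface$date <= window$dates[length(window$dates)] &
    !(observations$near_surface$date %in% window$dates)
  if (any(bad_ns)) stop("observation dated outside the window days", call. = FALSE)
  list(near_surface = ns, column_total = ct,
       y = c(ns$value, ct$value), sd = c(ns$sd, ct$sd))
}

#' Map ensemble states to predicted observations
#'
#' The near-surface prediction for an observed day is that day's top-layer
#' storage; the column-total prediction is the calendar-month mean of daily
#' total water storage (surface water included in the total even though it is
#' not part of the smoother state vector).
#'
#' @param window an [ensemble_window()].
#' @param observations an [observation_set()]; only records falling in the
#'   window are used. An observation dated inside the window span but on no
#'   window day is an error.
#' @return matrix `(n_obs, n_members)` of predicted observation values, in
#'   the order: near-surface records (by date), then the column total.
#' @export
observation_operator <- function(window, observations) {
  obs <- .window_obs(window, observations)
  n_members <- dim(window$states)[2]
  preds <- matrix(numeric(0), 0, n_members)
  if (nrow(obs$near_surface) > 0) {
    idx <- match(obs$near_surface$date, window$dates)
    preds <- window$states[idx, , 1, drop = FALSE]
    dim(preds) <- c(length(idx), n_members)
  }
  if (nrow(obs$column_total) > 0) {
    totals <- window$surface_water +
      window$states[, , 1] + window$states[, , 2] +
      window$states[, , 3] + window$states[, , 4]
    preds <- rbind(preds, colMeans(totals))
  }
  preds
}

#' Ensemble Kalman smoother update of one window
#'
#' Stochastic (perturbed-observation) update. The state vector stacks the
#' four below-surface stores for every day of the window (day-major: the four
#' stores of day 1, then day 2, ...). Every member is updated as
#' `x + K (y + e - H x)` with the gain from the ensemble sample
#' cross-covariance and the observation error covariance; all days of the
#' window are adjusted by the month's observations through the temporal
#' cross-covariances. Updated storages are clipped to \[0, capacity\]
#' (groundwater has no upper bound) and the clipped mass is reported.
#'
#' @param window an [ensemble_window()].
#' @param observations an [observation_set()] with at least one record in the
#'   window.
#' @param params the [column_params()] supplying the capacities.
#' @param seed integer seed for the observation perturbations.
#' @param inflation multiplicative inflation of ensemble anomalies (1 = none).
#' @return list: `window` (updated [ensemble_window()]), `increment` (matrix
#'   `(n_days, 4)`: posterior-mean minus prior-mean per day and store),
#'   `clip_mass` (total absolute storage removed or added by clipping, mm).
#' @export
enks_update <- function(window, observations, params = column_params(),
                        seed = 1L, inflation = 1) {
  obs <- .window_obs(window, observations)
  n_obs <- length(obs$y)
  if (n_obs < 1) stop("need at least one observation in the window", call. = FALSE)
  n_days <- dim(window$states)[1]
  n_members <- dim(window$states)[2]

  # day-major state matrix: row (d-1)*4 + s is store s on day d
  X <- matrix(aperm(window$states, c(3, 1, 2)), nrow = 4 * n_days)
  Y <- observation_operator(window, observations)

  A <- inflation * (X - rowMeans(X))
  HA <- inflation * (Y - rowMeans(Y))
  R <- diag(obs$sd^2, n_obs)
  Pyy <- HA %*% t(HA) / (n_members - 1) + R
  if (rcond(Pyy) < 1e-12) {
    stop("singular innovation covariance; increase the ensemble size or inflation",
         call. = FALSE)
  }
  K <- (A %*% t(HA) / (n_members - 1)) %*% solve(Pyy)

  E <- withr::with_seed(seed,
    matrix(rnorm(n_obs * n_members, 0, obs$sd), n_obs, n_members))
  Xpost <- X + K %*% (obs$y + E - Y)

  post <- aperm(array(Xpost, dim = c(4, n_days, n_members)), c(2, 3, 1))
  caps <- c(params$cap_top, params$cap_shallow, params$cap_deep, Inf)
  clip_mass <- 0
  for (s in 1:4) {
    clipped <- pmin(pmax(post[, , s], 0), caps[s])
    clip_mass <- clip_mass + sum(abs(clipped - post[, , s]))
    post[, , s] <- clipped
  }
  prior_mean <- apply(window$states, c(1, 3), mean)
  post_mean <- apply(post, c(1, 3), mean)
  list(window = ensemble_window(window$dates, post, window$surface_water),
       increment = post_mean - prior_mean,
       clip_mass = clip_mass)
}

#' Assimilate a full observation record month by month
#'
#' Iterates over calendar-month windows: propagates the forcing-perturbed
#' ensemble through the water-balance model, nudges the surface-water store
#' at 8-day fraction observations, applies the ensemble Kalman smoother with
#' the month's near-surface and column-total observations, and reinitialises
#' the next month from the updated end-of-month member states. A month with
#' no smoother observations is propagated open loop (with a notice).
#'
#' The returned flux and increment ledgers close the water balance of the
#' posterior-mean trajectory exactly: for every day, the change in total
#' analysis storage equals the ensemble-mean net flux plus the ledgered
#' nudging and smoother increments (see [check_mass_balance()]).
#'
#' @param forcings daily forcing tibble covering whole calendar months.
#' @param observations an [observation_set()] (may be empty for an open-loop
#'   run); observation dates must fall within the forcing span.
#' @param params a [column_params()].
#' @param initial a [column_state()]; default starts the soil stores at 40%
#'   of capacity with 150 mm of groundwater.
#' @param n_members ensemble size, default 100.
#' @param seed integer root seed for perturbations and observation noise.
#' @param pet optional daily PET series; by default PET is recomputed per
#'   member from the perturbed forcings.
#' @param rh relative humidity for the PET computation, percent.
#' @param sd_precip,sd_temp,sd_rad forcing perturbation magnitudes (see
#'   [perturb_forcings()]).
#' @param nudge_gain gain of the surface-water nudging.
#' @param inflation ensemble anomaly inflation passed to [enks_update()].
#' @param quiet suppress open-loop-month notices.
#' @return list: `analysis` (daily posterior-mean states tibble, first row the
#'   initial state), `spread` (daily ensemble sd per store), `fluxes`
#'   (ensemble-mean flux ledger), `increments` (tibble `date`, `store`,
#'   `increment_mm`, `source` in nudge/enks), `clip_mass`.
#' @export
assimilate_series <- function(forcings, observations,
                              params = column_params(), initial = NULL,
                              n_members = 100, seed = 1L,
                              pet = NULL, rh = 60,
                              sd_precip = 0.3, sd_temp = 1, sd_rad = 0.1,
                              nudge_gain = 0.9, inflation = 1,
                              quiet = FALSE) {
  if (n_members < 2) stop("n_members must be >= 2", call. = FALSE)
  initial <- initial %||% column_state(0, 0.4 * params$cap_top,
                                       0.4 * params$cap_shallow,
                                       0.4 * params$cap_deep, 150)
  dates <- forcings$date
  obs_dates <- c(observations$near_surface$date, observations$column_total$month,
                 observations$surface_fraction$date)
  if (length(obs_dates) > 0 &&
      (min(obs_dates) < min(dates) || max(obs_dates) > max(dates))) {
    stop("observation dates must fall within the forcing span", call. = FALSE)
  }
  months <- split_by_month(dates)
  n_days_tot <- length(dates)
  caps <- c(params$cap_top, params$cap_shallow, params$cap_deep, Inf)

  M <- matrix(rep(unclass(initial), each = n_members), n_members, 5)
  analysis <- matrix(NA_real_, n_days_tot + 1, 5,
                     dimnames = list(NULL, STORE_NAMES))
  spread <- matrix(NA_real_, n_days_tot, 5, dimnames = list(NULL, STORE_NAMES))
  fluxes <- matrix(NA_real_, n_days_tot, 4,
                   dimnames = list(NULL, c("precip_in", "et", "discharge", "sw_loss")))
  analysis[1, ] <- unclass(initial)
  inc_rows <- list()
  clip_total <- 0
  prev_mean <- colMeans(M)   # posterior mean at the day before the window

  for (w in seq_along(months)) {
    idx <- months[[w]]
    nd <- length(idx)
    fw <- forcings[idx, , drop = FALSE]
    fac <- .perturb_factors(n_members, sd_precip, sd_temp, sd_rad,
                            spawn_seed(seed, "perturb", w))
    precip_m <- outer(fw$precipitation + (fw$snowfall_rate %||% 0), fac$precip)
    temp_m <- outer(fw$air_temperature, rep(1, n_members)) +
      matrix(fac$temp, nd, n_members, byrow = TRUE)
    rad_m <- outer(fw$net_radiation, fac$rad)
    pet_m <- if (is.null(pet)) {
      matrix(pet_penman_monteith(temp_m, rad_m,
                                 matrix(fw$wind_speed, nd, n_members),
                                 matrix(fw$surface_pressure, nd, n_members),
                                 rh = rh), nd, n_members)
    } else {
      matrix(pet[idx], nd, n_members)
    }

    sfr <- observations$surface_fraction
    sfr <- sfr[sfr$date %in% fw$date, , drop = FALSE]

    states_w <- array(NA_real_, dim = c(nd, n_members, 4))
    sw_w <- matrix(NA_real_, nd, n_members)
    for (d in seq_len(nd)) {
      out <- .step_matrix(M, precip_m[d, ], pet_m[d, ], params)
      M <- out$S
      fluxes[idx[d], ] <- colMeans(out$fluxes)
      hit <- which(sfr$date == fw$date[d])
      if (length(hit) == 1) {
        target <- storage_from_fraction(sfr$value[hit], observations$sw_frac_scale)
        before <- mean(M[, 1])
        M[, 1] <- (1 - nudge_gain) * M[, 1] + nudge_gain * target
        inc_rows[[length(inc_rows) + 1]] <- tibble::tibble(
          date = fw$date[d], store = "surface_water",
          increment_mm = mean(M[, 1]) - before, source = "nudge")
      }
      sw_w[d, ] <- M[, 1]
      states_w[d, , ] <- M[, 2:5]
    }

    window <- ensemble_window(fw$date, states_w, sw_w)
    wobs <- .window_obs(window, observations)
    prior_mean_w <- apply(states_w, c(1, 3), mean)
    if (length(wobs$y) >= 1) {
      upd <- enks_update(window, observations, params = params,
                         seed = spawn_seed(seed, "enks", w),
                         inflation = inflation)
      states_w <- upd$window$states
      clip_total <- clip_total + upd$clip_mass
      post_mean_w <- apply(states_w, c(1, 3), mean)
      # ledger the day-to-day change of the smoother adjustment so that the
      # posterior-mean trajectory closes day by day
      adj <- post_mean_w - prior_mean_w
      daily_inc <- rbind(adj[1, ], diff(adj))
      inc_rows[[length(inc_rows) + 1]] <- tibble::tibble(
        date = rep(fw$date, 4),
        store = rep(SOIL_STORES, each = nd),
        increment_mm = as.vector(daily_inc),
        source = "enks")
      M[, 2:5] <- states_w[nd, , ]
    } else if (!quiet) {
      message(sprintf("window %s: no smoother observations; open loop",
                      format(fw$date[1], "%Y-%m")))
    }

    analysis[idx + 1, 2:5] <- apply(states_w, c(1, 3), mean)
    analysis[idx + 1, 1] <- rowMeans(sw_w)
    spread[idx, 1] <- apply(sw_w, 1, sd)
    spread[idx, 2:5] <- apply(states_w, c(1, 3), sd)
  }

  increments <- if (length(inc_rows) > 0) {
    dplyr::bind_rows(inc_rows)
  } else {
    tibble::tibble(date = as.Date(character()), store = character(),
                   increment_mm = numeric(), source = character())
  }
  list(
    analysis = tibble::as_tibble(cbind(
      data.frame(date = c(dates[1] - 1, dates)), as.data.frame(analysis))),
    spread = tibble::as_tibble(cbind(data.frame(date = dates),
                                     as.data.frame(spread))),
    fluxes = tibble::as_tibble(cbind(data.frame(date = dates),
                                     as.data.frame(fluxes))),
    increments = increments,
    clip_mass = clip_total)
}
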