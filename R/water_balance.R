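# Layered bucket water-balance model
#
# A deliberately simple surrogate for a full ecohydrological land-surface
# scheme: one soil column with surface water, three unsaturated soil layers
# (top 0-5 cm, shallow 5-100 cm, deep 1-10 m) and an unconfined groundwater
# store, integrated explicitly at a daily step. The model serves both as the
# truth generator for synthetic experiments and as the forecast model inside
# the assimilation loop, so exact per-step mass closure is part of its
# contract.

STORE_NAMES <- c("surface_water", "s_top", "s_shallow", "s_deep", "groundwater")
SOIL_STORES <- c("s_top", "s_shallow", "s_deep", "groundwater")

#' Water column state for one pixel-day
#'
#' All stores are in mm of equivalent water thickness. Soil stores are capped
#' by the capacities in [column_params()]; surface water and groundwater are
#' unbounded above.
#'
#' @param surface_water,s_top,s_shallow,s_deep,groundwater store contents, mm.
#' @return an object of class `column_state` (a named numeric vector).
#' @export
#' @examples
#' column_state(s_top = 10, s_shallow = 80)
column_state <- function(surface_water = 0, s_top = 0, s_shallow = 0,
                         s_deep = 0, groundwater = 0) {
  x <- c(surface_water = surface_water, s_top = s_top, s_shallow = s_shallow,
         s_deep = s_deep, groundwater = groundwater)
  check_finite(x, "column_state")
  if (any(x < 0)) {
    stop(sprintf("negative storage in field '%s'", names(x)[which(x < 0)[1]]),
         call. = FALSE)
  }
  structure(x, class = "column_state")
}

#' Parameters of the layered water-balance column
#'
#' Flux forms are first-order: drainage from a layer and groundwater discharge
#' are linear in the donor store, capillary rise is linear in groundwater
#' capped by the deep-layer deficit, and actual evapotranspiration is
#' potential evapotranspiration times a saturating storage stress per layer
#' weighted by root access. Infiltration fills the layers in cascade
#' (top, shallow, deep, then groundwater). Surface runoff is generated only by
#' rainfall in excess of an infiltration threshold and decays exponentially.
#'
#' Defaults are fixture choices giving the layers strongly contrasting
#' memories (days / weeks / seasons / years from top to groundwater), the
#' property the downstream depth inference relies on.
#'
#' @param cap_top,cap_shallow,cap_deep soil layer capacities, mm.
#' @param drain_top,drain_shallow,drain_deep drainage coefficients, 1/day.
#' @param cap_rise capillary-rise coefficient (groundwater to deep layer), 1/day.
#' @param gw_discharge groundwater discharge coefficient, 1/day.
#' @param half_sat evapotranspiration stress half-saturation per store
#'   (top, shallow, deep, groundwater), mm.
#' @param access_shallow_veg,access_deep_veg root-access fractions of
#'   shallow-rooted and deep-rooted vegetation for the four below-surface
#'   stores, each in \[0, 1\].
#' @param frac_deep_veg areal fraction of deep-rooted vegetation in \[0, 1\].
#' @param runoff_coef fraction of above-threshold rainfall routed to surface
#'   water.
#' @param runoff_threshold rainfall intensity above which runoff is generated,
#'   mm/day.
#' @param sw_decay surface-water decay coefficient, 1/day.
#' @return an object of class `column_params`.
#' @export
column_params <- function(cap_top = 25, cap_shallow = 250, cap_deep = 800,
                          drain_top = 0.25, drain_shallow = 0.03,
                          drain_deep = 0.006, cap_rise = 0.001,
                          gw_discharge = 0.004,
                          half_sat = c(top = 5, shallow = 40, deep = 120, gw = 200),
                          access_shallow_veg = c(top = 0.35, shallow = 0.40,
                                                 deep = 0.05, gw = 0),
                          access_deep_veg = c(top = 0.10, shallow = 0.30,
                                              deep = 0.40, gw = 0.10),
                          frac_deep_veg = 0.5,
                          runoff_coef = 0.5, runoff_threshold = 10,
                          sw_decay = 0.5) {
  p <- list(cap_top = cap_top, cap_shallow = cap_shallow, cap_deep = cap_deep,
            drain_top = drain_top, drain_shallow = drain_shallow,
            drain_deep = drain_deep, cap_rise = cap_rise,
            gw_discharge = gw_discharge, half_sat = half_sat,
            access_shallow_veg = access_shallow_veg,
            access_deep_veg = access_deep_veg,
            frac_deep_veg = frac_deep_veg,
            runoff_coef = runoff_coef, runoff_threshold = runoff_threshold,
            sw_decay = sw_decay)
  check_finite(p, "column_params")
  coefs <- c(drain_top, drain_shallow, drain_deep, cap_rise, gw_discharge,
             runoff_coef, sw_decay)
  if (any(coefs < 0)) stop("all rate coefficients must be >= 0", call. = FALSE)
  if (any(coefs > 1)) stop("rate coefficients are daily fractions and must be <= 1",
                           call. = FALSE)
  fr <- c(access_shallow_veg, access_deep_veg, frac_deep_veg)
  if (any(fr < 0 | fr > 1)) {
    stop("root-access fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "column_params")
}

# effective per-store root access, mixing the two vegetation classes
effective_access <- function(params) {
  f <- params$frac_deep_veg
  (1 - f) * params$access_shallow_veg + f * params$access_deep_veg
}

# Core daily step on a member matrix S (n_members x 5 stores, columns in
# STORE_NAMES order). precip and pet are scalars or length-n vectors.
# Flux order is fixed (infiltration, ET, drainage, capillary rise, discharge)
# and part of the model definition: permuting it changes results at the
# second decimal.
.step_matrix <- function(S, precip, pet, params) {
  n <- nrow(S)
  precip <- rep_len(precip, n)
  pet <- rep_len(pet, n)
  caps <- c(params$cap_top, params$cap_shallow, params$cap_deep)

  # infiltration-excess runoff to surface water; the rest infiltrates
  runoff <- params$runoff_coef * pmax(precip - params$runoff_threshold, 0)
  infil <- precip - runoff
  S[, 1] <- S[, 1] + runoff
  for (j in 2:4) {
    take <- pmin(infil, caps[j - 1] - S[, j])
    S[, j] <- S[, j] + take
    infil <- infil - take
  }
  S[, 5] <- S[, 5] + infil

  # actual ET: saturating stress per store, weighted by root access,
  # never more than the store holds
  acc <- effective_access(params)
  hs <- params$half_sat
  et_total <- numeric(n)
  for (j in 2:5) {
    s <- S[, j]
    demand <- pet * acc[j - 1] * s / (s + hs[j - 1])
    demand[s <= 0] <- 0
    et_j <- pmin(demand, s)
    S[, j] <- s - et_j
    et_total <- et_total + et_j
  }

  # gravity drainage down the cascade, overflow continues downwards
  for (j in 2:4) {
    coef <- c(params$drain_top, params$drain_shallow, params$drain_deep)[j - 1]
    dr <- coef * S[, j]
    S[, j] <- S[, j] - dr
    k <- j + 1
    while (k <= 4 && any(dr > 0)) {
      take <- pmin(dr, caps[k - 1] - S[, k])
      S[, k] <- S[, k] + take
      dr <- dr - take
      k <- k + 1
    }
    if (k == 5) S[, 5] <- S[, 5] + dr
  }

  # capillary rise groundwater -> deep layer, capped by the deep deficit
  cr <- pmin(params$cap_rise * S[, 5], caps[3] - S[, 4])
  S[, 5] <- S[, 5] - cr
  S[, 4] <- S[, 4] + cr

  # losses out of the column
  q <- params$gw_discharge * S[, 5]
  S[, 5] <- S[, 5] - q
  sw_loss <- params$sw_decay * S[, 1]
  S[, 1] <- S[, 1] - sw_loss

  list(S = S,
       fluxes = cbind(precip_in = precip, et = et_total,
                      discharge = q, sw_loss = sw_loss))
}

#' Advance the water column by one day
#'
#' Applies, in fixed order, infiltration (with infiltration-excess runoff to
#' surface water and cascade filling of the soil layers), actual
#' evapotranspiration, drainage, capillary rise and discharge. The water
#' balance closes exactly: the change in total storage equals precipitation
#' minus evapotranspiration, groundwater discharge and surface-water loss.
#'
#' @param state a [column_state()].
#' @param forcing a list or one-row data frame with fields `precipitation`,
#'   `air_temperature`, `net_radiation`, `wind_speed`, `surface_pressure`,
#'   `snowfall_rate` (snowfall is added to precipitation; no snowpack is
#'   simulated).
#' @param pet potential evapotranspiration, mm/day, `>= 0`.
#' @param params a [column_params()].
#' @return the next-day `column_state`, with the day's fluxes (mm) attached as
#'   attribute `"fluxes"` (`precip_in`, `et`, `discharge`, `sw_loss`).
#' @export
step_day <- function(state, forcing, pet, params = column_params()) {
  stopifnot(inherits(state, "column_state"))
  f <- as.list(forcing)
  check_finite(f[c("precipitation", "air_temperature", "net_radiation",
                   "wind_speed", "surface_pressure", "snowfall_rate")],
               "forcing")
  check_finite(unclass(state), "state")
  if (f$precipitation < 0) stop("precipitation must be >= 0", call. = FALSE)
  if (!is.finite(pet) || pet < 0) stop("pet must be finite and >= 0", call. = FALSE)
  p_total <- f$precipitation + (f$snowfall_rate %||% 0)
  out <- .step_matrix(matrix(unclass(state), nrow = 1), p_total, pet, params)
  st <- column_state(out$S[1, 1], out$S[1, 2], out$S[1, 3], out$S[1, 4], out$S[1, 5])
  attr(st, "fluxes") <- out$fluxes[1, ]
  st
}

#' Run the water-balance model over a forcing sequence
#'
#' @param initial a [column_state()] valid at the day before the first forcing.
#' @param forcings tibble of daily forcings with columns `date`,
#'   `precipitation`, `air_temperature`, `net_radiation`, `wind_speed`,
#'   `surface_pressure`, `snowfall_rate`.
#' @param pet_series daily potential evapotranspiration, mm/day, same length
#'   as `forcings`.
#' @param params a [column_params()].
#' @return list with `states` (tibble: `date` plus the five stores; the first
#'   row is the initial state dated the day before the first forcing) and
#'   `fluxes` (tibble: `date`, `precip_in`, `et`, `discharge`, `sw_loss`).
#' @export
run_simulation <- function(initial, forcings, pet_series,
                           params = column_params()) {
  stopifnot(inherits(initial, "column_state"))
  n <- nrow(forcings)
  if (n < 1) stop("forcings must have at least one day", call. = FALSE)
  if (length(pet_series) != n) {
    stop("forcings and pet_series must have the same length", call. = FALSE)
  }
  check_finite(list(precipitation = forcings$precipitation,
                    pet = pet_series), "forcing series")
  if (any(forcings$precipitation < 0)) stop("precipitation must be >= 0", call. = FALSE)
  if (any(pet_series < 0)) stop("pet must be >= 0", call. = FALSE)

  precip <- forcings$precipitation + (forcings$snowfall_rate %||% 0)
  states <- matrix(NA_real_, n + 1, 5, dimnames = list(NULL, STORE_NAMES))
  fluxes <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, c("precip_in", "et", "discharge", "sw_loss")))
  S <- matrix(unclass(initial), nrow = 1)
  states[1, ] <- S
  for (t in seq_len(n)) {
    out <- .step_matrix(S, precip[t], pet_series[t], params)
    S <- out$S
    states[t + 1, ] <- S
    fluxes[t, ] <- out$fluxes
  }
  list(
    states = tibble::as_tibble(cbind(
      data.frame(date = c(forcings$date[1] - 1, forcings$date)),
      as.data.frame(states))),
    fluxes = tibble::as_tibble(cbind(data.frame(date = forcings$date),
                                     as.data.frame(fluxes)))
  )
}

#' Total column water storage
#'
#' Sum of surface water, the three soil stores and groundwater, in mm.
#' Biomass water is not represented in this column model.
#'
#' @param state a [column_state()] or a states tibble from [run_simulation()].
#' @return a scalar (for a single state) or a vector (one value per row).
#' @export
total_water_storage <- function(state) {
  if (inherits(state, "column_state")) return(sum(unclass(state)))
  rowSums(as.matrix(state[, STORE_NAMES]))
}

#' Maximum mass-balance closure error of a trajectory
#'
#' Recomputes, for every step, the difference between the change in total
#' storage and the net flux (precipitation in, minus evapotranspiration,
#' discharge and surface-water loss, plus any assimilation increments), and
#' returns the largest absolute discrepancy in mm.
#'
#' @param states states tibble (one row more than `fluxes`).
#' @param fluxes fluxes tibble from [run_simulation()] or [assimilate_series()].
#' @param increments optional increments ledger tibble with columns `date`,
#'   `store`, `increment_mm` (as written by [assimilate_series()]); increments
#'   are credited to the day they were applied.
#' @return max absolute closure error, mm.
#' @export
check_mass_balance <- function(states, fluxes, increments = NULL) {
  if (nrow(states) != nrow(fluxes) + 1) {
    stop("trajectory must be one row longer than the flux ledger", call. = FALSE)
  }
  total <- total_water_storage(states)
  delta <- diff(total)
  net <- fluxes$precip_in - fluxes$et - fluxes$discharge - fluxes$sw_loss
  if (!is.null(increments) && nrow(increments) > 0) {
    inc <- tapply(increments$increment_mm, as.character(increments$date), sum)
    idx <- match(names(inc), as.character(fluxes$date))
    if (anyNA(idx)) stop("increment dated outside the flux ledger", call. = FALSE)
    net[idx] <- net[idx] + as.numeric(inc)
  }
  max(abs(delta - net))
}
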