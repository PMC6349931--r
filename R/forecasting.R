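# Statistical greenness forecasting and hindcast evaluation
#
# The deterministic anomaly forecast is a linear combination of the current
# greenness anomaly (unit coefficient, as defined) and the current
# accessible-storage anomaly:
#   dV_{t0 + t} = dV_{t0} + beta1 * S_{z, t0} + beta2.
# Baselines: persistence (same anomaly next month), climatology (mean of
# past observations of the target calendar month) and an antecedent
# precipitation index used in place of the storage anomaly. Skill is
# evaluated by three-fold segment-wise hindcast cross-validation with
# Spearman rank correlation against observed greenness.

#' Fit the storage-based anomaly forecast model
#'
#' Least-squares fit of `dV(t0 + lead) - dV(t0)` on `S(t0)` with intercept;
#' the persistence term enters with a fixed unit coefficient, so only the
#' storage slope `beta1` and intercept `beta2` are estimated.
#'
#' @param dv monthly greenness anomaly series.
#' @param s monthly accessible-storage anomaly series aligned with `dv`.
#' @param lead forecast lead in months (1..12).
#' @param train optional integer index of months usable for training; a
#'   training pair is used only when both its endpoints are in `train`.
#' @return an object of class `forecast_model` with elements `lead`, `beta1`,
#'   `beta2`, `n_train`.
#' @export
fit_forecast_model <- function(dv, s, lead, train = NULL) {
  n <- length(dv)
  if (length(s) != n) stop("dv and s must be aligned", call. = FALSE)
  if (lead < 1 || lead > 12) stop("lead must be in 1..12", call. = FALSE)
  t0 <- seq_len(n - lead)
  if (!is.null(train)) t0 <- t0[t0 %in% train & (t0 + lead) %in% train]
  y <- dv[t0 + lead] - dv[t0]
  x <- s[t0]
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 12) stop("need at least 12 training triplets", call. = FALSE)
  if (sd(x) == 0) {
    warning("constant storage predictor; degenerating to persistence plus intercept",
            call. = FALSE)
    beta1 <- 0
    beta2 <- mean(y)
  } else {
    beta1 <- cov(x, y) / var(x)
    beta2 <- mean(y) - beta1 * mean(x)
  }
  structure(list(lead = lead, beta1 = beta1, beta2 = beta2,
                 n_train = length(y)), class = "forecast_model")
}

#' Forecast absolute greenness from current anomalies
#'
#' Applies the anomaly forecast and adds back the seasonal climatology of the
#' target month (computed excluding the evaluation period), clipping to
#' \[0, 1\].
#'
#' @param model a [fit_forecast_model()] fit.
#' @param dv0 current greenness anomaly.
#' @param s0 current accessible-storage anomaly.
#' @param climatology NDVI seasonal climatology (length 12).
#' @param target_month calendar month number (1-12) of the forecast month.
#' @return absolute NDVI forecast in \[0, 1\]. Vectorised over `dv0`, `s0`
#'   and `target_month`.
#' @export
forecast_greenness <- function(model, dv0, s0, climatology, target_month) {
  stopifnot(inherits(model, "forecast_model"), length(climatology) == 12)
  dvt <- dv0 + model$beta1 * s0 + model$beta2
  pmin(pmax(dvt + climatology[target_month], 0), 1)
}

#' Persistence forecast of the greenness anomaly
#'
#' The next months are assumed to keep the current anomaly.
#'
#' @param dv0 current greenness anomaly.
#' @return the same anomaly.
#' @export
persistence_forecast <- function(dv0) dv0

#' Climatology forecast of absolute greenness
#'
#' The mean of previous available observations of the target calendar month,
#' excluding an optional held-out segment.
#'
#' @param values observed monthly NDVI history.
#' @param months calendar month number (1-12) of each value.
#' @param target_month month to forecast.
#' @param exclude optional index of values excluded (the evaluation segment).
#' @return mean NDVI of the target calendar month.
#' @export
climatology_forecast <- function(values, months, target_month, exclude = NULL) {
  use <- rep(TRUE, length(values))
  if (!is.null(exclude)) use[exclude] <- FALSE
  sel <- use & months == target_month & !is.na(values)
  if (!any(sel)) {
    stop(sprintf("no observation of calendar month %d outside the excluded set",
                 target_month), call. = FALSE)
  }
  mean(values[sel])
}

#' Antecedent precipitation index
#'
#' Exponentially decayed running precipitation sum,
#' `API_t = k * API_{t-1} + P_t` with `API_0 = 0`.
#'
#' @param precipitation precipitation series (daily or monthly), mm, `>= 0`.
#' @param k decay coefficient per step in (0, 1), default 0.9.
#' @return API series of the same length.
#' @export
api_index <- function(precipitation, k = 0.9) {
  if (k <= 0 || k >= 1) stop("decay coefficient k must lie in (0, 1)", call. = FALSE)
  if (any(precipitation < 0)) stop("precipitation must be >= 0", call. = FALSE)
  as.numeric(stats::filter(precipitation, k, method = "recursive"))
}

#' Monthly API predictor from daily precipitation
#'
#' The daily API sampled on the last day of each calendar month, the monthly
#' predictor used in place of the storage anomaly in the forecast equation.
#'
#' @param forcings daily forcing tibble with `date` and `precipitation`.
#' @param k daily decay coefficient.
#' @return tibble `month`, `api`.
#' @export
api_monthly <- function(forcings, k = 0.9) {
  api <- api_index(forcings$precipitation, k)
  months <- split_by_month(forcings$date)
  last <- vapply(months, max, integer(1))
  tibble::tibble(month = month_floor(forcings$date[last]), api = api[last])
}

# contiguous three-fold (or n-fold) segmentation; trailing months join the
# last segment
hindcast_segments <- function(n_months, n_segments = 3, min_segment = 12) {
  base <- n_months %/% n_segments
  if (base < min_segment) {
    stop(sprintf("segments of %d months are too short (need >= %d)",
                 base, min_segment), call. = FALSE)
  }
  starts <- (seq_len(n_segments) - 1) * base + 1
  ends <- c(starts[-1] - 1, n_months)
  lapply(seq_len(n_segments), function(g) seq(starts[g], ends[g]))
}

#' Segment-wise hindcast forecasts for all methods
#'
#' Splits the record into `n_segments` contiguous segments; each segment is
#' forecast with climatologies and model coefficients derived exclusively
#' from the other segments. Storage-type predictors use the anomaly forecast
#' equation; `persistence` and `climatology` baselines are always included.
#'
#' @param greenness tibble `month`, `month_num`, `ndvi`.
#' @param predictors named list of monthly predictor series (levels, e.g.
#'   monthly-mean storage or API), each aligned with `greenness`.
#' @param leads forecast leads in months.
#' @param n_segments number of hindcast segments, default 3.
#' @return tibble: `segment`, `lead`, `method`, `t0`, `month`, `forecast`,
#'   `observed` — one row per held-out forecast.
#' @export
hindcast_forecasts <- function(greenness, predictors = list(),
                               leads = 1:12, n_segments = 3) {
  n <- nrow(greenness)
  segs <- hindcast_segments(n, n_segments)
  mn <- greenness$month_num
  rows <- list()
  for (g in seq_along(segs)) {
    ev <- segs[[g]]
    train <- setdiff(seq_len(n), ev)
    dec <- monthly_anomalies(greenness$ndvi, mn, exclude = ev)
    clim <- dec$climatology
    dv <- dec$anomalies
    s_anom <- lapply(predictors, function(p) {
      monthly_anomalies(p, mn, exclude = ev)$anomalies
    })
    for (lead in leads) {
      targets <- ev[ev > lead]
      t0 <- targets - lead
      obs <- greenness$ndvi[targets]
      base <- tibble::tibble(segment = g, lead = lead, t0 = t0,
                             month = greenness$month[targets], observed = obs)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        base, method = "persistence",
        forecast = pmin(pmax(dv[t0] + clim[mn[targets]], 0), 1))
      rows[[length(rows) + 1]] <- dplyr::mutate(
        base, method = "climatology", forecast = clim[mn[targets]])
      for (p in names(predictors)) {
        fm <- fit_forecast_model(dv, s_anom[[p]], lead, train = train)
        rows[[length(rows) + 1]] <- dplyr::mutate(
          base, method = p,
          forecast = forecast_greenness(fm, dv[t0], s_anom[[p]][t0],
                                        clim, mn[targets]))
      }
    }
  }
  dplyr::bind_rows(rows)[, c("segment", "lead", "method", "t0", "month",
                             "forecast", "observed")]
}

#' Hindcast skill per method and lead
#'
#' Pools the held-out forecasts of [hindcast_forecasts()] across segments and
#' computes the Spearman rank correlation with observed greenness, per method
#' and lead. The reported NDVI-only reference per pixel is the better of the
#' persistence and climatology baselines.
#'
#' @inheritParams hindcast_forecasts
#' @return list: `skill` (tibble `method`, `lead`, `rho`, `n`), `forecasts`
#'   (the pooled forecast table).
#' @export
hindcast_evaluate <- function(greenness, predictors = list(),
                              leads = 1:12, n_segments = 3) {
  fc <- hindcast_forecasts(greenness, predictors, leads, n_segments)
  skill <- fc |>
    dplyr::group_by(method, lead) |>
    dplyr::summarise(
      rho = suppressWarnings(cor(forecast, observed, method = "spearman")),
      n = dplyr::n(), .groups = "drop")
  list(skill = skill, forecasts = fc)
}

#' Best NDVI-only baseline skill per lead
#'
#' @param skill the skill tibble of [hindcast_evaluate()].
#' @return tibble `lead`, `rho_ndvi`: the pointwise best of the persistence
#'   and climatology baselines.
#' @export
baseline_best <- function(skill) {
  skill |>
    dplyr::filter(method %in% c("persistence", "climatology")) |>
    dplyr::group_by(lead) |>
    dplyr::summarise(rho_ndvi = max(rho, na.rm = TRUE), .groups = "drop")
}
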