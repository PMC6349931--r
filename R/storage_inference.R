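# Inference of vegetation-accessible storage
#
# The depth range whose water-storage anomalies best predict future greenness
# anomalies is taken as the vegetation-accessible storage. Candidate depths
# are the nested integrations of the model column; association is measured by
# Spearman rank correlation at lead times of 1 to 12 months.

#' Candidate integration-depth classes
#'
#' Nested vertical integrations of the water column, from surface water alone
#' to the full column: `surface` (surface water), `top` (0-5 cm soil),
#' `top_shallow` (0-100 cm), `top_shallow_deep` (0-10 m) and `all` (the full
#' column including surface water and groundwater).
#'
#' @return character vector of the five class names, shallowest first.
#' @export
depth_classes <- function() {
  c("surface", "top", "top_shallow", "top_shallow_deep", "all")
}

#' Integrate daily storage over each depth class
#'
#' @param states states tibble from [run_simulation()] or
#'   [assimilate_series()] (rows dated before the first forcing day are kept).
#' @return tibble: `date` plus one column of integrated storage (mm) per
#'   depth class.
#' @export
integrate_storage <- function(states) {
  tibble::tibble(
    date = states$date,
    surface = states$surface_water,
    top = states$s_top,
    top_shallow = states$s_top + states$s_shallow,
    top_shallow_deep = states$s_top + states$s_shallow + states$s_deep,
    all = total_water_storage(states))
}

#' Calendar-month means of a daily storage table
#'
#' @param daily tibble with a `date` column and numeric storage columns. A
#'   leading initial-condition row dated the day before the record starts is
#'   dropped; every calendar month present is averaged as found.
#' @return tibble: `month` (first-of-month Date), `month_num` (1-12), and the
#'   monthly mean of every storage column.
#' @export
monthly_storage <- function(daily) {
  # drop a leading initial-condition row dated the day before the record
  if (nrow(daily) > 1 && daily$date[1] == daily$date[2] - 1 &&
      format(daily$date[1], "%d") != "01") {
    daily <- daily[-1, , drop = FALSE]
  }
  key <- format(daily$date, "%Y-%m")
  ukey <- unique(key)
  vals <- daily[setdiff(names(daily), "date")]
  out <- lapply(vals, function(v) as.numeric(tapply(v, key, mean)[ukey]))
  month <- as.Date(paste0(ukey, "-01"))
  dplyr::bind_cols(tibble::tibble(month = month, month_num = month_of(month)),
                   tibble::as_tibble(out))
}

#' Seasonal climatology and anomalies of a monthly series
#'
#' The climatology of calendar month m is the mean over its non-excluded
#' occurrences; the anomaly is the value minus the climatology of its month.
#' By construction the mean anomaly of each calendar month over non-excluded
#' data is zero, and climatology plus anomaly reconstructs the input exactly.
#'
#' @param values monthly values (>= 24).
#' @param months calendar month number (1-12) of each value.
#' @param exclude optional integer or logical index of values to exclude from
#'   the climatology (e.g. a held-out evaluation segment).
#' @return list with `climatology` (length 12) and `anomalies` (same length
#'   as `values`).
#' @export
monthly_anomalies <- function(values, months, exclude = NULL) {
  if (length(values) < 24) stop("need at least 24 months", call. = FALSE)
  if (length(months) != length(values)) {
    stop("values and months must be aligned", call. = FALSE)
  }
  use <- rep(TRUE, length(values))
  if (!is.null(exclude)) use[exclude] <- FALSE
  use <- use & !is.na(values)
  if (!all(1:12 %in% months[use])) {
    stop("every calendar month must be represented outside the excluded set",
         call. = FALSE)
  }
  clim <- as.numeric(tapply(values[use], factor(months[use], levels = 1:12), mean))
  list(climatology = clim, anomalies = values - clim[months])
}

#' Lagged Spearman rank correlation
#'
#' Correlates `x` at time t with `y` at time t + lag, using average ranks for
#' ties and dropping incomplete pairs.
#'
#' @param x,y aligned monthly series.
#' @param lag forward shift of `y` in months (>= 0).
#' @param min_n minimum number of complete pairs required.
#' @return Spearman rho in \[-1, 1\], or `NA` if either rank series is
#'   constant over the overlap.
#' @export
lagged_spearman <- function(x, y, lag = 0, min_n = 12) {
  n <- length(x)
  if (length(y) != n) stop("x and y must be aligned", call. = FALSE)
  if (lag < 0 || lag >= n) stop("lag must be in [0, length(x) - 1]", call. = FALSE)
  xi <- x[seq_len(n - lag)]
  yi <- y[seq_len(n - lag) + lag]
  ok <- !is.na(xi) & !is.na(yi)
  if (sum(ok) < min_n) {
    stop(sprintf("only %d complete pairs at lag %d (need >= %d)",
                 sum(ok), lag, min_n), call. = FALSE)
  }
  suppressWarnings(cor(xi[ok], yi[ok], method = "spearman"))
}

#' Select the vegetation-accessible integration depth
#'
#' For each depth class, correlates the monthly storage anomaly with the
#' greenness anomaly over the subsequent 1 to 12 months; a class's score is
#' its maximum lagged rho. The optimal class maximises the score, with ties
#' broken toward the shallower class. Pixels whose best score falls below
#' `min_rho` are flagged as not water-responsive.
#'
#' @param storage_monthly tibble from [monthly_storage()] with one column per
#'   depth class.
#' @param greenness tibble with columns `month`, `month_num`, `ndvi`, aligned
#'   on the same months.
#' @param lags lead times scanned, months.
#' @param min_rho responsiveness screen on the best correlation.
#' @return list: `depth_class` (`NA` when not responsive), `score`,
#'   `responsive`, `profile` (tibble `depth_class`, `lag`, `rho`), and
#'   `rho_star` (the rho-by-lag vector of the selected class).
#' @export
select_accessible_depth <- function(storage_monthly, greenness,
                                    lags = 1:12, min_rho = 0.3) {
  if (!identical(storage_monthly$month, greenness$month)) {
    stop("storage and greenness must cover the same months", call. = FALSE)
  }
  classes <- intersect(depth_classes(), names(storage_monthly))
  dv <- monthly_anomalies(greenness$ndvi, greenness$month_num)$anomalies
  prof <- matrix(NA_real_, length(classes), length(lags),
                 dimnames = list(classes, NULL))
  for (z in classes) {
    sz <- monthly_anomalies(storage_monthly[[z]], storage_monthly$month_num)$anomalies
    for (j in seq_along(lags)) {
      prof[z, j] <- tryCatch(lagged_spearman(sz, dv, lags[j]),
                             error = function(e) NA_real_)
    }
  }
  score <- apply(prof, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  profile <- tibble::tibble(
    depth_class = rep(classes, each = length(lags)),
    lag = rep(lags, length(classes)),
    rho = as.vector(t(prof)))
  if (all(is.na(score)) || max(score, na.rm = TRUE) < min_rho) {
    return(list(depth_class = NA_character_, score = suppressWarnings(
      if (all(is.na(score))) NA_real_ else max(score, na.rm = TRUE)),
      responsive = FALSE, profile = profile, rho_star = rep(NA_real_, length(lags))))
  }
  best <- classes[which.max(score)]   # which.max takes the first (shallower) tie
  list(depth_class = best, score = unname(score[best]), responsive = TRUE,
       profile = profile, rho_star = unname(prof[best, ]))
}

#' Accessible storage capacity
#'
#' The 98th percentile of the accessible-storage series, by linear
#' interpolation between order statistics, taken as the maximum storage of
#' the layer vegetation responds to most strongly.
#'
#' @param x accessible-storage series, mm (>= 50 values).
#' @param prob percentile, default 0.98.
#' @return capacity in mm.
#' @export
storage_capacity <- function(x, prob = 0.98) {
  x <- x[!is.na(x)]
  if (length(x) < 50) stop("need at least 50 values", call. = FALSE)
  unname(quantile(x, prob, type = 7))
}

#' Skilful forecast lead time
#'
#' Number of consecutive lead months, counted from a one-month lead, over
#' which the lagged rank correlation exceeds the threshold. Zero means skilful
#' prediction only of the current month.
#'
#' @param rho correlation profile at leads 1..12 (NAs count as
#'   non-exceedance).
#' @param threshold rho threshold, default 0.6.
#' @return integer lead time in months, 0..12.
#' @export
skilful_lead_time <- function(rho, threshold = 0.6) {
  exceed <- !is.na(rho) & rho > threshold
  lead <- match(FALSE, exceed, nomatch = length(exceed) + 1L) - 1L
  as.integer(lead)
}
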