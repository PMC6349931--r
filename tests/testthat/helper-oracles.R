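# Independent brute-force oracles used to check the package's statistical
# machinery. These deliberately avoid the code paths they verify.

# Spearman rho via average ranks and the explicit product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# percentile by explicit sort and linear interpolation between order statistics
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# antecedent precipitation index by direct geometric convolution
oracle_api <- function(p, k) {
  vapply(seq_along(p), function(t) sum(k^(seq(t - 1, 0)) * p[seq_len(t)]),
         numeric(1))
}

# least squares through the normal equations
oracle_ls <- function(x, y) {
  X <- cbind(x, 1)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# per-calendar-month bucket mean
oracle_month_mean <- function(values, months, m, use = rep(TRUE, length(values))) {
  v <- values[use & months == m]
  sum(v) / length(v)
}

# first index at which a profile stops exceeding a threshold
oracle_lead <- function(rho, thr) {
  n <- 0L
  for (r in rho) {
    if (is.na(r) || r <= thr) break
    n <- n + 1L
  }
  n
}

# Exact Gaussian batch smoother for a linear AR(1) trajectory observed
# linearly: x_1 ~ N(m1, v1), x_{t+1} = phi x_t + w, w ~ N(0, q);
# y = H x + e, e ~ N(0, R). Returns the exact posterior mean of the whole
# trajectory, the oracle for the ensemble smoother.
oracle_batch_smoother <- function(n_days, m1, v1, phi, q, H, y, r_diag) {
  mean_prior <- m1 * phi^(0:(n_days - 1))
  P <- matrix(0, n_days, n_days)
  v <- v1
  P[1, 1] <- v1
  for (t in 2:n_days) {
    v <- phi^2 * v + q
    P[t, t] <- v
  }
  for (i in 1:(n_days - 1)) {
    for (j in (i + 1):n_days) {
      P[i, j] <- P[j, i] <- phi^(j - i) * P[i, i]
    }
  }
  R <- diag(r_diag, length(y))
  S <- H %*% P %*% t(H) + R
  as.numeric(mean_prior + P %*% t(H) %*% solve(S, y - H %*% mean_prior))
}

# Independent statement of the column's daily balance residual at steady
# state under constant precipitation p and pet. Mirrors the documented flux
# forms; used with a numeric root-find to predict the model's equilibrium.
oracle_steady_residual <- function(st, p, pet, params) {
  sw <- st[1]; top <- st[2]; sh <- st[3]; dp <- st[4]; gw <- st[5]
  caps <- c(params$cap_top, params$cap_shallow, params$cap_deep)
  runoff <- params$runoff_coef * max(p - params$runoff_threshold, 0)
  infil <- p - runoff
  sw <- sw + runoff
  for (j in 1:3) {
    s <- c(top, sh, dp)[j]
    take <- min(infil, caps[j] - s)
    if (j == 1) top <- top + take else if (j == 2) sh <- sh + take else dp <- dp + take
    infil <- infil - take
  }
  gw <- gw + infil
  acc <- (1 - params$frac_deep_veg) * params$access_shallow_veg +
    params$frac_deep_veg * params$access_deep_veg
  hs <- params$half_sat
  stores <- c(top, sh, dp, gw)
  et <- pmin(pet * acc * stores / (stores + hs), stores)
  et[stores <= 0] <- 0
  top <- top - et[1]; sh <- sh - et[2]; dp <- dp - et[3]; gw <- gw - et[4]
  dr <- params$drain_top * top; top <- top - dr
  add <- min(dr, caps[2] - sh); sh <- sh + add; dr <- dr - add
  add <- min(dr, caps[3] - dp); dp <- dp + add; gw <- gw + dr - add
  dr <- params$drain_shallow * sh; sh <- sh - dr
  add <- min(dr, caps[3] - dp); dp <- dp + add; gw <- gw + dr - add
  dr <- params$drain_deep * dp; dp <- dp - dr; gw <- gw + dr
  cr <- min(params$cap_rise * gw, caps[3] - dp); gw <- gw - cr; dp <- dp + cr
  gw <- gw - params$gw_discharge * gw
  sw <- sw - params$sw_decay * sw
  c(sw, top, sh, dp, gw) - st
}

# small fast configuration used across tests
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_pixels = 2, n_years = 3, seed = seed, ...)
}

empty_observation_set <- function(scale = 10) {
  ns <- tibble::tibble(date = as.Date(character()), value = numeric(),
                       sd = numeric())
  ct <- tibble::tibble(month = as.Date(character()), value = numeric(),
                       sd = numeric())
  observation_set(ns, ct, ns, sw_frac_scale = scale)
}

constant_forcing <- function(dates, precip = 2, temp = 20, rad = 12,
                             wind = 2, pressure = 95) {
  tibble::tibble(date = dates, precipitation = precip, air_temperature = temp,
                 net_radiation = rad, wind_speed = wind,
                 surface_pressure = pressure, snowfall_rate = 0)
}
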