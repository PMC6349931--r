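test_that("the anomaly forecast model recovers exact linear structure", {
  set.seed(1)
  n <- 60
  s <- rnorm(n, 0, 30)
  dv <- numeric(n); dv[1] <- 0.02
  for (t in 2:n) dv[t] <- dv[t - 1] + 0.002 * s[t - 1] + 0.01
  fm <- fit_forecast_model(dv, s, lead = 1)
  expect_equal(fm$beta1, 0.002, tolerance = 1e-9)
  expect_equal(fm$beta2, 0.01, tolerance = 1e-9)
  # constant storage degenerates to persistence plus intercept, with a warning
  expect_warning(fm0 <- fit_forecast_model(dv, rep(0, n), lead = 1),
                 "persistence")
  expect_equal(fm0$beta1, 0)
  expect_equal(fm0$beta2, mean(diff(dv)))
  # noisy fits match the normal-equations solve
  for (i in 1:20) {
    y <- rnorm(n); x <- rnorm(n, 0, 10)
    fm2 <- fit_forecast_model(y, x, lead = 2)
    ora <- oracle_ls(x[1:(n - 2)], y[3:n] - y[1:(n - 2)])
    expect_equal(c(fm2$beta1, fm2$beta2), ora, tolerance = 1e-9)
  }
})

test_that("absolute forecasts add the climatology and clip to [0, 1]", {
  clim <- seq(0.2, 0.42, length.out = 12)
  fm <- structure(list(lead = 1, beta1 = 0, beta2 = 0, n_train = 24),
                  class = "forecast_model")
  # zero coefficients: persistence anomaly plus climatology
  expect_equal(forecast_greenness(fm, 0.05, 10, clim, 4), 0.05 + clim[4])
  expect_equal(forecast_greenness(fm, 0, 0, clim, 7), clim[7])
  # round trip: forecast minus climatology is the anomaly equation
  fm2 <- structure(list(lead = 1, beta1 = 0.001, beta2 = -0.02, n_train = 24),
                   class = "forecast_model")
  f <- forecast_greenness(fm2, 0.03, 25, clim, 9)
  expect_equal(f - clim[9], 0.03 + 0.001 * 25 - 0.02, tolerance = 1e-12)
  expect_equal(forecast_greenness(fm2, 5, 1e5, clim, 1), 1)   # clipped
})

test_that("persistence is the identity on anomalies", {
  expect_equal(persistence_forecast(0.05), 0.05)
  expect_equal(persistence_forecast(0), 0)
  x <- rnorm(10)
  expect_equal(persistence_forecast(x), x)
})

test_that("climatology forecasts are month-bucket means of the history", {
  v <- c(0.3); m <- c(5)
  expect_equal(climatology_forecast(v, m, 5), 0.3)
  months <- rep(1:12, 4)
  per <- cos(2 * pi * months / 12) / 4 + 0.5
  for (mm in 1:12) {
    expect_equal(climatology_forecast(per, months, mm), per[mm])
  }
  set.seed(30)
  v <- rnorm(48); m <- rep(1:12, 4)
  ex <- 37:48
  for (mm in c(2, 8, 11)) {
    use <- rep(TRUE, 48); use[ex] <- FALSE
    expect_equal(climatology_forecast(v, m, mm, exclude = ex),
                 oracle_month_mean(v, m, mm, use))
  }
  expect_error(climatology_forecast(v[1:3], m[1:3], 9), "no observation")
})

test_that("the antecedent precipitation index is the geometric convolution", {
  expect_equal(api_index(c(10, 0, 0), 0.9), c(10, 9, 8.1))
  expect_equal(api_index(rep(0, 5), 0.9), rep(0, 5))
  set.seed(14)
  for (i in 1:20) {
    p <- rgamma(40, 0.6, scale = 9) * rbinom(40, 1, 0.4)
    k <- runif(1, 0.5, 0.99)
    expect_equal(api_index(p, k), oracle_api(p, k), tolerance = 1e-9)
  }
  expect_error(api_index(c(1, -1), 0.9), ">= 0")
  expect_error(api_index(1:3, 1.0), "\\(0, 1\\)")
})

# small synthetic greenness record with a persistent anomaly signal
toy_greenness <- function(n_months = 72, seed = 10) {
  withr::with_seed(seed, {
    month <- seq(as.Date("2010-01-01"), by = "month", length.out = n_months)
    mn <- as.integer(format(month, "%m"))
    s <- as.numeric(arima.sim(list(ar = 0.8), n_months, sd = 10))
    ndvi <- 0.3 + 0.1 * sin(2 * pi * mn / 12) + 0.004 * s +
      rnorm(n_months, 0, 0.01)
    list(greenness = tibble::tibble(month = month, month_num = mn,
                                    ndvi = pmin(pmax(ndvi, 0), 1)),
         storage = s)
  })
}

test_that("hindcast evaluation scores perfect and useless forecasts correctly", {
  tg <- toy_greenness()
  out <- hindcast_evaluate(tg$greenness, list(storage = tg$storage), leads = c(1, 3))
  expect_true(all(c("persistence", "climatology", "storage") %in% out$skill$method))
  # the storage predictor drives the anomalies: high skill at lead 1
  rho_s <- out$skill$rho[out$skill$method == "storage" & out$skill$lead == 1]
  expect_gt(rho_s, 0.85)
  # a shuffled predictor earns no anomaly skill beyond the seasonal cycle:
  # its skill collapses to about the climatology baseline
  shuf <- withr::with_seed(2, sample(tg$storage))
  out2 <- hindcast_evaluate(tg$greenness, list(noise = shuf), leads = 3)
  rho_noise <- out2$skill$rho[out2$skill$method == "noise"]
  rho_clim <- out2$skill$rho[out2$skill$method == "climatology"]
  expect_lt(rho_noise, rho_s)
  expect_lt(abs(rho_noise - rho_clim), 0.25)
  # forecasts identical to observations give rho 1
  fc <- out$forecasts
  fc$forecast <- fc$observed
  rho <- suppressWarnings(cor(fc$forecast, fc$observed, method = "spearman"))
  expect_equal(rho, 1)
})

test_that("anomaly forecasts on pure anomalies carry no seasonal crutch", {
  # remove the seasonal cycle entirely; a shuffled predictor then has |rho| < 0.3
  withr::with_seed(4, {
    month <- seq(as.Date("2010-01-01"), by = "month", length.out = 72)
    gg <- tibble::tibble(month = month,
                         month_num = as.integer(format(month, "%m")),
                         ndvi = pmin(pmax(0.4 + rnorm(72, 0, 0.05), 0), 1))
    shuf <- rnorm(72)
  })
  out <- hindcast_evaluate(gg, list(noise = shuf), leads = 3)
  expect_lt(abs(out$skill$rho[out$skill$method == "noise"]), 0.3)
})

test_that("held-out observations never influence the fitted hindcast models", {
  tg <- toy_greenness()
  fc1 <- hindcast_forecasts(tg$greenness, list(storage = tg$storage), leads = 2)
  # mutate segment 3's observations; forecasts of segments 1-2 whose model
  # excluded segment 3 must be unchanged
  g2 <- tg$greenness
  seg3 <- 49:72
  g2$ndvi[seg3] <- rev(g2$ndvi[seg3])
  fc2 <- hindcast_forecasts(g2, list(storage = tg$storage), leads = 2)
  # forecasts FOR segment 3 depend on its observations only through the
  # initial-condition anomaly, so those launched from t0 outside segment 3
  # must be bit-identical after the mutation
  f3_1 <- fc1[fc1$segment == 3 & fc1$t0 < 49, ]
  f3_2 <- fc2[fc2$segment == 3 & fc2$t0 < 49, ]
  expect_equal(f3_1$forecast, f3_2$forecast, tolerance = 1e-12)
})

test_that("series not divisible by three put trailing months in the last segment", {
  segs <- aridcast:::hindcast_segments(74, 3)
  expect_equal(lengths(segs), c(24, 24, 26))
  expect_equal(segs[[3]][26], 74)
  expect_error(aridcast:::hindcast_segments(30, 3), "too short")
})

test_that("the reported NDVI baseline is the better of persistence and climatology", {
  tg <- toy_greenness()
  out <- hindcast_evaluate(tg$greenness, leads = 1:3)
  bb <- baseline_best(out$skill)
  for (l in 1:3) {
    r <- out$skill$rho[out$skill$lead == l]
    m <- out$skill$method[out$skill$lead == l]
    expect_equal(bb$rho_ndvi[bb$lead == l],
                 max(r[m %in% c("persistence", "climatology")]))
  }
})
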