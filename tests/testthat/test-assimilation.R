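# builds a one-month toy window whose only active store is the top layer
toy_window <- function(n_members, n_days = 31, phi = 0.9, m1 = 20, v1 = 16,
                       q = 4, seed = 1) {
  dates <- seq(as.Date("2010-01-01"), by = "day", length.out = n_days)
  states <- array(0, dim = c(n_days, n_members, 4))
  withr::with_seed(seed, {
    x <- matrix(NA_real_, n_days, n_members)
    x[1, ] <- rnorm(n_members, m1, sqrt(v1))
    for (t in 2:n_days) x[t, ] <- phi * x[t - 1, ] + rnorm(n_members, 0, sqrt(q))
  })
  states[, , 1] <- pmax(x, 0)
  ensemble_window(dates, states, matrix(0, n_days, n_members))
}

toy_obs <- function(dates, ns_days, ns_values, ns_sd, ct_value = NULL, ct_sd = 5) {
  ns <- tibble::tibble(date = dates[ns_days], value = ns_values,
                       sd = rep_len(ns_sd, length(ns_days)))
  ct <- if (is.null(ct_value)) {
    tibble::tibble(month = as.Date(character()), value = numeric(), sd = numeric())
  } else {
    tibble::tibble(month = as.Date(format(dates[1], "%Y-%m-01")),
                   value = ct_value, sd = ct_sd)
  }
  observation_set(ns, ct, tibble::tibble(date = as.Date(character()),
                                         value = numeric(), sd = numeric()))
}

test_that("forcing perturbations have unit mean and reproduce under a seed", {
  f <- constant_forcing(seq(as.Date("2010-01-01"), by = "day", length.out = 10),
                        precip = 5)
  # zero sds: members identical to the input
  mem0 <- perturb_forcings(f, 3, sd_precip = 0, sd_temp = 0, sd_rad = 0)
  expect_identical(mem0[[1]], f)
  expect_identical(mem0[[3]], f)
  # same seed, same member set
  m1 <- perturb_forcings(f, 5, seed = 7)
  m2 <- perturb_forcings(f, 5, seed = 7)
  expect_identical(m1, m2)
  # law of large numbers: ensemble-mean precipitation within 2% of unperturbed
  mem <- perturb_forcings(f, 1e4, sd_precip = 0.3, seed = 2)
  pbar <- mean(vapply(mem, function(m) m$precipitation[1], numeric(1)))
  expect_lt(abs(pbar - 5) / 5, 0.02)
})

test_that("the observation operator selects days and averages the month", {
  w <- toy_window(4, n_days = 31)
  # constant member: column prediction equals the constant total
  w$states[, , 1] <- 120
  obs <- toy_obs(w$dates, c(3, 10), c(1, 1), 1, ct_value = 100)
  pred <- observation_operator(w, obs)
  expect_equal(dim(pred), c(3, 4))
  expect_equal(pred[3, ], rep(120, 4))
  # near-surface prediction is exactly that day's top storage
  w$states[10, , 1] <- 55
  pred <- observation_operator(w, obs)
  expect_equal(pred[2, ], rep(55, 4))
  # ramp: column prediction is the arithmetic mean, against brute-force
  ramp <- seq(0, 30, length.out = 31)
  w$states[, , 1] <- matrix(ramp, 31, 4)
  pred <- observation_operator(w, obs)
  expect_equal(pred[3, 1], sum(ramp) / 31, tolerance = 1e-12)
  # observation inside the span but on no window day -> error
  all_days <- seq(as.Date("2010-01-01"), by = "day", length.out = 31)
  bad <- toy_obs(all_days[16], 1, 1, 1)
  # a window with a mid-span gap on that very day
  wgap <- ensemble_window(all_days[-16],
                        toy_window(4, n_days = 30)$states,
                        matrix(0, 30, 4))
  expect_error(observation_operator(wgap, bad), "outside the window")
})

test_that("the smoother update recovers textbook Kalman limits", {
  wide <- column_params(cap_top = 1e6)   # keep the linear toy unclipped
  # infinite observation variance: posterior equals prior
  w <- toy_window(50, seed = 3)
  obs <- toy_obs(w$dates, 15, 10, ns_sd = 1e6)
  upd <- enks_update(w, obs, params = wide, seed = 1)
  expect_lt(max(abs(upd$window$states - w$states)), 1e-3)
  expect_lt(max(abs(upd$increment)), 1e-3)

  # scalar toy: prior N(0,1), obs 1 with unit variance -> posterior mean 1/2.
  # large N; rho = 0 dynamics so only day 1 matters
  n <- 5000
  dates <- seq(as.Date("2010-01-01"), by = "day", length.out = 2)
  states <- array(0, dim = c(2, n, 4))
  states[1, , 1] <- withr::with_seed(8, rnorm(n, 0, 1)) + 50  # shift to stay positive
  states[2, , 1] <- 50
  w2 <- ensemble_window(dates, states, matrix(0, 2, n))
  obs2 <- toy_obs(dates, 1, 51, ns_sd = 1)
  upd2 <- enks_update(w2, obs2, params = wide, seed = 2)
  post_mean <- mean(upd2$window$states[1, , 1])
  expect_equal(post_mean, 50.5, tolerance = 0.05)
})

test_that("a numerically singular innovation covariance is reported", {
  w <- toy_window(3, n_days = 5)
  obs <- toy_obs(w$dates, c(2, 3), c(1, 1), ns_sd = 1)
  obs$near_surface$sd <- c(1e-12, 1e8)   # hopeless conditioning
  expect_error(enks_update(w, obs, seed = 1), "singular|ensemble size")
})

test_that("nudging is a convex combination in storage space", {
  st <- column_state(10, 5, 50, 100, 30)
  expect_equal(nudge_surface_water(st, 0.3, gain = 0), st)
  target <- storage_from_fraction(0.3, 10)
  full <- nudge_surface_water(st, 0.3, gain = 1)
  expect_equal(unname(full["surface_water"]), target)
  mixed <- nudge_surface_water(st, fraction_from_storage(20, 10), gain = 0.9)
  expect_equal(unname(mixed["surface_water"]), 0.1 * 10 + 0.9 * 20,
               tolerance = 1e-9)
  expect_equal(unname(mixed["s_shallow"]), 50)   # other stores untouched
  expect_error(nudge_surface_water(st, 1.2, 0.9), "\\[0, 1\\]")
})

test_that("the fraction transform inverts cleanly", {
  sw <- c(0, 1, 5, 20, 80)
  f <- fraction_from_storage(sw, 10)
  expect_true(all(f >= 0 & f < 1))
  expect_equal(storage_from_fraction(f, 10), sw, tolerance = 1e-9)
})

test_that("assimilation with no observations is the open-loop ensemble mean", {
  cfg <- tiny_config(seed = 31)
  f <- generate_forcings(cfg, 1)
  out <- assimilate_series(f, empty_observation_set(), n_members = 10,
                           seed = 4, quiet = TRUE)
  expect_equal(nrow(out$increments), 0)
  expect_equal(out$clip_mass, 0)
  # reproducible under the seed
  out2 <- assimilate_series(f, empty_observation_set(), n_members = 10,
                            seed = 4, quiet = TRUE)
  expect_identical(out$analysis, out2$analysis)
  # vanishing perturbations: equal to a deterministic model run
  out0 <- assimilate_series(f, empty_observation_set(), n_members = 5, seed = 4,
                            sd_precip = 0, sd_temp = 0, sd_rad = 0, quiet = TRUE)
  det <- run_simulation(column_state(0, 10, 100, 320, 150), f, pet_series(f))
  expect_equal(as.matrix(out0$analysis[, -1]), as.matrix(det$states[, -1]),
               tolerance = 1e-9)
  expect_true(all(out0$spread$s_deep < 1e-9))
})

test_that("huge observation variance drives the analysis to the open loop", {
  cfg <- tiny_config(seed = 17)
  tr <- generate_truth(cfg, 1)
  obs <- simulate_observations(tr$states, cfg, 1)
  obs$near_surface$sd[] <- 1e6
  obs$column_total$sd[] <- 1e6
  obs$surface_fraction <- obs$surface_fraction[0, ]
  f <- tr$forcings[1:90, ]   # first quarter is enough
  obs$near_surface <- obs$near_surface[obs$near_surface$date <= max(f$date), ]
  obs$column_total <- obs$column_total[obs$column_total$month <= max(f$date), ]
  da <- assimilate_series(f, obs, n_members = 30, seed = 9, quiet = TRUE)
  ol <- assimilate_series(f, empty_observation_set(), n_members = 30, seed = 9,
                          quiet = TRUE)
  expect_equal(as.matrix(da$analysis[, -1]), as.matrix(ol$analysis[, -1]),
               tolerance = 1e-3)
})

test_that("posterior stores respect bounds and the ledger closes the balance", {
  cfg <- tiny_config(seed = 23)
  tr <- generate_truth(cfg, 2)
  obs <- simulate_observations(tr$states, cfg, 2)
  f <- degrade_forcings(tr$forcings, seed = 77)[1:181, ]
  obs$near_surface <- obs$near_surface[obs$near_surface$date <= max(f$date), ]
  obs$column_total <- obs$column_total[obs$column_total$month <= max(f$date), ]
  obs$surface_fraction <- obs$surface_fraction[obs$surface_fraction$date <= max(f$date), ]
  da <- assimilate_series(f, obs, n_members = 40, seed = 3, quiet = TRUE)
  params <- column_params()
  expect_true(all(da$analysis$s_top >= 0 & da$analysis$s_top <= params$cap_top))
  expect_true(all(da$analysis$s_shallow <= params$cap_shallow))
  expect_true(all(da$analysis$s_deep <= params$cap_deep))
  expect_true(all(da$analysis$groundwater >= 0))
  # physics + ledgered increments close to numerical precision
  expect_lt(check_mass_balance(da$analysis, da$fluxes, da$increments), 1e-6)
  # without the increments the balance is (intentionally) open
  expect_gt(check_mass_balance(da$analysis, da$fluxes), 0.01)
})
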