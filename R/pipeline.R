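# End-to-end pipeline: simulate -> assimilate -> infer -> forecast -> evaluate
#
# Every stage reads its inputs from, and writes its outputs to, a run
# directory of long-format CSV files, each accompanied by a manifest that
# records the configuration hash and seed, so a run is fully reproducible
# and stages can be re-run individually.

SCHEMAS <- list(
  forcings = list(date = "date", chr = character(),
                  cols = c("date", "pixel_id", "precipitation", "air_temperature",
                           "net_radiation", "wind_speed", "surface_pressure",
                           "snowfall_rate")),
  trajectory = list(date = "date", chr = "variable",
                    cols = c("date", "pixel_id", "variable", "value_mm")),
  greenness = list(date = "month", chr = character(),
                   cols = c("month", "pixel_id", "ndvi")),
  observations = list(date = "date", chr = "kind",
                      cols = c("date", "pixel_id", "kind", "value", "error_sd")),
  increments = list(date = "date", chr = c("store", "source"),
                    cols = c("date", "pixel_id", "store", "increment_mm", "source")),
  results = list(date = NULL, chr = "depth_class",
                 cols = c("pixel_id", "depth_class", "capacity_mm",
                          "lead_time_months", paste0("rho_lag", 1:12))),
  forecasts = list(date = "month", chr = "method",
                   cols = c("pixel_id", "segment", "lead", "method", "month",
                            "forecast", "observed")),
  skill = list(date = NULL, chr = "method",
               cols = c("pixel_id", "method", "lead", "rho")),
  summary = list(date = NULL, chr = "method",
                 cols = c("method", "lead", "frac_skilful")))

#' Write / read a pipeline CSV with schema validation
#'
#' Tables are written in full precision (shortest round-tripping decimal
#' representation) with ISO-8601 dates. Reading validates the column set and
#' rejects malformed dates with the offending row index.
#'
#' @param x tibble to write.
#' @param path CSV path.
#' @param schema one of `r paste(names(aridcast:::SCHEMAS), collapse = ", ")`.
#' @return `write_series` returns `path` invisibly; `read_series` returns a
#'   tibble.
#' @export
write_series <- function(x, path, schema) {
  sc <- SCHEMAS[[schema]] %||% stop("unknown schema: ", schema, call. = FALSE)
  missing <- setdiff(sc$cols, names(x))
  if (length(missing) > 0) {
    stop(sprintf("schema '%s': missing column(s) %s", schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- x[, sc$cols]
  # 17 significant digits: doubles survive the text round trip bit for bit
  for (j in names(x)) {
    if (is.double(x[[j]]) && !inherits(x[[j]], "Date")) {
      x[[j]] <- ifelse(is.na(x[[j]]), NA_character_, sprintf("%.17g", x[[j]]))
    }
  }
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, schema) {
  sc <- SCHEMAS[[schema]] %||% stop("unknown schema: ", schema, call. = FALSE)
  # read everything as text, then convert with base R's correctly rounded
  # decimal parser so the round trip is bit-exact
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(sc$cols, names(x))
  if (length(missing) > 0) {
    stop(sprintf("schema '%s': missing column(s) %s in %s", schema,
                 paste(missing, collapse = ", "), path), call. = FALSE)
  }
  for (j in sc$cols) {
    if (identical(j, sc$date)) {
      parsed <- as.Date(x[[j]], format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & !is.na(x[[j]]))
      if (length(bad) > 0) {
        stop(sprintf("schema '%s': malformed date in row %d of %s", schema,
                     bad[1], path), call. = FALSE)
      }
      x[[j]] <- parsed
    } else if (!j %in% sc$chr) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[j]]))) &
                     !is.na(x[[j]]) & x[[j]] != "NA")
      if (length(bad) > 0) {
        stop(sprintf("schema '%s': non-numeric value in column %s, row %d of %s",
                     schema, j, bad[1], path), call. = FALSE)
      }
      x[[j]] <- as.numeric(x[[j]])
    }
  }
  x
}

#' Pipeline run configuration
#'
#' Bundles the synthetic-data configuration, the water-balance parameters and
#' the assimilation, inference and forecasting options, under a single root
#' seed. Defaults follow the method definition: 100 ensemble members, a
#' skill threshold of rho > 0.6, the 98th-percentile capacity, an API decay
#' of 0.9 and three hindcast segments.
#'
#' @param seed root seed; all stage seeds derive from it.
#' @param synthetic a [synthetic_config()].
#' @param params a [column_params()].
#' @param n_members ensemble size.
#' @param sd_precip,sd_temp,sd_rad forcing perturbation sds.
#' @param nudge_gain surface-water nudging gain.
#' @param inflation smoother anomaly inflation.
#' @param model_precip_bias,model_precip_sd,model_temp_sd forcing degradation
#'   applied to the forcings that drive the (imperfect) assimilation model.
#' @param rho_threshold skilful-forecast correlation threshold.
#' @param capacity_prob capacity percentile.
#' @param min_rho responsiveness screen of [select_accessible_depth()].
#' @param leads forecast leads evaluated.
#' @param n_segments hindcast segments.
#' @param api_k API decay coefficient per day.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       synthetic = synthetic_config(seed = seed),
                       params = column_params(),
                       n_members = 100,
                       sd_precip = 0.3, sd_temp = 1, sd_rad = 0.1,
                       nudge_gain = 0.9, inflation = 1,
                       model_precip_bias = 0.8, model_precip_sd = 0.4,
                       model_temp_sd = 1,
                       rho_threshold = 0.6, capacity_prob = 0.98,
                       min_rho = 0.3, leads = 1:12, n_segments = 3,
                       api_k = 0.9) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

.manifest <- function(config, stage, files, outdir) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("aridcast")),
              seed = config$seed,
              config_hash = rlang::hash(unclass(config)),
              files = files)
  jsonlite::write_json(man, file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.pixels <- function(config) seq_len(config$synthetic$n_pixels)

# long <-> wide helpers for state trajectories
.states_long <- function(states, pixel) {
  tidyr::pivot_longer(dplyr::mutate(states, pixel_id = pixel),
                      dplyr::all_of(STORE_NAMES),
                      names_to = "variable", values_to = "value_mm")
}

.states_wide <- function(long, pixel) {
  x <- tidyr::pivot_wider(long[long$pixel_id == pixel, ],
                          id_cols = "date", names_from = "variable",
                          values_from = "value_mm")
  dplyr::arrange(x, date)
}

.stage_simulate <- function(config, outdir) {
  rows_f <- list(); rows_t <- list(); rows_g <- list(); rows_o <- list()
  for (px in .pixels(config)) {
    truth <- generate_truth(config$synthetic, px, config$params)
    obs <- simulate_observations(truth$states, config$synthetic, px)
    rows_f[[px]] <- dplyr::mutate(truth$forcings, pixel_id = px)
    rows_t[[px]] <- .states_long(truth$states, px)
    rows_g[[px]] <- tibble::tibble(month = truth$greenness$month, pixel_id = px,
                                   ndvi = truth$greenness$ndvi)
    rows_o[[px]] <- dplyr::bind_rows(
      tibble::tibble(date = obs$near_surface$date, pixel_id = px,
                     kind = "near_surface", value = obs$near_surface$value,
                     error_sd = obs$near_surface$sd),
      tibble::tibble(date = obs$column_total$month, pixel_id = px,
                     kind = "column_total", value = obs$column_total$value,
                     error_sd = obs$column_total$sd),
      tibble::tibble(date = obs$surface_fraction$date, pixel_id = px,
                     kind = "surface_fraction", value = obs$surface_fraction$value,
                     error_sd = obs$surface_fraction$sd))
  }
  files <- c(forcings = "forcings.csv", truth = "truth_trajectory.csv",
             greenness = "greenness.csv", observations = "observations.csv")
  write_series(dplyr::bind_rows(rows_f), file.path(outdir, files["forcings"]), "forcings")
  write_series(dplyr::bind_rows(rows_t), file.path(outdir, files["truth"]), "trajectory")
  write_series(dplyr::bind_rows(rows_g), file.path(outdir, files["greenness"]), "greenness")
  write_series(dplyr::bind_rows(rows_o), file.path(outdir, files["observations"]), "observations")
  .manifest(config, "simulate", files, outdir)
}

# rebuild an observation_set for one pixel from the observations CSV
.obs_for_pixel <- function(obs_tab, pixel, sw_frac_scale) {
  o <- obs_tab[obs_tab$pixel_id == pixel, ]
  observation_set(
    near_surface = with(o[o$kind == "near_surface", ],
                        tibble::tibble(date = date, value = value, sd = error_sd)),
    column_total = with(o[o$kind == "column_total", ],
                        tibble::tibble(month = date, value = value, sd = error_sd)),
    surface_fraction = with(o[o$kind == "surface_fraction", ],
                            tibble::tibble(date = date, value = value, sd = error_sd)),
    sw_frac_scale = sw_frac_scale)
}

.stage_assimilate <- function(config, outdir) {
  need <- file.path(outdir, c("forcings.csv", "observations.csv"))
  if (!all(file.exists(need))) {
    stop("assimilate needs simulate outputs; run the 'simulate' stage first",
         call. = FALSE)
  }
  forc <- read_series(need[1], "forcings")
  obs_tab <- read_series(need[2], "observations")
  rows_a <- list(); rows_o <- list(); rows_i <- list()
  for (px in .pixels(config)) {
    f_true <- forc[forc$pixel_id == px, ]
    f_model <- degrade_forcings(f_true,
                                precip_bias = config$model_precip_bias,
                                precip_sd = config$model_precip_sd,
                                temp_sd = config$model_temp_sd,
                                seed = spawn_seed(config$seed, "degrade", px))
    obs <- .obs_for_pixel(obs_tab, px, config$synthetic$sw_frac_scale)
    empty <- observation_set(
      obs$near_surface[0, ], obs$column_total[0, ], obs$surface_fraction[0, ],
      sw_frac_scale = config$synthetic$sw_frac_scale)
    da <- assimilate_series(f_model, obs, params = config$params,
                            n_members = config$n_members,
                            seed = spawn_seed(config$seed, "da", px),
                            sd_precip = config$sd_precip,
                            sd_temp = config$sd_temp, sd_rad = config$sd_rad,
                            nudge_gain = config$nudge_gain,
                            inflation = config$inflation, quiet = TRUE)
    ol <- assimilate_series(f_model, empty, params = config$params,
                            n_members = config$n_members,
                            seed = spawn_seed(config$seed, "da", px),
                            sd_precip = config$sd_precip,
                            sd_temp = config$sd_temp, sd_rad = config$sd_rad,
                            nudge_gain = config$nudge_gain,
                            inflation = config$inflation, quiet = TRUE)
    rows_a[[px]] <- .states_long(da$analysis, px)
    rows_o[[px]] <- .states_long(ol$analysis, px)
    rows_i[[px]] <- dplyr::mutate(da$increments, pixel_id = px)
  }
  files <- c(analysis = "analysis_trajectory.csv",
             open_loop = "open_loop_trajectory.csv",
             increments = "increments.csv")
  write_series(dplyr::bind_rows(rows_a), file.path(outdir, files["analysis"]), "trajectory")
  write_series(dplyr::bind_rows(rows_o), file.path(outdir, files["open_loop"]), "trajectory")
  write_series(dplyr::bind_rows(rows_i), file.path(outdir, files["increments"]), "increments")
  .manifest(config, "assimilate", files, outdir)
}

.stage_infer <- function(config, outdir) {
  need <- file.path(outdir, c("analysis_trajectory.csv", "greenness.csv"))
  if (!all(file.exists(need))) {
    stop("infer needs assimilate outputs; run the 'assimilate' stage first",
         call. = FALSE)
  }
  traj <- read_series(need[1], "trajectory")
  green <- read_series(need[2], "greenness")
  rows <- list()
  for (px in .pixels(config)) {
    daily <- integrate_storage(.states_wide(traj, px))
    sm <- monthly_storage(daily)
    g <- green[green$pixel_id == px, ]
    gg <- tibble::tibble(month = g$month, month_num = month_of(g$month),
                         ndvi = g$ndvi)
    sel <- select_accessible_depth(sm, gg, min_rho = config$min_rho)
    # capacity from the daily accessible-storage record of the chosen class
    cap <- if (sel$responsive) {
      storage_capacity(daily[[sel$depth_class]], config$capacity_prob)
    } else NA_real_
    lead <- skilful_lead_time(sel$rho_star, config$rho_threshold)
    rows[[px]] <- tibble::as_tibble(c(
      list(pixel_id = px,
           depth_class = sel$depth_class %||% NA_character_,
           capacity_mm = cap, lead_time_months = lead),
      setNames(as.list(sel$rho_star), paste0("rho_lag", 1:12))))
  }
  write_series(dplyr::bind_rows(rows), file.path(outdir, "results.csv"), "results")
  .manifest(config, "infer", c(results = "results.csv"), outdir)
}

# monthly predictor series for one pixel, aligned with the greenness months
.pixel_predictors <- function(config, px, gg, traj_a, traj_o, forc, obs_tab) {
  pick_series <- function(traj) {
    sm <- monthly_storage(integrate_storage(.states_wide(traj, px)))
    sel <- select_accessible_depth(sm, gg, min_rho = 0)
    sm[[sel$depth_class %||% "top_shallow"]]
  }
  obs <- .obs_for_pixel(obs_tab, px, config$synthetic$sw_frac_scale)
  ns_monthly <- with(obs$near_surface,
                     tapply(value, format(date, "%Y-%m"), mean))
  ns <- as.numeric(ns_monthly[format(gg$month, "%Y-%m")])
  ct <- obs$column_total$value[match(gg$month, obs$column_total$month)]
  f_true <- forc[forc$pixel_id == px, ]
  api <- api_monthly(f_true, config$api_k)
  list(da_storage = pick_series(traj_a),
       open_loop = pick_series(traj_o),
       api = api$api[match(gg$month, api$month)],
       obs_surface = ns,
       obs_column = ct)
}

.stage_forecast <- function(config, outdir) {
  need <- file.path(outdir, c("analysis_trajectory.csv", "open_loop_trajectory.csv",
                              "greenness.csv", "forcings.csv", "observations.csv"))
  if (!all(file.exists(need))) {
    stop("forecast needs simulate and assimilate outputs; run those stages first",
         call. = FALSE)
  }
  green <- read_series(file.path(outdir, "greenness.csv"), "greenness")
  traj_a <- read_series(file.path(outdir, "analysis_trajectory.csv"), "trajectory")
  traj_o <- read_series(file.path(outdir, "open_loop_trajectory.csv"), "trajectory")
  forc <- read_series(file.path(outdir, "forcings.csv"), "forcings")
  obs_tab <- read_series(file.path(outdir, "observations.csv"), "observations")
  rows <- list()
  for (px in .pixels(config)) {
    g <- green[green$pixel_id == px, ]
    gg <- tibble::tibble(month = g$month, month_num = month_of(g$month),
                         ndvi = g$ndvi)
    preds <- .pixel_predictors(config, px, gg, traj_a, traj_o, forc, obs_tab)
    fc <- hindcast_forecasts(gg, preds, leads = config$leads,
                             n_segments = config$n_segments)
    rows[[px]] <- dplyr::mutate(fc, pixel_id = px)
  }
  write_series(dplyr::bind_rows(rows), file.path(outdir, "forecasts.csv"), "forecasts")
  .manifest(config, "forecast", c(forecasts = "forecasts.csv"), outdir)
}

.stage_evaluate <- function(config, outdir) {
  need <- file.path(outdir, "forecasts.csv")
  if (!file.exists(need)) {
    stop("evaluate needs forecast outputs; run the 'forecast' stage first",
         call. = FALSE)
  }
  fc <- read_series(need, "forecasts")
  skill <- fc |>
    dplyr::group_by(pixel_id, method, lead) |>
    dplyr::summarise(
      rho = suppressWarnings(cor(forecast, observed, method = "spearman")),
      .groups = "drop")
  summary <- skill |>
    dplyr::group_by(method, lead) |>
    dplyr::summarise(frac_skilful = mean(rho > config$rho_threshold, na.rm = TRUE),
                     .groups = "drop")
  write_series(skill, file.path(outdir, "skill.csv"), "skill")
  write_series(summary, file.path(outdir, "skill_summary.csv"), "summary")
  .manifest(config, "evaluate", c(skill = "skill.csv",
                                  summary = "skill_summary.csv"), outdir)
}

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages, in order: `simulate` (truth twin and observations), `assimilate`
#' (ensemble smoother analysis and open-loop run driven by degraded
#' forcings), `infer` (accessible depth, capacity, lead time), `forecast`
#' (hindcast forecasts for all methods), `evaluate` (skill tables). A stage
#' whose inputs are missing stops with the name of the stage to run first.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir run directory (created if needed).
#' @param stages character vector of stages, or `"all"`.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config, outdir, stages = "all") {
  all_stages <- c("simulate", "assimilate", "infer", "forecast", "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (st in all_stages[all_stages %in% stages]) {
    switch(st,
           simulate = .stage_simulate(config, outdir),
           assimilate = .stage_assimilate(config, outdir),
           infer = .stage_infer(config, outdir),
           forecast = .stage_forecast(config, outdir),
           evaluate = .stage_evaluate(config, outdir))
  }
  invisible(outdir)
}
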