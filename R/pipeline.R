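#' Run configuration for the full pipeline
#'
#' Aggregates every analysis choice of an end-to-end run: data source
#' (synthetic scenarios or per-city CSV paths), covariate specification,
#' exposure lag and lag panel, IV stage toggle and hyperparameter
#' overrides, exposure-response spline layouts, reference concentrations,
#' restriction thresholds, Monte-Carlo draws and the master seed. One
#' master seed deterministically spawns per-stage substreams, so adding a
#' city never perturbs another city's draws (scenario seeds are fixed per
#' city at construction).
#'
#' @param scenarios list of [city_scenario()] (synthetic run), or `NULL`
#'   when `input_files` is given.
#' @param input_files named character vector of per-city CSV paths
#'   (see [read_city_csv()]).
#' @param cov a [cov_spec()].
#' @param exposure_lag main exposure [lag_spec()].
#' @param lag_panel list of additional [lag_spec()]s for the lag panel
#'   (`NULL` to skip).
#' @param iv run the instrumental-variable stage.
#' @param iv_args list of overrides for [calibrate_instrument()].
#' @param erc_spec [spline_spec()] for the exposure-response curves.
#' @param reference reference concentration for attribution: a number, or
#'   `"minimum"` for the observed minimum lagged exposure across cities.
#' @param thresholds restriction cutoffs (ug/m3), `NULL` to skip.
#' @param n_sim Monte-Carlo draws for attribution CIs.
#' @param seed master seed.
#' @return A `run_config`.
#' @export
run_config <- function(scenarios = NULL, input_files = NULL,
                       cov = cov_spec(),
                       exposure_lag = lag_spec("moving_average", 0:1),
                       lag_panel = NULL,
                       iv = TRUE, iv_args = list(),
                       erc_spec = spline_spec(),
                       reference = "minimum",
                       thresholds = c(250, 125, 100, 75, 60),
                       n_sim = 1000L, seed = 1L) {
  if (is.null(scenarios) && is.null(input_files))
    stop("either scenarios or input_files must be given")
  if (!is.null(input_files) && !all(file.exists(input_files)))
    stop("missing input files: ",
         paste(input_files[!file.exists(input_files)], collapse = ", "))
  structure(list(scenarios = scenarios, input_files = input_files,
                 cov = cov, exposure_lag = exposure_lag,
                 lag_panel = lag_panel, iv = iv, iv_args = iv_args,
                 erc_spec = erc_spec, reference = reference,
                 thresholds = thresholds, n_sim = as.integer(n_sim),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Supported keys mirror [run_config()]; lag specs are written as
#' `{kind, lags}` maps, the covariate spec as a `covariates` map, spline
#' knots as `erc_knot_percentiles`, and synthetic scenarios as a list of
#' [city_scenario()] argument maps under `scenarios`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_lag <- function(z, default) {
    if (is.null(z)) default else lag_spec(z$kind, z$lags)
  }
  cv <- y$covariates
  cov <- cov_spec(
    time_df_per_year = cv$time_df_per_year %||% 9,
    temp_lag = as_lag(cv$temp_lag, lag_spec("moving_average", 0:4)),
    temp_df = cv$temp_df %||% 4,
    dow = cv$dow %||% TRUE)
  scen <- NULL
  if (!is.null(y$scenarios))
    scen <- lapply(y$scenarios, function(a) {
      if (!is.null(a$curve)) {
        a$curve <- if (a$curve$kind == "linear") linear_curve(a$curve$beta)
                   else supralinear_curve(a$curve$alpha, a$curve$scale)
      }
      do.call(city_scenario, a)
    })
  run_config(
    scenarios = scen,
    input_files = unlist(y$input_files),
    cov = cov,
    exposure_lag = as_lag(y$exposure_lag, lag_spec("moving_average", 0:1)),
    iv = y$iv %||% TRUE,
    erc_spec = spline_spec(y$erc_knot_percentiles %||% 50),
    reference = y$reference %||% "minimum",
    thresholds = y$thresholds %||% c(250, 125, 100, 75, 60),
    n_sim = y$n_sim %||% 1000L,
    seed = y$seed %||% 1L)
}

#' Execute the full multi-city pipeline
#'
#' Runs synthesis-or-read, the city-specific quasi-Poisson stage (with
#' optional lag panel and restriction thresholds), the IV stage, univariate
#' random-effects pooling, exposure-response curve estimation with
#' multivariate pooling into the integrated curve, and attributable-burden
#' estimation with Monte-Carlo intervals. Every table is written as CSV
#' under `out_dir` together with a JSON manifest (config hash, seeds,
#' package version, stage diagnostics).
#'
#' @param config a [run_config()] (or a YAML path).
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing files and return results only.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all stage results: `series`, `stage1`
#'   (forest table), `pooled`, `iv` (forest table), `iv_pooled`, `curves`,
#'   `mvmeta`, `integrated`, `af`, `thresholds`, `lag_panel`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()

  # stage: data
  say("stage data: ", if (!is.null(config$scenarios)) "generating synthetic series"
      else "reading input files")
  series <- if (!is.null(config$scenarios)) generate_multicity(config$scenarios)
            else {
              out <- lapply(config$input_files, read_city_csv)
              names(out) <- vapply(out, function(s) s$city[1], character(1))
              out
            }

  # stage 1: conventional estimates
  say("stage 1: city-specific quasi-Poisson fits")
  fits <- lapply(series, function(s)
    fit_quasipoisson(build_design(s, config$cov, config$exposure_lag)))
  pooled <- pool(fits)
  stage1_tab <- forest_table(pooled)

  # lag panel
  lag_tab <- NULL
  if (!is.null(config$lag_panel)) {
    say("stage 1: lag panel")
    lag_tab <- do.call(rbind, lapply(series, function(s)
      run_lag_panel(s, config$cov, config$lag_panel)))
  }

  # thresholds
  thr_tab <- NULL
  if (!is.null(config$thresholds)) {
    say("stage 1: restriction thresholds")
    thr_rows <- list()
    for (ct in config$thresholds) {
      for (s in series) {
        r <- tryCatch({
          rs <- restrict_below(s, ct, config$exposure_lag)
          fit <- fit_quasipoisson(build_design(rs, config$cov))
          cbind(threshold = ct, stage1_row(fit, label = format(config$exposure_lag)),
                n_kept = rs$n_kept)
        }, error = function(e) NULL)
        if (!is.null(r)) thr_rows[[length(thr_rows) + 1]] <- r
      }
    }
    thr_tab <- do.call(rbind, thr_rows)
  }

  # IV stage
  iv_tab <- NULL; iv_pooled <- NULL; iv_fits <- NULL
  if (isTRUE(config$iv)) {
    say("stage IV: calibrated-instrument fits")
    iv_fits <- lapply(series, function(s)
      do.call(iv_effect, c(list(s, config$cov, config$exposure_lag),
                           config$iv_args)))
    iv_pooled <- pool(lapply(iv_fits, function(z) z$fit))
    iv_tab <- forest_table(iv_pooled)
    iv_tab$instrument_r2 <- c(vapply(iv_fits, function(z)
      z$instrument$r_squared, numeric(1)), NA)
  }

  # exposure-response curves and integrated curve
  say("stage ERC: city curves and multivariate pooling")
  curves <- lapply(series, function(s)
    fit_city_curve(s, config$cov, config$exposure_lag, config$erc_spec))
  all_exp <- unlist(lapply(series, function(s)
    lagged(s$pm25, config$exposure_lag)))
  all_exp <- all_exp[!is.na(all_exp)]
  common <- resolve_spline_spec(config$erc_spec, all_exp)
  reference <- if (identical(config$reference, "minimum")) min(all_exp)
               else as.numeric(config$reference)
  projected <- project_to_common_basis(curves, common, reference)
  mv <- mvmeta_pool(projected)
  icurve <- integrated_curve(mv, common, reference)

  # attribution
  say("stage AF: attributable burden (", config$n_sim, " Monte-Carlo draws)")
  af <- monte_carlo_ci(series, mv, common, reference,
                       n_sim = config$n_sim,
                       seed = (config$seed + 777L) %% .Machine$integer.max,
                       exposure_lag = config$exposure_lag)

  manifest <- list(
    package_version = as.character(utils::packageVersion("airmort")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(t_start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    seed = config$seed,
    n_cities = length(series),
    reference = reference,
    n_sim = config$n_sim,
    diagnostics = lapply(seq_along(fits), function(i) list(
      city = names(series)[i],
      converged = fits[[i]]$converged,
      dispersion = fits[[i]]$dispersion,
      edf_time = fits[[i]]$edf_time,
      instrument_r2 = if (!is.null(iv_fits)) iv_fits[[i]]$instrument$r_squared else NULL)),
    mvmeta_converged = mv$converged)

  out <- list(series = series, stage1 = stage1_tab, pooled = pooled,
              iv = iv_tab, iv_pooled = iv_pooled, curves = curves,
              mvmeta = mv, integrated = icurve, af = af,
              thresholds = thr_tab, lag_panel = lag_tab,
              common = common, reference = reference, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, nm) utils::write.csv(
      df, file.path(out_dir, nm), row.names = FALSE)
    wcsv(stage1_tab, "stage1_estimates.csv")
    if (!is.null(iv_tab)) wcsv(iv_tab, "iv_estimates.csv")
    if (!is.null(thr_tab)) wcsv(thr_tab, "threshold_estimates.csv")
    if (!is.null(lag_tab)) wcsv(lag_tab, "lag_panel.csv")
    wcsv(curve_table(icurve), "integrated_curve.csv")
    wcsv(af_table(af, series), "attributable_burden.csv")
    cfg_path <- file.path(out_dir, "config.yaml")
    .write_config_yaml(config, cfg_path)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  say(sprintf("done in %.1f s", as.numeric(difftime(Sys.time(), t_start,
                                                    units = "secs"))))
  invisible(out)
}

# serialize a run_config to YAML (round-trippable through read_run_config)
.write_config_yaml <- function(config, path) {
  lag_to_list <- function(ls) list(kind = ls$kind, lags = ls$lags)
  y <- list(
    covariates = list(time_df_per_year = config$cov$time_df_per_year,
                      temp_lag = lag_to_list(config$cov$temp_lag),
                      temp_df = config$cov$temp_df, dow = config$cov$dow),
    exposure_lag = lag_to_list(config$exposure_lag),
    iv = config$iv,
    erc_knot_percentiles = config$erc_spec$knot_percentiles,
    reference = config$reference,
    thresholds = config$thresholds,
    n_sim = config$n_sim,
    seed = config$seed)
  if (!is.null(config$input_files)) y$input_files <- as.list(config$input_files)
  if (!is.null(config$scenarios))
    y$scenarios <- lapply(config$scenarios, function(sc) {
      cl <- if (sc$curve$kind == "linear") list(kind = "linear", beta = sc$curve$beta)
            else list(kind = "supralinear", alpha = sc$curve$alpha,
                      scale = sc$curve$scale)
      list(city_id = sc$city_id, n_years = sc$n_years,
           start_date = format(sc$start_date),
           base_deaths = sc$base_deaths,
           trend_amplitude = sc$trend_amplitude,
           drift_linear = sc$drift_linear,
           dow_effects = sc$dow_effects,
           temp_mean = sc$temp_mean, temp_amplitude = sc$temp_amplitude,
           temp_sd = sc$temp_sd, temp_mmt = sc$temp_mmt,
           temp_cold = sc$temp_cold, temp_heat = sc$temp_heat,
           pblh = sc$pblh, wind = sc$wind, pressure = sc$pressure,
           pm_mean = sc$pm_mean, pm_sd = sc$pm_sd,
           local_fraction = sc$local_fraction,
           regional_share = sc$regional_share, regional_ar = sc$regional_ar,
           confounder_pm = sc$confounder_pm,
           confounder_mort = sc$confounder_mort,
           confounder_ar = sc$confounder_ar,
           curve = cl, overdispersion = sc$overdispersion, seed = sc$seed)
    })
  yaml::write_yaml(y, path)
  invisible(path)
}
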