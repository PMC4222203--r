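# Run configuration and the end-to-end demonstration pipeline:
# simulate -> prepare (yearly and monthly) -> fit -> project -> future
# ensembles -> consensus -> evaluate, every artifact listed in a manifest.

#' Default run configuration
#'
#' A nested list mirroring the module options, sized so the full pipeline
#' runs in about a minute: 2-degree synthetic ocean, 200 presences, 1000
#' background points, 10 hinge knots per variable, 2 pseudo-GCMs under one
#' warming scenario.
#'
#' @return named list (see [validate_config()] for the schema).
#' @export
default_config <- function() {
  list(
    seed = 42L,
    ocean = list(grid_step = 2, lat_range = c(-78, 80), lon_range = c(-180, 180),
                 sst_pole = -1.8, sst_equator = 28, seasonal_amp = 3,
                 nitrate_max = 30, nutrient_decay_lat = 4,
                 si_decouple_band = c(-50, -40), land_fraction = 0.2),
    truth = list(nitrate_mid = 15, nitrate_slope = 1, sst_max = 7.5, sst_slope = 1),
    sampling = list(n_presences = 200L, use_bias = FALSE),
    prepare = list(background = 1000L, replace = FALSE),
    fit = list(beta_multiplier = 1, knots_per_variable = 10,
               tol = 1e-5, max_iter = 500),
    project = list(threshold = 0.2),
    ensemble = list(scenarios = list(list(name = "rcp85", delta_sst = 2,
                                          nitrate_scale = 0.8)),
                    n_gcms = 2L, perturb_sd = 0.1),
    evaluate = list(cv_folds = 3L, jackknife = TRUE)
  )
}

.config_domains <- list(
  seed = c(-Inf, Inf),
  ocean.grid_step = c(1e-6, 90), ocean.sst_pole = c(-5, 40),
  ocean.sst_equator = c(-5, 45), ocean.seasonal_amp = c(0, 20),
  ocean.nitrate_max = c(0, 100), ocean.nutrient_decay_lat = c(0.1, 90),
  ocean.land_fraction = c(0, 0.3),
  truth.nitrate_mid = c(0, 100), truth.nitrate_slope = c(1e-9, Inf),
  truth.sst_max = c(-5, 40), truth.sst_slope = c(1e-9, Inf),
  sampling.n_presences = c(1, Inf),
  prepare.background = c(10, Inf),
  fit.beta_multiplier = c(0, Inf), fit.knots_per_variable = c(1, 200),
  fit.tol = c(0, 1), fit.max_iter = c(1, Inf),
  project.threshold = c(1e-9, 1 - 1e-9),
  ensemble.n_gcms = c(1, Inf), ensemble.perturb_sd = c(0, 1),
  evaluate.cv_folds = c(0, Inf)
)

#' Validate a run configuration
#'
#' Accepts a path to a JSON config file or an already-parsed list. Unknown
#' keys are rejected (with a nearest-known-key suggestion) and every numeric
#' option is checked against its documented domain; ALL violations are
#' collected and reported together.
#'
#' @param config path to a JSON file, or a list.
#' @return the completed config (defaults filled in) with attribute
#'   `violations = character(0)`, or — if anything is wrong — throws an
#'   error listing every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("I/O error: no such config file: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- default_config()
  viol <- character(0)
  known_top <- names(def)
  for (k in setdiff(names(config), known_top)) {
    hint <- agrep(k, known_top, max.distance = 0.4, value = TRUE)
    viol <- c(viol, paste0("unknown section '", k, "'",
                           if (length(hint)) paste0(" (did you mean '", hint[1], "'?)") else ""))
  }
  merged <- def
  for (sec in intersect(names(config), known_top)) {
    if (!is.list(def[[sec]])) { merged[[sec]] <- config[[sec]]; next }
    for (k in names(config[[sec]])) {
      if (!k %in% names(def[[sec]])) {
        hint <- agrep(k, names(def[[sec]]), max.distance = 0.4, value = TRUE)
        viol <- c(viol, paste0("unknown key '", sec, ".", k, "'",
                               if (length(hint)) paste0(" (did you mean '", hint[1], "'?)") else ""))
      } else merged[[sec]][[k]] <- config[[sec]][[k]]
    }
  }
  for (key in names(.config_domains)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- if (length(parts) == 1L) merged[[parts]] else merged[[parts[1]]][[parts[2]]]
    dom <- .config_domains[[key]]
    if (!is.numeric(val) || any(!is.finite(val)) ||
        any(val < dom[1]) || any(val > dom[2]))
      viol <- c(viol, sprintf("%s = %s outside domain [%g, %g]", key,
                              paste(format(val), collapse = ","), dom[1], dom[2]))
  }
  band <- merged$ocean$si_decouple_band
  if (length(band) != 2L || band[1] >= band[2])
    viol <- c(viol, "ocean.si_decouple_band must be c(lo, hi) with lo < hi")
  if (length(viol))
    stop("invalid config:\n  - ", paste(viol, collapse = "\n  - "), call. = FALSE)
  attr(merged, "violations") <- character(0)
  merged
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full demonstration pipeline on the synthetic ocean
#'
#' Executes simulate -> prepare (yearly and monthly) -> fit (MaxEnt yearly
#' and monthly, plus six envelope models) -> project (annual + 12 monthly
#' maps) -> future ensembles (mean/sd per month per scenario) -> consensus
#' -> evaluation, writing every artifact under `out_dir` together with a
#' `manifest.json` listing the config, the derived stage seeds and the MD5
#' of every file. Re-running with the same config and seed is bit-identical.
#'
#' @param config a config list or path (see [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(ocean = cfg$seed, sampling = cfg$seed + 1L,
                background = cfg$seed + 2L, cv = cfg$seed + 3L,
                future = cfg$seed + 4L)
  files <- character(0)
  emit <- function(rel) files <<- c(files, rel)
  wgrid <- function(g, rel) { write_grid(g, file.path(out_dir, rel)); emit(rel) }

  ## simulate ----------------------------------------------------------
  op <- do.call(ocean_params, c(cfg$ocean, list(seed = seeds$ocean)))
  env <- make_environment(op)
  tp <- do.call(truth_params, cfg$truth)
  truth_monthly <- lapply(env$monthly, true_suitability, truth = tp)
  truth_annual <- true_suitability(env$annual, tp)
  dir.create(file.path(out_dir, "env"), showWarnings = FALSE)
  for (v in names(env$annual$grids))
    wgrid(env$annual$grids[[v]], file.path("env", paste0("annual_", v, ".asc")))
  wgrid(truth_annual, file.path("env", "truth_annual.asc"))
  .log_stage("simulate", sum(env$annual$grids[[1]]$mask), " ocean cells on a ",
             cfg$ocean$grid_step, "-degree grid")

  occ <- sample_presences(truth_monthly, cfg$sampling$n_presences,
                          bias = NULL, seed = seeds$sampling)
  utils::write.csv(occ, file.path(out_dir, "occurrences.csv"), row.names = FALSE)
  emit("occurrences.csv")

  ## prepare -----------------------------------------------------------
  ref <- env$annual$grids[[1]]
  occ_y <- dedupe(occ, ref, "yearly")
  occ_m <- dedupe(occ, ref, "monthly")
  if (nrow(occ_m) == 0L)
    stop("prepare: no dated records available for the monthly model", call. = FALSE)
  pres_y <- extract_covariates(occ_y, env$annual, mode = "yearly")
  pres_m <- extract_covariates(occ_m, env$annual, env$monthly, mode = "monthly")
  bg_y <- sample_background(env$annual, cfg$prepare$background,
                            seed = seeds$background, replace = cfg$prepare$replace)
  bg_m <- sample_background(env$annual, cfg$prepare$background,
                            seed = seeds$background, replace = cfg$prepare$replace,
                            monthly = env$monthly)
  .log_stage("prepare", nrow(occ), " records -> ", nrow(occ_y), " yearly / ",
             nrow(occ_m), " monthly after grid-cell dedupe; background ",
             cfg$prepare$background)

  ## fit ---------------------------------------------------------------
  fit_args <- list(beta_multiplier = cfg$fit$beta_multiplier,
                   knots_per_variable = cfg$fit$knots_per_variable,
                   tol = cfg$fit$tol, max_iter = cfg$fit$max_iter)
  model_y <- do.call(maxent_fit, c(list(pres_y, bg_y), fit_args))
  model_m <- do.call(maxent_fit, c(list(pres_m, bg_m), fit_args))
  write_model(model_y, file.path(out_dir, "model_yearly.json")); emit("model_yearly.json")
  write_model(model_m, file.path(out_dir, "model_monthly.json")); emit("model_monthly.json")
  env_specs <- list(list("bioclim", "euclidean"), list("envelope_score", "euclidean"),
                    list("env_distance", "euclidean"), list("env_distance", "mahalanobis"),
                    list("env_distance", "manhattan_gower"), list("env_distance", "chebyshev"))
  env_models <- lapply(env_specs, function(s)
    fit_envelope(pres_y, s[[1]], s[[2]], background = bg_y))
  .log_stage("fit", "maxent yearly (", sum(model_y$lambda != 0), " active), ",
             "monthly (", sum(model_m$lambda != 0), " active), ",
             length(env_models), " envelope models")

  ## project -----------------------------------------------------------
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  map_y <- project(model_y, env$annual)
  map_m_annual <- project(model_m, env$annual)
  wgrid(map_y$grid, file.path("maps", "yearly_on_annual.asc"))
  wgrid(map_m_annual$grid, file.path("maps", "monthly_on_annual.asc"))
  monthly_maps <- vector("list", 12L)
  for (m in 1:12) {
    monthly_maps[[m]] <- project(model_m, env$monthly[[m]])
    wgrid(monthly_maps[[m]]$grid, file.path("maps", sprintf("monthly_m%02d.asc", m)))
  }
  bnd <- boundary_latitude(map_m_annual, t = cfg$project$threshold, pole = "south")
  utils::write.csv(bnd, file.path(out_dir, "boundary_monthly_on_annual.csv"),
                   row.names = FALSE)
  emit("boundary_monthly_on_annual.csv")

  ## consensus ---------------------------------------------------------
  all_maps <- c(list(map_y, map_m_annual),
                lapply(env_models, function(mo) project(mo, env$annual)))
  cons <- consensus(all_maps, t = cfg$project$threshold)
  wgrid(cons$grid, "consensus.asc")
  .log_stage("project", "1 annual + 12 monthly maps; consensus over ",
             cons$n_models, " models at t=", cfg$project$threshold)

  ## future ensembles --------------------------------------------------
  dir.create(file.path(out_dir, "future"), showWarnings = FALSE)
  for (sc in cfg$ensemble$scenarios) {
    futs <- make_future(env$monthly, delta_sst = sc$delta_sst,
                        nitrate_scale = sc$nitrate_scale,
                        n_gcms = cfg$ensemble$n_gcms, seed = seeds$future,
                        scenario = sc$name, perturb_sd = cfg$ensemble$perturb_sd)
    for (m in 1:12) {
      ens <- ensemble(model_m, lapply(futs, `[[`, m))
      wgrid(ens$mean, file.path("future", sprintf("%s_m%02d_mean.asc", sc$name, m)))
      wgrid(ens$sd, file.path("future", sprintf("%s_m%02d_sd.asc", sc$name, m)))
    }
    .log_stage("ensemble", sc$name, ": ", cfg$ensemble$n_gcms,
               " pseudo-GCMs x 12 months")
  }

  ## evaluate ----------------------------------------------------------
  report_m <- evaluate_model(model_m, pres_m, bg_m, k = cfg$evaluate$cv_folds,
                             seed = seeds$cv, jackknife = cfg$evaluate$jackknife,
                             beta_multiplier = cfg$fit$beta_multiplier,
                             knots_per_variable = cfg$fit$knots_per_variable)
  report_y <- evaluate_model(model_y, pres_y, bg_y, k = cfg$evaluate$cv_folds,
                             seed = seeds$cv, jackknife = FALSE,
                             beta_multiplier = cfg$fit$beta_multiplier,
                             knots_per_variable = cfg$fit$knots_per_variable)
  jsonlite::write_json(unclass(report_m), file.path(out_dir, "evaluation_monthly.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  jsonlite::write_json(unclass(report_y), file.path(out_dir, "evaluation_yearly.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  emit("evaluation_monthly.json"); emit("evaluation_yearly.json")
  .log_stage("evaluate", sprintf("yearly AUC %.3f, monthly AUC %.3f (cv %.3f)",
                                 report_y$auc, report_m$auc, report_m$cv_auc_mean))

  ## manifest ----------------------------------------------------------
  files <- sort(files)
  md5 <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(config = merge_sorted(cfg), seeds = seeds,
                   counts = list(records = nrow(occ), yearly = nrow(occ_y),
                                 monthly = nrow(occ_m)),
                   files = data.frame(path = files, md5 = md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# config with stable (sorted) key order so manifests compare bit-identically
merge_sorted <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x)) && all(nzchar(names(x)))) x <- x[order(names(x))]
  lapply(x, merge_sorted)
}
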