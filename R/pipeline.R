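#' Pipeline configuration
#'
#' Validates and normalises the configuration for [run_pipeline()]. Exactly
#' one of `paths` (real input files) or `synthetic` (generator settings) must
#' be supplied. A single master seed deterministically spawns per-stage seeds
#' so stochastic stages (synthesis, train/test split, collinearity sample,
#' bootstrap) can be re-run in isolation.
#'
#' @param synthetic list of [simulate_env_stack()] / [simulate_occurrences()]
#'   settings: `nrow`, `ncol`, `variables`, `smoothness`, `nodata_frac`,
#'   `envelope`, `n_occurrences`, `noise`. Missing entries take the
#'   generator defaults.
#' @param paths list with `occurrences` (CSV path), `rasters` (named vector
#'   of ASCII-grid paths) and optional `units`.
#' @param train_frac training fraction for [clean_and_split()].
#' @param cor_threshold,n_cor_points [correlation_filter()] settings.
#' @param E,n_boot,resample_frac [partial_roc()] settings.
#' @param conditions a `condition_set`; default [enceladus_conditions()].
#' @param scenario `"full_ocean"`, `"hydrothermal"`, or `"both"`.
#' @param t_horizon evaluation time for the growth scenarios, yr.
#' @param budget a [hydrogen_budget()].
#' @param params [growth_parameters()].
#' @param seed master integer seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            train_frac = 0.75, cor_threshold = 0.8,
                            n_cor_points = 10000, E = 0.05, n_boot = 1000,
                            resample_frac = 0.5, conditions = NULL,
                            scenario = "both",
                            t_horizon = const_value("life_horizon"),
                            budget = hydrogen_budget(),
                            params = growth_parameters(), seed = 1) {
  if (is.null(synthetic) == is.null(paths))
    stop("exactly one of `synthetic` or `paths` must be supplied")
  stopifnot(train_frac > 0, train_frac < 1, cor_threshold > 0,
            E > 0, E < 1, n_boot >= 1, resample_frac > 0,
            resample_frac <= 1, t_horizon > 0)
  if (!scenario %in% c("full_ocean", "hydrothermal", "both"))
    stop(sprintf("unknown scenario '%s'", scenario))
  structure(list(synthetic = synthetic, paths = paths,
                 train_frac = train_frac, cor_threshold = cor_threshold,
                 n_cor_points = n_cor_points, E = E, n_boot = n_boot,
                 resample_frac = resample_frac, conditions = conditions,
                 scenario = scenario, t_horizon = t_horizon,
                 budget = budget, params = params, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar tunables are read from YAML; complex objects (budget, parameters,
#' conditions) keep their defaults unless overridden programmatically.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("synthetic", "paths", "train_frac", "cor_threshold",
                        "n_cor_points", "E", "n_boot", "resample_frac",
                        "scenario", "t_horizon", "seed"))]
  do.call(pipeline_config, args)
}

#' Run the full niche + biomass analysis
#'
#' Executes the stages in order: generate (or read) the environmental stack
#' and occurrences; clean, extract and split; filter collinear predictors;
#' fit the Bioclim envelope; predict the suitability grid; evaluate by
#' partial ROC on the held-out test records; overlay the condition registry
#' on the fitted response curves; and compute the hydrogen-budget growth
#' scenarios. A second run with the same config produces an identical report.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, writes `report.json`,
#'   `suitability.asc`, `response_curves.csv`, and (for synthetic runs)
#'   the stack, occurrences and a truth sidecar JSON.
#' @return a `run_report` list: counts, retained variables, the fitted
#'   model, AUC ratio and p-value, overlay verdicts, biomass summaries,
#'   per-stage seeds, and accumulated warnings.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, 4))
  names(seeds) <- c("simulate", "split", "corfilter", "bootstrap")
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # stage: inputs
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    variables <- sy$variables %||% default_variables()
    stack <- simulate_env_stack(
      nrow = sy$nrow %||% 100, ncol = sy$ncol %||% 100,
      variables = variables,
      smoothness = sy$smoothness %||% 3,
      nodata_frac = sy$nodata_frac %||% 0,
      seed = seeds[["simulate"]])
    envelope <- sy$envelope %||% default_true_envelope(variables)
    occ <- simulate_occurrences(stack, envelope,
                                n = sy$n_occurrences %||% 400,
                                noise = sy$noise %||% 0.05,
                                seed = seeds[["simulate"]] + 1)
  } else {
    stack <- read_env_stack(unlist(config$paths$rasters),
                            names(config$paths$rasters),
                            units = config$paths$units)
    occ <- read_occurrences(config$paths$occurrences)
    envelope <- NULL
  }

  # stage: clean / extract / split
  occ_set <- withCallingHandlers(
    clean_and_split(occ, stack, train_frac = config$train_frac,
                    seed = seeds[["split"]]),
    warning = log_warn)

  # stage: collinearity prefilter
  retained <- withCallingHandlers(
    correlation_filter(stack, n_points = config$n_cor_points,
                       threshold = config$cor_threshold,
                       seed = seeds[["corfilter"]]),
    warning = log_warn)

  # stage: fit + predict
  model <- withCallingHandlers(
    bioclim(occ_set, variables = retained), warning = log_warn)
  suitability <- predict(model, stack)

  # stage: partial ROC on the test partition
  test_rows <- occ_set[occ_set$partition == "test", , drop = FALSE]
  test_suit <- predict(model, test_rows[, retained, drop = FALSE])
  roc <- withCallingHandlers(
    partial_roc(suitability, test_suit, E = config$E,
                n_boot = config$n_boot,
                resample_frac = config$resample_frac,
                seed = seeds[["bootstrap"]]),
    warning = log_warn)

  # stage: condition overlay
  curves <- response_curves(model)
  conditions <- config$conditions
  if (is.null(conditions)) {
    conditions <- enceladus_conditions()
    conditions <- conditions[conditions$variable %in% retained, ,
                             drop = FALSE]
  }
  overlay <- if (nrow(conditions) > 0L)
    overlay_conditions(curves, conditions) else NULL

  # stage: biomass scenarios
  scenarios <- if (config$scenario == "both")
    c("full_ocean", "hydrothermal") else config$scenario
  biomass <- lapply(scenarios, function(sc)
    scenario_concentration(config$params, config$budget, sc,
                           t = config$t_horizon))
  names(biomass) <- scenarios

  report <- structure(list(
    counts = list(raw = nrow(occ), cleaned = nrow(occ_set),
                  train = sum(occ_set$partition == "train"),
                  test = sum(occ_set$partition == "test")),
    retained_variables = retained,
    true_envelope = envelope,
    model = model,
    suitability = suitability,
    auc_ratio = roc$auc_ratio,
    p_value = roc$p_value,
    roc = roc,
    overlay = overlay,
    biomass = biomass,
    seeds = as.list(seeds),
    master_seed = config$seed,
    warnings = warnings_log), class = "run_report")

  if (!is.null(outdir)) write_run_report(report, stack, curves, outdir)
  report
}

# Serialise the pipeline artifacts under `outdir`.
write_run_report <- function(report, stack, curves, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_suitability_raster(report$suitability, stack,
                           file.path(outdir, "suitability.asc"))
  curve_df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(variable = attr(cv, "variable"), value = cv$value,
               suitability = cv$suitability)))
  utils::write.csv(curve_df, file.path(outdir, "response_curves.csv"),
                   row.names = FALSE)
  json <- list(
    counts = report$counts,
    retained_variables = as.list(report$retained_variables),
    envelope = lapply(report$model$envelopes, function(v)
      c(min = v[1], max = v[length(v)])),
    auc_ratio = report$auc_ratio,
    p_value = report$p_value,
    overlay = if (!is.null(report$overlay))
      as.data.frame(report$overlay) else NULL,
    biomass = lapply(report$biomass, function(b)
      b[c("scenario", "t", "supply_rate", "cells", "order_of_magnitude")]),
    seeds = report$seeds,
    master_seed = report$master_seed,
    warnings = report$warnings)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Niche + biomass pipeline report\n")
  cat(sprintf("  occurrences: %d raw -> %d cleaned (%d train / %d test)\n",
              x$counts$raw, x$counts$cleaned, x$counts$train,
              x$counts$test))
  cat(sprintf("  retained predictors: %s\n",
              paste(x$retained_variables, collapse = ", ")))
  cat(sprintf("  partial ROC: mean AUC ratio %.4f, p %s\n", x$auc_ratio,
              if (x$p_value < 1 / x$roc$n_boot)
                sprintf("< %.4g", 1 / x$roc$n_boot)
              else sprintf("= %.4g", x$p_value)))
  if (!is.null(x$overlay)) {
    cat("  overlay verdicts:\n")
    for (i in seq_len(nrow(x$overlay)))
      cat(sprintf("    %-18s %s\n", x$overlay$variable[i],
                  x$overlay$verdict[i]))
  }
  for (nm in names(x$biomass))
    cat(sprintf("  biomass [%s]: %.3g cells/cm^3 (order 10^%d) at t = %.3g yr\n",
                nm, x$biomass[[nm]]$cells,
                x$biomass[[nm]]$order_of_magnitude, x$biomass[[nm]]$t))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s) logged\n", length(x$warnings)))
  invisible(x)
}
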