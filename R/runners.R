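#' Run configuration for the command-level entry points
#'
#' Validates the options shared by the `run_*` commands. A `seed` is
#' mandatory: every command is deterministic end to end for a fixed
#' configuration.
#'
#' @param input path to a CSV data set (commands that read data).
#' @param model model code or [model_spec()].
#' @param out_dir output directory; created if missing.
#' @param seed integer seed.
#' @param a_ref reference asymptote for the \eqn{k'} reparameterization.
#' @param bounds optional bounds overrides (see [model_spec()]).
#' @param settings a [pso_settings()] object.
#' @param B bootstrap resample count.
#' @param age_col,size_col input column names.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, model = "PG", out_dir = "nonchron-run",
                       seed = NULL, a_ref = 25, bounds = NULL,
                       settings = pso_settings(), B = 1001L,
                       age_col = "age", size_col = "size") {
  if (is.null(seed) || !is.finite(seed))
    stop("a 'seed' is required for reproducible runs", call. = FALSE)
  spec <- if (inherits(model, "model_spec")) model
          else model_spec(model, a_ref = a_ref, bounds = bounds)
  structure(list(input = input, spec = spec, out_dir = out_dir,
                 seed = as.integer(seed), settings = settings,
                 B = as.integer(B), age_col = age_col,
                 size_col = size_col),
            class = "run_config")
}

.prepare_out <- function(config, what) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(command = what, model = config$spec$model,
              a_ref = config$spec$a_ref, bounds = config$spec$bounds,
              seed = config$seed, B = config$B, input = config$input,
              settings = unclass(config$settings))
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

.fit_as_list <- function(fit) {
  th <- fit$theta
  list(model = fit$spec$model,
       theta = list(k = th$k, k_prime = th$k_prime, b = th$b, l = th$l,
                    a_ref = th$a_ref),
       dist = unclass(fit$dist), nll = fit$nll, k_params = fit$k_params,
       aic = fit$aic, n = nrow(fit$data), seed = fit$seed)
}

#' Command-level runners
#'
#' Thin deterministic drivers over the fitting API that write their
#' results to `out_dir` as JSON and CSV: `run_fit()` fits one model
#' (`fit.json`, `params.csv`, `curves.csv`), `run_compare()` fits
#' several and writes the AIC table and LRT matrix, `run_bootstrap()`
#' adds percentile confidence intervals, `run_simulate()` generates a
#' synthetic data set from a true model, and `run_reproduce()` runs the
#' reproductivity experiment. All are also reachable from the
#' `nonchron-cli.R` script installed under `inst/scripts`.
#'
#' @param config a [run_config()].
#' @param models model codes for `run_compare()`.
#' @param truth a [true_model()] for `run_simulate()`/`run_reproduce()`.
#' @param n observations per (simulated) data set.
#' @param reps replicate count for `run_reproduce()`.
#' @return The main result object, invisibly; artifacts on disk.
#' @name runners
NULL

#' @rdname runners
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .prepare_out(config, "fit")
  obs <- read_observations(config$input, config$age_col, config$size_col)
  fit <- fit_growth_model(obs, config$spec, settings = config$settings,
                          seed = config$seed)
  jsonlite::write_json(.fit_as_list(fit),
                       file.path(config$out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pv <- .fit_param_vector(fit)
  utils::write.csv(data.frame(parameter = names(pv), estimate = unname(pv)),
                   file.path(config$out_dir, "params.csv"),
                   row.names = FALSE)
  ages <- seq(min(obs$age), max(obs$age), length.out = 50)
  utils::write.csv(percentile_curves(fit, ages = ages),
                   file.path(config$out_dir, "curves.csv"),
                   row.names = FALSE)
  invisible(fit)
}

#' @rdname runners
#' @export
run_compare <- function(config, models = c("AL", "AG", "PL", "PG")) {
  stopifnot(inherits(config, "run_config"))
  .prepare_out(config, "compare")
  obs <- read_observations(config$input, config$age_col, config$size_col)
  cmp <- compare_models(obs, models = models, settings = config$settings,
                        seed = config$seed)
  utils::write.csv(cmp$aic_table,
                   file.path(config$out_dir, "aic_table.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$lrt, file.path(config$out_dir, "lrt.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(cmp$fits, .fit_as_list),
                       file.path(config$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cmp)
}

#' @rdname runners
#' @export
run_bootstrap <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .prepare_out(config, "bootstrap")
  obs <- read_observations(config$input, config$age_col, config$size_col)
  boot <- bootstrap_ci(obs, config$spec, B = config$B, seed = config$seed,
                       settings = config$settings)
  ci <- data.frame(parameter = rownames(boot$ci), boot$ci,
                   row.names = NULL)
  utils::write.csv(ci, file.path(config$out_dir, "params.csv"),
                   row.names = FALSE)
  invisible(boot)
}

#' @rdname runners
#' @export
run_simulate <- function(config, truth, n) {
  stopifnot(inherits(config, "run_config"), inherits(truth, "true_model"))
  .prepare_out(config, "simulate")
  obs <- simulate_observations(truth, n, seed = config$seed)
  write_observations(obs, file.path(config$out_dir, "simulated.csv"))
  invisible(obs)
}

#' @rdname runners
#' @export
run_reproduce <- function(config, truth, n, reps) {
  stopifnot(inherits(config, "run_config"), inherits(truth, "true_model"))
  .prepare_out(config, "reproduce")
  rep <- reproductivity_experiment(truth, config$spec, n = n, reps = reps,
                                   seed = config$seed,
                                   settings = config$settings)
  utils::write.csv(rep$curves, file.path(config$out_dir, "bands.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(estimator = rep$estimator, n = rep$n,
                            reps_used = rep$reps_used,
                            n_failed = rep$n_failed,
                            coverage = as.list(rep$coverage)),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}
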