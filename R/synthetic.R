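#' Fully specified generating ("true") models
#'
#' A true model bundles curve parameters, an asymptote distribution and
#' an observable age range, and defines the sampling process the
#' likelihood assumes: ages uniform over the range, asymptotes drawn
#' from the distribution, and sizes computed deterministically from the
#' sampled asymptote and age through the curve set (all size variation
#' at a given age comes from the asymptote distribution; there is no
#' residual noise term).
#'
#' @param theta a [growth_params()] object.
#' @param dist an `"asym_dist"` object.
#' @param age_range `c(t_min, t_max)` in years, `0 < t_min < t_max`.
#' @return A list of class `"true_model"`.
#' @seealso [reference_true_models()] for published point estimates
#'   usable as simulation truths.
#' @export
true_model <- function(theta, dist, age_range = c(11, 110)) {
  stopifnot(inherits(theta, "growth_params"), inherits(dist, "asym_dist"),
            length(age_range) == 2L, age_range[1] > 0,
            age_range[2] > age_range[1])
  structure(list(theta = theta, dist = dist,
                 age_range = as.numeric(age_range)),
            class = "true_model")
}

#' Published point estimates as simulation truths
#'
#' The four instance models fitted to the cypress (*Chamaecyparis
#' obtusa*) and larch (*Larix kaempferi*) mean tree height surveys
#' (heights in metres, stand ages 11-110 and 11-118 years). Polymorphic
#' rows report the reparameterized rate \eqn{k'} (reference asymptote
#' 25 m); the natural rate is \eqn{k = k' / 25^l}.
#'
#' @return A nested list: `$cypress` and `$larch`, each with elements
#'   `AL`, `AG`, `PL`, `PG` of class `"true_model"`.
#' @export
reference_true_models <- function() {
  list(
    cypress = list(
      AL = true_model(growth_params(k = 0.0463, b = 1.76),
                      lognormal_dist(3.06, 0.194), c(11, 110)),
      AG = true_model(growth_params(k = 0.0413, b = 1.50),
                      gengamma_dist(11.9, 4.73, 2.47), c(11, 110)),
      PL = true_model(growth_params_kprime(0.0190, b = 1.16, l = 8.29),
                      lognormal_dist(3.25, 0.031), c(11, 110)),
      PG = true_model(growth_params_kprime(0.0278, b = 1.22, l = 3.85),
                      gengamma_dist(8.70, 30.98, 3.25), c(11, 110))),
    larch = list(
      AL = true_model(growth_params(k = 0.0471, b = 1.35),
                      lognormal_dist(3.26, 0.161), c(11, 118)),
      AG = true_model(growth_params(k = 0.0467, b = 1.29),
                      gengamma_dist(24.9, 1.70, 5.48), c(11, 118)),
      PL = true_model(growth_params_kprime(0.0488, b = 1.32, l = 0.75),
                      lognormal_dist(3.26, 0.123), c(11, 118)),
      PG = true_model(growth_params_kprime(0.0452, b = 1.30, l = 0.27),
                      gengamma_dist(24.1, 2.03, 5.48), c(11, 118))))
}

#' Simulate a nonchronological data set from a true model
#'
#' Draws `t_i ~ Uniform(t_min, t_max)` and `A_i` from the asymptote
#' distribution, then sets `x_i = growth_size(theta, A_i, t_i)` exactly.
#' Identical `(model, n, seed)` give identical data.
#'
#' @param model a [true_model()].
#' @param n number of individuals.
#' @param seed integer seed.
#' @return An [observation_set()] with attribute `"asymptotes"` (the
#'   generating `A_i`).
#' @export
simulate_observations <- function(model, n, seed) {
  stopifnot(inherits(model, "true_model"), n >= 1)
  with_seed(seed, {
    t <- stats::runif(n, model$age_range[1], model$age_range[2])
    A <- asym_sample(model$dist, n)
    x <- growth_size(model$theta, A, t)
    obs <- observation_set(t, x)
    attr(obs, "asymptotes") <- A
    obs
  })
}

#' Model reproductivity experiment
#'
#' Parametric simulation assessing whether the estimation procedure
#' reproduces a known generating model: for each replicate, `n`
#' observations are generated from `true_model`, the `estimator` model
#' is fitted blind to the truth, and the fitted percentile growth
#' curves (asymptote quantiles 2.5%, 50%, 97.5%) are recorded on a
#' common age grid. Across replicates the pointwise median and the
#' 2.5th/97.5th percentile envelope of each estimated curve are
#' compared with the true curves; with a proper (or compatible)
#' estimator the median estimates overlap the truth, while a
#' misspecified curve family leaves the true tail-percentile curves
#' outside the envelopes at old ages no matter how large `n` is.
#'
#' @param truth a [true_model()].
#' @param estimator a model code or [model_spec()].
#' @param n observations per replicate (100 or 200 in the reference
#'   experiment).
#' @param reps number of replicates (`>= 2`; 1001 in the reference
#'   experiment, desk-scale runs use about 100).
#' @param seed integer seed.
#' @param quantiles asymptote quantiles whose curves are tracked.
#' @param ages common age grid; defaults to 25 points spanning the
#'   truth's age range.
#' @param settings [pso_settings()] for the replicate fits.
#' @return A list of class `"reproductivity_report"`: `curves` (data
#'   frame with, per age and quantile: `true_size`, `est_median`,
#'   `env_lower`, `env_upper`, `covered`), `coverage` (per-quantile
#'   fraction of grid points whose envelope contains the true curve),
#'   `reps_used`, `n_failed`, plus the call ingredients.
#' @export
reproductivity_experiment <- function(truth, estimator, n, reps, seed = 1L,
                                      quantiles = c(0.025, 0.5, 0.975),
                                      ages = NULL,
                                      settings = pso_settings()) {
  stopifnot(inherits(truth, "true_model"), reps >= 2)
  reps <- as.integer(reps)
  spec <- .as_model_spec(estimator)
  if (is.null(ages))
    ages <- seq(truth$age_range[1], truth$age_range[2], length.out = 25)
  seeds <- derive_seeds(seed, 2L * reps)
  nq <- length(quantiles); na <- length(ages)
  est <- array(NA_real_, dim = c(reps, na, nq))
  failed <- 0L
  for (r in seq_len(reps)) {
    obs <- simulate_observations(truth, n, seeds[r])
    fit <- tryCatch(
      fit_growth_model(obs, spec, settings = settings,
                       seed = seeds[reps + r]),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    pc <- percentile_curves(fit, quantiles = quantiles, ages = ages)
    est[r, , ] <- matrix(pc$size, nrow = na)
  }
  used <- reps - failed
  if (used < 2L)
    stop(errorCondition("reproductivity experiment: fewer than 2 usable replicates",
                        class = c("nonchron_experiment_error", "nonchron_error")))
  true_pc <- percentile_curves(truth$theta, quantiles = quantiles,
                               ages = ages, dist = truth$dist)
  rows <- lapply(seq_len(nq), function(j) {
    sl <- est[, , j, drop = FALSE][, , 1]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = reps)
    med <- apply(sl, 2, stats::median, na.rm = TRUE)
    lo <- apply(sl, 2, stats::quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(sl, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
    tr <- true_pc$size[true_pc$quantile == quantiles[j]]
    data.frame(age = ages, quantile = quantiles[j], true_size = tr,
               est_median = med, env_lower = lo, env_upper = hi,
               covered = tr >= lo & tr <= hi)
  })
  curves <- do.call(rbind, rows)
  coverage <- vapply(split(curves$covered, curves$quantile), mean,
                     numeric(1))
  structure(list(curves = curves, coverage = coverage,
                 reps_used = used, n_failed = failed, n = n,
                 estimator = spec$model, quantiles = quantiles),
            class = "reproductivity_report")
}

#' @export
print.reproductivity_report <- function(x, ...) {
  cat(sprintf("Reproductivity experiment: estimator %s, n = %d, %d replicates (%d failed)\n",
              x$estimator, x$n, x$reps_used + x$n_failed, x$n_failed))
  cat("Envelope coverage of the true curve by asymptote quantile:\n")
  print(round(x$coverage, 3))
  invisible(x)
}
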