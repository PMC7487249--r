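#' Fit and compare the four instance models on one data set
#'
#' Fits each requested model, tabulates NLL / parameter count / AIC /
#' delta-AIC, and runs every admissible likelihood ratio test (reduced
#' model in rows, full model in columns). The AG-PL pair is not nested;
#' its cell is marked `"not conducted"`.
#'
#' @inheritParams fit_growth_model
#' @param models character vector of model codes to compare.
#' @return A list of class `"model_comparison"`: `fits` (named list of
#'   `"growth_fit"`), `aic_table` (data frame ordered as given), and
#'   `lrt` (data frame of pairwise tests with `chi2`, `df`, `p`,
#'   `stars`, `note`).
#' @export
compare_models <- function(data, models = c("AL", "AG", "PL", "PG"),
                           settings = pso_settings(), seed = 1L) {
  stopifnot(length(models) >= 1)
  fits <- lapply(models, function(m)
    fit_growth_model(data, m, settings = settings, seed = seed))
  names(fits) <- models
  aic_table <- data.frame(
    model = models,
    nll = vapply(fits, function(f) f$nll, numeric(1)),
    k_params = vapply(fits, function(f) f$k_params, integer(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  aic_table$delta_aic <- aic_table$aic - min(aic_table$aic)
  pairs <- expand.grid(reduced = models, full = models,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$reduced != pairs$full, ]
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    r <- pairs$reduced[i]; f <- pairs$full[i]
    res <- tryCatch(lr_test(fits[[r]], fits[[f]]),
                    nonchron_nonnested_error = function(e) "nonnested",
                    error = function(e) NULL)
    if (is.null(res)) next                      # not a reduced-full pair
    if (identical(res, "nonnested"))
      rows[[length(rows) + 1L]] <-
        data.frame(reduced = r, full = f, chi2 = NA_real_, df = NA_integer_,
                   p = NA_real_, stars = "",
                   note = "not conducted (nonnested)")
    else
      rows[[length(rows) + 1L]] <-
        data.frame(reduced = r, full = f, chi2 = res$chi2, df = res$df,
                   p = res$p, stars = res$stars, note = "")
  }
  lrt <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(fits = fits, aic_table = aic_table, lrt = lrt),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison\n\nAIC table:\n")
  tab <- x$aic_table
  tab$nll <- round(tab$nll, 2); tab$aic <- round(tab$aic, 2)
  tab$delta_aic <- round(tab$delta_aic, 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat("\nLikelihood ratio tests (reduced vs full):\n")
    tab <- x$lrt
    tab$chi2 <- round(tab$chi2, 2); tab$p <- round(tab$p, 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
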