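#' Information criteria
#'
#' `aic(loglik, k) = 2k - 2*loglik`; `bic(loglik, k, n) = k*log(n) -
#' 2*loglik` with `n` the number of trials entering the likelihood.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations (>= 1).
#' @return Scalar criterion value (lower is better).
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 0)
  2 * k - 2 * loglik
}

#' @rdname aic
#' @export
bic <- function(loglik, k, n) {
  stopifnot(k >= 0)
  if (n < 1) stop("n must be >= 1")
  k * log(n) - 2 * loglik
}

#' Construct a model-fit record
#'
#' Container for one model fit; the AIC/BIC invariants are enforced at
#' construction.
#'
#' @param model Model label (e.g. `"nbm"`, `"im_full"`, `"im_partial"`).
#' @param params Fitted parameter object.
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_obs Number of trials entering the likelihood.
#' @param converged Logical convergence flag.
#' @param seed Optional seed recorded for provenance.
#' @return A `swap_fit` list with `aic` and `bic` filled in.
#' @export
fit_result <- function(model, params, loglik, n_params, n_obs,
                       converged = TRUE, seed = NULL) {
  stopifnot(is.finite(loglik), n_params >= 0, n_obs >= 1)
  structure(list(model = model, params = params, loglik = loglik,
                 n_params = as.integer(n_params), n_obs = as.integer(n_obs),
                 aic = aic(loglik, n_params), bic = bic(loglik, n_params, n_obs),
                 converged = isTRUE(converged), seed = seed),
            class = "swap_fit")
}

#' @export
print.swap_fit <- function(x, ...) {
  cat(sprintf("<swap_fit %s> loglik %.2f  k %d  n %d  AIC %.1f  BIC %.1f%s\n",
              x$model, x$loglik, x$n_params, x$n_obs, x$aic, x$bic,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' Compare model fits across datasets
#'
#' Given, per dataset (e.g. per synthetic subject), one fit per model,
#' computes the AIC and BIC differences to the best model of each dataset
#' and counts for how many datasets each model is best under each criterion.
#' Ties are broken by the order in which models first appear (and noted).
#'
#' @param fits A list over datasets; each element a named list of
#'   `swap_fit` objects (same model set everywhere).
#' @return A `swap_comparison`: `table` (per model: mean delta AIC/BIC and
#'   best counts) and `per_dataset` (long data frame of deltas).
#' @export
compare_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  models <- names(fits[[1]])
  if (is.null(models)) stop("each dataset needs a named list of fits")
  for (d in seq_along(fits)) {
    if (!setequal(names(fits[[d]]), models)) {
      stop("dataset ", d, " is missing fits for: ",
           paste(setdiff(models, names(fits[[d]])), collapse = ", "))
    }
  }
  rows <- list()
  ties <- 0L
  for (d in seq_along(fits)) {
    f <- fits[[d]][models]
    a <- vapply(f, `[[`, numeric(1), "aic")
    b <- vapply(f, `[[`, numeric(1), "bic")
    if (sum(a == min(a)) > 1 || sum(b == min(b)) > 1) ties <- ties + 1L
    rows[[d]] <- data.frame(dataset = d, model = models,
                            delta_aic = a - min(a), delta_bic = b - min(b),
                            best_aic = seq_along(a) == which.min(a),
                            best_bic = seq_along(b) == which.min(b))
  }
  long <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(models, function(m) {
    s <- long[long$model == m, ]
    data.frame(model = m,
               mean_delta_aic = mean(s$delta_aic),
               mean_delta_bic = mean(s$delta_bic),
               n_best_aic = sum(s$best_aic),
               n_best_bic = sum(s$best_bic))
  }))
  if (ties > 0) message(ties, " dataset(s) had criterion ties; broken by model order")
  structure(list(table = tab, per_dataset = long, n_datasets = length(fits)),
            class = "swap_comparison")
}

#' @export
print.swap_comparison <- function(x, ...) {
  cat("<swap_comparison> over", x$n_datasets, "dataset(s)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
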