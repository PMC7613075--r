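#' Default pipeline configuration
#'
#' A complete synthetic study in one list: generate both report conditions
#' of the orientation/location task from the neural binding model, estimate
#' swap frequencies with all three estimators, predict location-report swap
#' rates from the orientation-report error pools, fit the three models, and
#' compare them. Every element can be overridden.
#'
#' @param n_trials_per_level Trials per condition level and report
#'   condition.
#' @param seed Top-level seed.
#' @return A config list understood by [run_pipeline()].
#' @export
pipeline_config <- function(n_trials_per_level = 96L, seed = 1L) {
  list(
    seed = as.integer(seed),
    n_trials_per_level = as.integer(n_trials_per_level),
    generator = list(
      model = "nbm",
      kappa_loc = 12, kappa_feat = 5, gain = 30,
      conjunction = c(low = 0.35, medium = 0.55, high = 0.8)
    ),
    predictor = list(n_iter = 1000L),
    randomization = list(n_iter = 200L),
    fit = list(models = c("nbm", "im_full", "im_partial"),
               nbm_restarts = 2L, nbm_maxit = 300L,
               im_restarts = 2L, im_maxit = 400L,
               grid_size = 720L)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    raw <- yaml::read_yaml(config)
    base <- pipeline_config()
    base[names(raw)] <- lapply(names(raw), function(nm) {
      if (is.list(base[[nm]]) && is.list(raw[[nm]])) {
        merged <- base[[nm]]
        merged[names(raw[[nm]])] <- raw[[nm]]
        merged
      } else raw[[nm]]
    })
    cj <- base$generator$conjunction
    if (is.list(cj)) base$generator$conjunction <- unlist(cj)
    base
  } else config
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

write_stage_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# swapkit %s  seed %s  written %s",
                     as.character(utils::packageVersion("swapkit")),
                     seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Stages: `simulate` (both report conditions from the configured
#' generator), `estimate` (nearest-item, mixture and resultant-vector swap
#' estimates per level in the location-report condition), `predict` (Monte
#' Carlo swap prediction from the orientation-report error pools), `fit`
#' (the configured models) and `compare`. Each stage writes plain-text
#' artifacts into `out_dir` and is skipped when its output already exists,
#' so deleting one intermediate recomputes only that stage and those after
#' it. Progress is logged via `message()`.
#'
#' @param config A config list from [pipeline_config()], or a path to a
#'   YAML file with overrides.
#' @param out_dir Artifact directory (created if missing).
#' @return Invisibly, a list with the main tables (estimates, predictions,
#'   fits, comparison).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "swapkit-run") {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  t_start <- proc.time()[3]
  message("swapkit pipeline: seed ", seed, ", output in ", normalizePath(out_dir))

  ## stage 1: simulate ------------------------------------------------------
  f_loc <- stage_file(out_dir, "responses_location_report.tsv")
  f_ori <- stage_file(out_dir, "responses_orientation_report.tsv")
  gp <- cfg$generator
  params <- nbm_params(gp$kappa_loc, gp$kappa_feat, gp$gain, gp$conjunction)
  cfg_loc <- task_orientation_location("location", cfg$n_trials_per_level)
  cfg_ori <- task_orientation_location("orientation", cfg$n_trials_per_level)
  if (!file.exists(f_loc) || !file.exists(f_ori)) {
    message("[simulate] generating ", cfg$n_trials_per_level, " trials/level/condition")
    trials_loc <- generate_trials(cfg_loc, seed = seed)
    resp_loc <- simulate_responses(trials_loc, gp$model, params, seed = seed + 1L)
    trials_ori <- generate_trials(cfg_ori, seed = seed + 2L)
    resp_ori <- simulate_responses(trials_ori, gp$model, params, seed = seed + 3L)
    write_trials(resp_loc, f_loc)
    write_trials(resp_ori, f_ori)
  } else {
    message("[simulate] cached")
  }
  resp_loc <- read_trials(f_loc); attr(resp_loc, "config") <- cfg_loc
  resp_ori <- read_trials(f_ori); attr(resp_ori, "config") <- cfg_ori

  ## stage 2: estimate ------------------------------------------------------
  f_est <- stage_file(out_dir, "swap_estimates.tsv")
  if (!file.exists(f_est)) {
    message("[estimate] nearest-item, mixture, resultant-vector")
    set.seed(seed + 10L)
    est <- rbind(estimate_swaps(resp_loc, "nearest_item"),
                 estimate_swaps(resp_loc, "mixture"),
                 estimate_swaps(resp_loc, "resultant_vector"))
    write_stage_tsv(est, f_est, seed)
  } else message("[estimate] cached")
  est <- read_stage_tsv(f_est)

  ## stage 3: predict -------------------------------------------------------
  f_pred <- stage_file(out_dir, "swap_predictions.tsv")
  if (!file.exists(f_pred)) {
    message("[predict] Monte Carlo, ", cfg$predictor$n_iter, " iterations/trial")
    pools <- build_error_pools(resp_ori)
    pred <- predict_swaps(resp_loc, pools, n_iter = cfg$predictor$n_iter,
                          seed = seed + 20L)
    write_stage_tsv(pred, f_pred, seed)
  } else message("[predict] cached")
  pred <- read_stage_tsv(f_pred)

  ## stage 4: fit -----------------------------------------------------------
  f_fit <- stage_file(out_dir, "model_fits.json")
  both <- rbind(as.data.frame(resp_loc), as.data.frame(resp_ori))
  class(both) <- class(resp_loc)
  if (!file.exists(f_fit)) {
    fits <- list()
    if ("nbm" %in% cfg$fit$models) {
      message("[fit] neural binding model")
      set.seed(seed + 30L)
      fits$nbm <- fit_nbm(both, n_restarts = cfg$fit$nbm_restarts,
                          grid_size = cfg$fit$grid_size,
                          maxit = cfg$fit$nbm_maxit)
    }
    if ("im_full" %in% cfg$fit$models) {
      message("[fit] interference model (full)")
      set.seed(seed + 31L)
      fits$im_full <- fit_im(both, "full", n_restarts = cfg$fit$im_restarts,
                             maxit = cfg$fit$im_maxit)
    }
    if ("im_partial" %in% cfg$fit$models) {
      message("[fit] interference model (partial, cue-independent weight = 0)")
      set.seed(seed + 32L)
      fits$im_partial <- fit_im(both, "partial", n_restarts = cfg$fit$im_restarts,
                                maxit = cfg$fit$im_maxit)
    }
    summ <- lapply(fits, function(f) {
      list(model = f$model, loglik = f$loglik, n_params = f$n_params,
           n_obs = f$n_obs, aic = f$aic, bic = f$bic, converged = f$converged,
           params = fit_params_to_list(f))
    })
    jsonlite::write_json(summ, f_fit, auto_unbox = TRUE, digits = 8, pretty = TRUE)
  } else {
    message("[fit] cached")
    summ <- jsonlite::read_json(f_fit)
    fits <- lapply(summ, function(s) {
      fit_result(s$model, s$params, s$loglik, s$n_params, s$n_obs, s$converged)
    })
  }

  ## stage 5: compare -------------------------------------------------------
  f_cmp <- stage_file(out_dir, "model_comparison.tsv")
  cmp <- NULL
  if (length(fits) >= 1) {
    if (!file.exists(f_cmp)) {
      message("[compare] AIC/BIC")
      cmp <- compare_fits(list(fits))
      write_stage_tsv(cmp$table, f_cmp, seed)
    } else message("[compare] cached")
    cmp <- read_stage_tsv(f_cmp)
  }

  message(sprintf("pipeline finished in %.1f s", proc.time()[3] - t_start))
  invisible(list(estimates = est, predictions = pred, fits = fits,
                 comparison = cmp))
}

# flatten fitted params for JSON
fit_params_to_list <- function(f) {
  p <- f$params
  if (inherits(p, "nbm_params")) {
    list(kappa_loc = p$kappa_loc, kappa_feat = p$kappa_feat, gain = p$gain,
         conjunction = as.list(p$conjunction))
  } else if (is.list(p) && !is.null(p$cells)) {
    lapply(p$cells, function(cf) {
      q <- cf$params
      list(kappa = q$kappa, kappa_f = q$kappa_f, A_a = q$A_a, A_b = q$A_b,
           s = q$s, r = q$r, loglik = cf$loglik)
    })
  } else p
}
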