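#' Configure a synthetic cued-recall experiment
#'
#' Describes the structure of a continuous-report cued recall task: set size,
#' which feature dimension serves as cue, condition levels, minimum pairwise
#' separations between item features, and how item locations are laid out.
#' All separations are given in radians of the analysis space, i.e. after any
#' orientation doubling (see [scale_orientation()]): a 15-degree separation in
#' the native 180-degree orientation space is `pi/6` here.
#'
#' @param set_size Number of items per memory array.
#' @param cue_dim One of `"location"`, `"orientation"`, `"direction"`: the
#'   dimension used to indicate the target. The other dimension is reported.
#' @param report_dim Name of the reported dimension.
#' @param levels Character vector of condition labels (e.g. reliability
#'   levels of the manipulated feature).
#' @param min_sep_cue,min_sep_rep Minimum pairwise circular separation of cue
#'   and report features (radians, analysis space). Use 0 for no constraint.
#' @param n_trials_per_level Default number of trials generated per level.
#' @param spatial_mode `"continuous"` (locations drawn uniformly subject to
#'   the minimum separation), `"fixed"` (same equispaced locations every
#'   trial), `"rotated"` (equispaced with a fresh uniform rotation per trial)
#'   or `"random"` (alias of continuous, used for the spatially cued task).
#' @return An object of class `swap_config`.
#' @seealso [task_orientation_location()], [task_direction_location()],
#'   [task_spatial_cue()] for ready-made designs.
#' @export
experiment_config <- function(set_size,
                              cue_dim = c("location", "orientation", "direction"),
                              report_dim = "location",
                              levels = "all",
                              min_sep_cue = 0,
                              min_sep_rep = 0,
                              n_trials_per_level = 100L,
                              spatial_mode = c("continuous", "fixed", "rotated", "random")) {
  cue_dim <- match.arg(cue_dim)
  spatial_mode <- match.arg(spatial_mode)
  stopifnot(set_size >= 1, min_sep_cue >= 0, min_sep_rep >= 0,
            n_trials_per_level >= 1, length(levels) >= 1)
  for (ms in c(min_sep_cue, min_sep_rep)) {
    if (set_size > 1 && set_size * ms > 2 * pi + 1e-12) {
      stop("infeasible design: set_size * min_sep exceeds the circle")
    }
  }
  structure(
    list(set_size = as.integer(set_size), cue_dim = cue_dim,
         report_dim = report_dim, levels = as.character(levels),
         min_sep_cue = min_sep_cue, min_sep_rep = min_sep_rep,
         n_trials_per_level = as.integer(n_trials_per_level),
         spatial_mode = spatial_mode),
    class = "swap_config")
}

#' @export
print.swap_config <- function(x, ...) {
  cat("<swap_config> ", x$set_size, " items, cue = ", x$cue_dim,
      ", report = ", x$report_dim, "\n", sep = "")
  cat("  levels: ", paste(x$levels, collapse = ", "),
      "; trials/level: ", x$n_trials_per_level, "\n", sep = "")
  cat(sprintf("  min separation cue %.1f deg / report %.1f deg; spatial mode %s\n",
              x$min_sep_cue * 180 / pi, x$min_sep_rep * 180 / pi, x$spatial_mode))
  invisible(x)
}

#' Ready-made task designs
#'
#' `task_orientation_location()`: six oriented ellipse-like items on an
#' invisible circle; locations have a 30-degree minimum separation and
#' orientations a 15-degree separation in the native 180-degree space
#' (30 degrees after doubling); three stimulus-reliability levels
#' (`low`/`medium`/`high` elongation). `report` chooses whether orientation
#' is reported with a location cue, or location reported with an orientation
#' cue.
#'
#' `task_direction_location()`: four moving-dot items; motion directions and
#' locations each separated by at least 60 degrees; three coherence levels.
#'
#' `task_spatial_cue()`: six orientation patches reported with a spatial cue;
#' orientations unconstrained; locations either fixed equispaced, equispaced
#' with a per-trial rotation, or random with a 36-degree minimum separation.
#'
#' @param report Which dimension is reported.
#' @param n_trials_per_level Trials generated per condition level.
#' @param mode Spatial layout for `task_spatial_cue()`.
#' @return A `swap_config`.
#' @export
task_orientation_location <- function(report = c("location", "orientation"),
                                      n_trials_per_level = 96L) {
  report <- match.arg(report)
  loc_sep <- 30 * pi / 180
  ori_sep <- scale_orientation(15)       # native 15 deg -> pi/6 doubled
  if (report == "location") {
    experiment_config(6L, cue_dim = "orientation", report_dim = "location",
                      levels = c("low", "medium", "high"),
                      min_sep_cue = ori_sep, min_sep_rep = loc_sep,
                      n_trials_per_level = n_trials_per_level)
  } else {
    experiment_config(6L, cue_dim = "location", report_dim = "orientation",
                      levels = c("low", "medium", "high"),
                      min_sep_cue = loc_sep, min_sep_rep = ori_sep,
                      n_trials_per_level = n_trials_per_level)
  }
}

#' @rdname task_orientation_location
#' @export
task_direction_location <- function(report = c("location", "direction"),
                                    n_trials_per_level = 96L) {
  report <- match.arg(report)
  sep <- 60 * pi / 180
  if (report == "location") {
    experiment_config(4L, cue_dim = "direction", report_dim = "location",
                      levels = c("low", "medium", "high"),
                      min_sep_cue = sep, min_sep_rep = sep,
                      n_trials_per_level = n_trials_per_level)
  } else {
    experiment_config(4L, cue_dim = "location", report_dim = "direction",
                      levels = c("low", "medium", "high"),
                      min_sep_cue = sep, min_sep_rep = sep,
                      n_trials_per_level = n_trials_per_level)
  }
}

#' @rdname task_orientation_location
#' @export
task_spatial_cue <- function(mode = c("fixed", "rotated", "random"),
                             n_trials_per_level = 109L) {
  mode <- match.arg(mode)
  experiment_config(6L, cue_dim = "location", report_dim = "orientation",
                    levels = mode,
                    min_sep_cue = if (mode == "random") 36 * pi / 180 else 60 * pi / 180,
                    min_sep_rep = 0,
                    n_trials_per_level = n_trials_per_level,
                    spatial_mode = mode)
}

# Draw one batch of candidate feature sets uniformly and keep those whose
# pairwise circular separations all reach min_sep. Returns n accepted rows.
rejection_sample_features <- function(n, set_size, min_sep) {
  if (set_size > 1 && set_size * min_sep >= 2 * pi - 1e-9 && min_sep > 0) {
    stop("minimum separation leaves no free volume for random sampling")
  }
  out <- matrix(NA_real_, n, set_size)
  filled <- 0L
  # acceptance probability for N points with circular gaps >= d is
  # (1 - N d / 2pi)^(N-1); batch size scales with its inverse
  acc <- if (min_sep > 0 && set_size > 1) {
    max((1 - set_size * min_sep / (2 * pi))^(set_size - 1), 1e-4)
  } else 1
  pairs <- if (set_size > 1L) utils::combn(set_size, 2) else NULL
  while (filled < n) {
    m <- ceiling((n - filled) / acc * 1.3) + 8L
    cand <- matrix(stats::runif(m * set_size, -pi, pi), m, set_size)
    if (set_size == 1L || min_sep <= 0) {
      ok <- rep(TRUE, m)
    } else {
      # all adjacent circular gaps >= d is equivalent to all pairwise
      # circular distances >= d, and the latter vectorizes
      ok <- rep(TRUE, m)
      for (p in seq_len(ncol(pairs))) {
        d <- abs(wrap_angle(cand[, pairs[1, p]] - cand[, pairs[2, p]]))
        ok <- ok & (d >= min_sep)
      }
    }
    take <- which(ok)[seq_len(min(sum(ok), n - filled))]
    if (length(take)) {
      out[filled + seq_along(take), ] <- cand[take, , drop = FALSE]
      filled <- filled + length(take)
    }
  }
  wrap_angle(out)
}

#' Generate item locations under a spatial layout
#'
#' `"fixed"` returns the same equispaced set on every trial; `"rotated"`
#' applies a fresh uniform rotation of the equispaced set per trial;
#' `"random"` rejection-samples locations uniformly subject to the minimum
#' separation. Uses the session RNG.
#'
#' @param mode One of `"fixed"`, `"rotated"`, `"random"`.
#' @param n_trials Number of trials (rows).
#' @param n_locations Items per trial.
#' @param min_sep Minimum separation in radians (random mode only).
#' @return Matrix `n_trials x n_locations` of angles in \eqn{(-\pi, \pi]}.
#' @export
generate_spatial_config <- function(mode = c("fixed", "rotated", "random"),
                                    n_trials, n_locations, min_sep = 0) {
  mode <- match.arg(mode)
  base <- wrap_angle(2 * pi * (seq_len(n_locations) - 1) / n_locations)
  switch(mode,
    fixed = matrix(base, n_trials, n_locations, byrow = TRUE),
    rotated = {
      rot <- stats::runif(n_trials, -pi, pi)
      wrap_angle(outer(rot, base, `+`))
    },
    random = rejection_sample_features(n_trials, n_locations, min_sep)
  )
}

#' Generate synthetic memory arrays
#'
#' Builds one memory array per trial under the structural constraints of a
#' [experiment_config()]: cue and report features are drawn uniformly over
#' the set of configurations satisfying the minimum-separation constraints
#' (by rejection sampling, so the accepted configurations are exactly uniform
#' on the constraint set), and the target item is chosen uniformly. For
#' layouts where location is the cue dimension, the `spatial_mode` of the
#' config governs how locations are placed.
#'
#' @param config A `swap_config`.
#' @param n_trials_per_level Optional override of the config's default.
#' @param seed Optional integer seed for reproducibility.
#' @return A `swap_trials` data frame with columns `trial_id`, `level`,
#'   `cue_dim`, `set_size`, `target_index` (1-based) and `cue_1..cue_N`,
#'   `rep_1..rep_N` in radians.
#' @export
generate_trials <- function(config, n_trials_per_level = NULL, seed = NULL) {
  stopifnot(inherits(config, "swap_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  npl <- if (is.null(n_trials_per_level)) config$n_trials_per_level else as.integer(n_trials_per_level)
  n <- npl * length(config$levels)
  N <- config$set_size

  spatial_dim <- if (config$cue_dim == "location") "cue" else "rep"
  # cue features
  cue <- if (spatial_dim == "cue" && config$spatial_mode != "continuous") {
    generate_spatial_config(config$spatial_mode, n, N, config$min_sep_cue)
  } else {
    rejection_sample_features(n, N, config$min_sep_cue)
  }
  rep_ <- rejection_sample_features(n, N, config$min_sep_rep)

  out <- data.frame(
    trial_id = seq_len(n),
    level = rep(config$levels, each = npl),
    cue_dim = config$cue_dim,
    set_size = N,
    target_index = sample.int(N, n, replace = TRUE)
  )
  colnames(cue) <- paste0("cue_", seq_len(N))
  colnames(rep_) <- paste0("rep_", seq_len(N))
  out <- cbind(out, cue, rep_)
  attr(out, "config") <- config
  class(out) <- c("swap_trials", "data.frame")
  out
}

#' Accessors for trial tables
#'
#' `cue_features()` / `report_features()` return the per-item feature
#' matrices; `target_index()` the 1-based target item; `trial_config()` the
#' attached design; `response_errors()` the signed deviation of each response
#' from the target's report feature; `nontarget_deviations()` the deviations
#' of each response from every non-target report feature (a
#' trials x (set size - 1) matrix).
#'
#' @param x A `swap_trials` or `swap_responses` data frame.
#' @return See details per accessor.
#' @export
cue_features <- function(x) {
  as.matrix(x[, grep("^cue_[0-9]+$", names(x)), drop = FALSE])
}

#' @rdname cue_features
#' @export
report_features <- function(x) {
  as.matrix(x[, grep("^rep_[0-9]+$", names(x)), drop = FALSE])
}

#' @rdname cue_features
#' @export
target_index <- function(x) x$target_index

#' @rdname cue_features
#' @export
trial_config <- function(x) attr(x, "config")

#' @rdname cue_features
#' @export
response_errors <- function(x) {
  stopifnot("response" %in% names(x))
  rp <- report_features(x)
  tgt <- rp[cbind(seq_len(nrow(x)), x$target_index)]
  circ_dist(x$response, tgt)
}

#' @rdname cue_features
#' @export
nontarget_deviations <- function(x) {
  stopifnot("response" %in% names(x))
  rp <- report_features(x)
  drop_target_columns(wrap_angle(x$response - rp), x$target_index)
}

# drop the target entry from each row of an n x N matrix, preserving the
# left-to-right order of the remaining columns
drop_target_columns <- function(m, target) {
  keep <- col(m) != target
  matrix(t(m)[t(keep)], nrow(m), ncol(m) - 1L, byrow = TRUE)
}

# non-target report features, trials x (N-1), same column order as
# nontarget_deviations()
nontarget_report_features <- function(x) {
  drop_target_columns(report_features(x), x$target_index)
}

# distances (absolute, radians) of each non-target's cue feature from the
# target's cue feature, trials x (N-1); column order matches
# nontarget_deviations()
nontarget_cue_distances <- function(x) {
  cf <- cue_features(x)
  tgt <- cf[cbind(seq_len(nrow(cf)), x$target_index)]
  abs(drop_target_columns(wrap_angle(cf - tgt), x$target_index))
}

#' Simulate responses on synthetic trials
#'
#' Attaches a response to every trial, drawn from one of the generative
#' processes implemented in the package, and records which item the process
#' actually selected (`ground_truth_selected`; `NA` for uniform/guess draws).
#' This ground truth is what estimator-validation compares against.
#'
#' Models:
#' \describe{
#'   \item{`target_only`}{response is a von Mises draw around the target's
#'     report feature; `params = list(kappa = ...)`.}
#'   \item{`mixture`}{classic three-component process: with probability
#'     `p_target` respond around the target, with `p_nontarget` around a
#'     uniformly chosen non-target, else uniformly. `params` also carries
#'     `kappa` and optionally `error = "von_mises"` (default) or
#'     `"wrapped_laplace"` with `rate`, to emulate non-von-Mises error
#'     shapes.}
#'   \item{`nbm`}{the spiking neural binding model; `params` from
#'     [nbm_params()].}
#'   \item{`im`}{the interference model; `params` from [im_params()].}
#' }
#'
#' @param trials A `swap_trials` data frame.
#' @param model One of `"target_only"`, `"mixture"`, `"nbm"`, `"im"`.
#' @param params Model parameters, see Details.
#' @param seed Optional integer seed.
#' @return A `swap_responses` data frame: the trials plus `response`,
#'   `ground_truth_selected` and `error_to_target`.
#' @export
simulate_responses <- function(trials, model = c("target_only", "mixture", "nbm", "im"),
                               params, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(trials, "swap_trials"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(trials)
  rp <- report_features(trials)
  N <- ncol(rp)
  tgt <- trials$target_index
  tgt_rep <- rp[cbind(seq_len(n), tgt)]

  draw_error <- function(m, params) {
    err_kind <- if (is.null(params$error)) "von_mises" else params$error
    switch(err_kind,
      von_mises = vm_sample(m, 0, params$kappa),
      wrapped_laplace = wrapped_laplace_sample(m, 0, params$rate),
      stop("unknown error distribution: ", err_kind))
  }

  if (model == "target_only") {
    if (is.null(params$kappa) || params$kappa < 0) stop("target_only needs kappa >= 0")
    response <- wrap_angle(tgt_rep + draw_error(n, params))
    selected <- tgt
  } else if (model == "mixture") {
    w <- c(params$p_target, params$p_nontarget, params$p_uniform)
    if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("mixture needs p_target, p_nontarget, p_uniform summing to 1")
    }
    comp <- sample.int(3L, n, replace = TRUE, prob = w)
    selected <- tgt
    offs <- sample.int(N - 1L, n, replace = TRUE)   # uniform among non-targets
    nt_pick <- ((tgt - 1L + offs) %% N) + 1L
    selected[comp == 2L] <- nt_pick[comp == 2L]
    selected[comp == 3L] <- NA_integer_
    centre <- rp[cbind(seq_len(n), ifelse(is.na(selected), 1L, selected))]
    response <- wrap_angle(centre + draw_error(n, params))
    response[comp == 3L] <- stats::runif(sum(comp == 3L), -pi, pi)
  } else if (model == "nbm") {
    sim <- nbm_simulate(trials, params)
    response <- sim$response
    selected <- sim$selected
  } else {  # im
    sim <- im_simulate(trials, params)
    response <- sim$response
    selected <- sim$selected
  }

  out <- trials
  out$response <- wrap_angle(response)
  out$ground_truth_selected <- selected
  out$error_to_target <- circ_dist(out$response, tgt_rep)
  class(out) <- c("swap_responses", class(trials))
  out
}

#' Read and write trial/response tables
#'
#' Tables are stored as plain TSV with angles in radians (6 decimal places),
#' one row per trial, matching the column layout of [generate_trials()].
#'
#' @param x A `swap_trials`/`swap_responses` data frame.
#' @param path File path.
#' @return `read_trials()` returns the table with class restored from its
#'   columns.
#' @export
write_trials <- function(x, path) {
  y <- as.data.frame(x)
  num <- vapply(y, is.double, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, 6))
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  y <- utils::read.delim(path, stringsAsFactors = FALSE)
  cls <- if ("response" %in% names(y)) c("swap_responses", "swap_trials", "data.frame")
         else c("swap_trials", "data.frame")
  class(y) <- cls
  y
}
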