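#' Error pools from a report condition
#'
#' Collects the signed response errors (deviation from the target's report
#' feature) per condition level. These pools feed the parameter-free Monte
#' Carlo swap predictor: errors observed when a feature dimension is
#' *reported* stand in for memory variability of the same dimension when it
#' is used as *cue*.
#'
#' @param responses A `swap_responses` data frame from the condition where
#'   the manipulated dimension was reported.
#' @return Named list, one numeric vector of errors per level.
#' @export
build_error_pools <- function(responses) {
  split(response_errors(responses), responses$level)
}

#' Parameter-free Monte Carlo prediction of swap frequency
#'
#' For each trial, draws one error per item (with replacement) from the
#' matching level's pool, adds it to the items' cue features to emulate
#' memory variability in the cue dimension, and flags a swap when the
#' perturbed cue feature nearest the cue value belongs to a non-target.
#' Repeating this `n_iter` times per trial and averaging yields the
#' predicted swap proportion per level — no free parameters are involved.
#' Errors are drawn independently across items and iterations; ties at the
#' nearest item are resolved in favour of the target (they have measure zero
#' for continuously distributed errors).
#'
#' @param trials A `swap_trials` data frame (the condition whose swap rate
#'   is being predicted; its responses, if any, are ignored).
#' @param pools Named list of error vectors per level, see
#'   [build_error_pools()].
#' @param n_iter Monte Carlo iterations per trial.
#' @param seed Optional integer seed.
#' @param chunk Iterations processed per vectorized block (memory knob).
#' @return Data frame with `level`, `predicted_proportion`, `n_trials`,
#'   `n_iter`, and the Monte Carlo standard error `mc_se` of the mean over
#'   trials.
#' @export
predict_swaps <- function(trials, pools, n_iter = 1000L, seed = NULL,
                          chunk = 250L) {
  stopifnot(inherits(trials, "swap_trials"), n_iter >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  miss <- setdiff(unique(trials$level), names(pools))
  if (length(miss)) stop("missing error pool for level(s): ", paste(miss, collapse = ", "))
  if (any(vapply(pools, length, integer(1)) == 0L)) stop("empty error pool")

  out <- lapply(unique(trials$level), function(lv) {
    sub <- trials[trials$level == lv, , drop = FALSE]
    pool <- pools[[lv]]
    cf <- cue_features(sub)
    n <- nrow(cf); N <- ncol(cf)
    cue_val <- cf[cbind(seq_len(n), sub$target_index)]
    d_base <- cf - cue_val                  # perturbed by errors below
    tgt_col <- cbind(seq_len(n), sub$target_index)
    swap_mean_per_trial <- numeric(n)
    done <- 0L
    while (done < n_iter) {
      B <- min(chunk, n_iter - done)
      # stack B iterations: (n*B) x N error draws
      err <- matrix(sample(pool, n * B * N, replace = TRUE), n * B, N)
      pert <- abs(wrap_angle(err + d_base[rep(seq_len(n), B), , drop = FALSE]))
      to_tgt <- pert[cbind(seq_len(n * B), rep(sub$target_index, B))]
      swap <- row_mins(pert) < to_tgt
      swap_mean_per_trial <- swap_mean_per_trial +
        rowsum(as.numeric(swap), rep(seq_len(n), B))[, 1]
      done <- done + B
    }
    swap_mean_per_trial <- swap_mean_per_trial / n_iter
    data.frame(level = lv,
               predicted_proportion = mean(swap_mean_per_trial),
               n_trials = n, n_iter = n_iter,
               mc_se = stats::sd(swap_mean_per_trial) / sqrt(n))
  })
  do.call(rbind, out)
}

# row minima without extra dependencies
row_mins <- function(m) {
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}
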