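#' Nearest-item swap classification
#'
#' Classifies each response as a swap error iff it is strictly closer (in
#' absolute circular distance) to some non-target's report feature than to
#' the target's. Exact ties are resolved in favour of the target, which is
#' conservative with respect to swap claims and has probability zero under
#' continuously distributed features. The heuristic is reliable when report
#' features are well separated relative to report noise.
#'
#' @param responses A `swap_responses` data frame.
#' @return A list: `labels` (logical per trial), `proportion`, `n_trials`,
#'   `nearest_item` (1-based index of the item nearest to each response) and
#'   `by_level` (data frame of per-level proportions).
#' @export
nearest_item_swaps <- function(responses) {
  stopifnot(inherits(responses, "swap_responses"), nrow(responses) >= 1)
  rp <- report_features(responses)
  n <- nrow(rp)
  dup <- vapply(seq_len(n), function(i) anyDuplicated(rp[i, ]) > 0, logical(1))
  if (any(dup)) stop("duplicate report features within a trial: nearest item undefined")
  adist <- abs(wrap_angle(responses$response - rp))
  nearest <- max.col(-adist, ties.method = "first")
  to_target <- adist[cbind(seq_len(n), responses$target_index)]
  # swap iff some non-target is strictly nearer than the target
  is_swap <- unname(apply(adist, 1L, min) < to_target)
  by_level <- stats::aggregate(is_swap, list(level = responses$level), mean)
  names(by_level)[2] <- "proportion"
  by_level$n_trials <- as.vector(table(responses$level)[by_level$level])
  list(labels = is_swap, proportion = mean(is_swap), n_trials = n,
       nearest_item = nearest, by_level = by_level)
}

#' Fit the three-component response mixture
#'
#' Maximum-likelihood fit of the standard mixture of a von Mises component
#' centred on the target's report feature, von Mises components centred on
#' each non-target (sharing one non-target weight, split equally), and a
#' circular-uniform guessing component:
#' \deqn{p(x) = p_T f(x - r_t; \kappa) + \frac{p_N}{N-1} \sum_j f(x - r_j;
#'   \kappa) + \frac{p_U}{2\pi}.}
#' Optimization is by expectation-maximization with the concentration updated
#' through the Bessel-ratio inversion, run from several dispersed starting
#' points; the best converged run is returned.
#'
#' @param responses A `swap_responses` data frame (mixed set sizes allowed).
#' @param n_restarts Number of dispersed EM starts.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per start.
#' @return A `mixture_estimate` list: `p_target`, `p_nontarget`, `p_uniform`,
#'   `kappa`, `loglik`, `converged`, `n_trials`. With purely uniform data the
#'   concentration is unidentifiable and reported as fitted.
#' @export
fit_mixture <- function(responses, n_restarts = 10L, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(responses, "swap_responses"))
  err_t <- response_errors(responses)
  dev_nt <- nontarget_deviations(responses)   # n x (N-1)
  n <- length(err_t)
  Nn <- ncol(dev_nt)

  em_run <- function(p_t, p_n, p_u, kappa) {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      f_t <- vm_pdf(err_t, 0, kappa)
      f_nt <- matrix(vm_pdf(dev_nt, 0, kappa), n, Nn)
      mix_t <- p_t * f_t
      mix_nt <- (p_n / Nn) * f_nt
      mix_u <- p_u / (2 * pi)
      tot <- mix_t + rowSums(mix_nt) + mix_u
      ll <- sum(log(tot))
      g_t <- mix_t / tot
      g_nt <- mix_nt / tot
      g_u <- mix_u / tot
      p_t <- mean(g_t); p_n <- mean(rowSums(g_nt)); p_u <- mean(g_u)
      wsum <- sum(g_t) + sum(g_nt)
      if (wsum > 1e-10) {
        cbar <- (sum(g_t * cos(err_t)) + sum(g_nt * cos(dev_nt))) / wsum
        sbar <- (sum(g_t * sin(err_t)) + sum(g_nt * sin(dev_nt))) / wsum
        kappa <- a1_inv(sqrt(cbar^2 + sbar^2))
      }
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
      ll_old <- ll
    }
    list(p_target = p_t, p_nontarget = p_n, p_uniform = p_u, kappa = kappa,
         loglik = ll_old, converged = converged)
  }

  starts <- list(c(0.8, 0.1, 0.1, 8), c(0.5, 0.4, 0.1, 4), c(0.3, 0.2, 0.5, 2))
  while (length(starts) < n_restarts) {
    w <- stats::runif(3); w <- w / sum(w)
    starts[[length(starts) + 1L]] <- c(w, exp(stats::runif(1, log(0.5), log(50))))
  }
  best <- NULL
  for (s in starts[seq_len(n_restarts)]) {
    fit <- em_run(s[1], s[2], s[3], s[4])
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik)) best <- fit
  }
  best$n_trials <- n
  if (!best$converged) warning("mixture EM did not converge in any restart at tol")
  class(best) <- "mixture_estimate"
  best
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("<mixture_estimate> p_target %.3f  p_nontarget %.3f  p_uniform %.3f  kappa %.2f\n",
              x$p_target, x$p_nontarget, x$p_uniform, x$kappa))
  cat(sprintf("  loglik %.2f on %d trials%s\n", x$loglik, x$n_trials,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

# Resample a causally inert replacement value for one non-target's report
# feature, respecting the minimum separation to the remaining report
# features. Returns n_iter draws for one trial.
resample_inert_values <- function(other_features, min_sep, n_iter) {
  if (min_sep <= 0) return(stats::runif(n_iter, -pi, pi))
  excl <- length(other_features) * 2 * min_sep / (2 * pi)
  if (excl >= 1) {
    # conservative bound; actual free volume may still exist if arcs overlap
    acc <- 0.02
  } else acc <- 1 - excl
  out <- numeric(n_iter)
  filled <- 0L
  tries <- 0L
  while (filled < n_iter) {
    m <- ceiling((n_iter - filled) / max(acc, 0.02)) + 8L
    cand <- stats::runif(m, -pi, pi)
    d <- abs(wrap_angle(outer(cand, other_features, `-`)))
    ok <- rowSums(d < min_sep) == 0L
    take <- which(ok)[seq_len(min(sum(ok), n_iter - filled))]
    if (length(take)) {
      out[filled + seq_along(take)] <- cand[take]
      filled <- filled + length(take)
    }
    tries <- tries + 1L
    if (tries > 200L && filled == 0L) stop("resampling constraints infeasible")
  }
  out
}

#' Expected non-target deviation profile under the no-swap null
#'
#' Minimum separations between item features make the distribution of
#' response deviations from non-target features non-uniform even when
#' non-targets have no influence on responses (responses clustered on the
#' target are then also kept away from non-targets, producing a central dip).
#' This randomization estimates that null distribution: one non-target's
#' report feature per trial is replaced by a fresh value respecting the
#' minimum-separation constraints, the deviation of the real response from
#' this causally inert value is recorded, and the procedure is repeated
#' `n_iter` times per trial. The expected histogram is subtracted from the
#' observed histogram of deviations so that structure left over indicates a
#' real influence of non-targets; the same draws yield the expected mean
#' absolute deviation.
#'
#' @param responses A `swap_responses` data frame.
#' @param min_sep_rep Minimum separation of report features (radians);
#'   defaults to the value stored in the trial config.
#' @param n_iter Randomization iterations per trial.
#' @param n_bins Number of histogram bins on \eqn{(-\pi, \pi]} (odd counts
#'   centre a bin on zero, where swap mass peaks).
#' @param seed Optional integer seed.
#' @return A `deviation_profile` list: `bin_edges`, `bin_centers`, `observed`,
#'   `expected`, `corrected` (densities; corrected = observed - expected),
#'   `mad_observed`, `mad_expected`, `n_trials`, `n_iter`.
#' @export
expected_nontarget_profile <- function(responses, min_sep_rep = NULL,
                                       n_iter = 1000L, n_bins = 37L, seed = NULL) {
  stopifnot(inherits(responses, "swap_responses"), n_iter >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- trial_config(responses)
  if (is.null(min_sep_rep)) {
    if (is.null(cfg)) stop("min_sep_rep not supplied and no config attached")
    min_sep_rep <- cfg$min_sep_rep
  }
  rp <- report_features(responses)
  n <- nrow(rp)
  N <- ncol(rp)
  exp_dev <- vector("list", n)
  for (i in seq_len(n)) {
    nts <- setdiff(seq_len(N), responses$target_index[i])
    drop_j <- nts[((i - 1L) %% length(nts)) + 1L]  # deterministic rotation over trials
    keep <- setdiff(seq_len(N), drop_j)
    vals <- resample_inert_values(rp[i, keep], min_sep_rep, n_iter)
    exp_dev[[i]] <- wrap_angle(responses$response[i] - vals)
  }
  exp_dev <- unlist(exp_dev)
  obs_dev <- as.vector(nontarget_deviations(responses))

  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  width <- diff(edges)[1]
  hist_density <- function(v) {
    h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins),
                  nbins = n_bins)
    h / (length(v) * width)
  }
  obs_h <- hist_density(obs_dev)
  exp_h <- hist_density(exp_dev)
  structure(list(bin_edges = edges, bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 observed = obs_h, expected = exp_h, corrected = obs_h - exp_h,
                 mad_observed = circ_mad(obs_dev), mad_expected = circ_mad(exp_dev),
                 n_trials = n, n_iter = n_iter),
            class = "deviation_profile")
}

#' @export
print.deviation_profile <- function(x, ...) {
  cat(sprintf("<deviation_profile> %d trials x %d iterations, %d bins\n",
              x$n_trials, x$n_iter, length(x$observed)))
  cat(sprintf("  MAD observed %.4f  expected %.4f  (pi/2 = %.4f)\n",
              x$mad_observed, x$mad_expected, pi / 2))
  invisible(x)
}

#' Resultant-vector estimate of mixture weights
#'
#' Distribution-free estimation of the target / non-target / uniform mixture
#' weights from pooled (group-level) data, using the fact that the resultant
#' of a mixture is the weighted sum of the component resultants. For each
#' harmonic \eqn{k}, the cosine moments of response deviations from the
#' target and (pooled) from the non-targets are linear in
#' \eqn{u_k = p_T \phi_k} and \eqn{v_k = p_N \phi_k}, where \eqn{\phi_k} is
#' the unknown error distribution's k-th Fourier coefficient. The
#' cross-contamination coefficients of that linear system are the moments of
#' the target/non-target separation distribution, computed directly from the
#' trial arrays — this is the closed-form counterpart of the randomization
#' correction for minimum feature separations. Solving the per-harmonic
#' systems reconstructs the non-uniform parts \eqn{p_T(\phi - 1/2\pi)} and
#' \eqn{p_N(\phi - 1/2\pi)}; integrating them over an antipodal window where
#' the error density is assumed negligible identifies the absolute weights
#' without any parametric assumption on the error shape.
#'
#' Estimates are unconstrained: a negative non-target weight is a legitimate
#' outcome indicating strong evidence for no swaps. Weights sum to one by
#' construction. The method needs more data than parametric fits; apply it
#' to pooled data.
#'
#' @param responses A `swap_responses` data frame (pooled across a level).
#' @param n_harmonics Number of cosine harmonics used.
#' @param window_start Start (radians) of the antipodal window
#'   \eqn{[w_0, \pi]} over which the error density is treated as zero.
#' @return A `resultant_estimate` list: `p_target`, `p_nontarget`,
#'   `p_uniform`, `component_resultant` (the error distribution's resultant
#'   length), `n_trials`, `unreliable` flag.
#' @export
resultant_vector_estimate <- function(responses, n_harmonics = 15L,
                                      window_start = 3 * pi / 4) {
  stopifnot(inherits(responses, "swap_responses"))
  err_t <- response_errors(responses)
  dev_nt <- as.vector(nontarget_deviations(responses))
  rp <- report_features(responses)
  n <- nrow(rp)
  N <- ncol(rp)

  # separation moments from the arrays: target vs non-target (C_k) and
  # between distinct non-targets (G_k)
  nt_rep <- nontarget_report_features(responses)
  tgt_rep <- rp[cbind(seq_len(n), responses$target_index)]
  sep_tn <- as.vector(wrap_angle(nt_rep - tgt_rep))
  sep_nn <- if (N >= 3) {
    pr <- utils::combn(N - 1L, 2)
    as.vector(wrap_angle(nt_rep[, pr[1, ], drop = FALSE] - nt_rep[, pr[2, ], drop = FALSE]))
  } else numeric(0)

  ks <- seq_len(n_harmonics)
  u <- numeric(n_harmonics)
  v <- numeric(n_harmonics)
  for (k in ks) {
    mT <- mean(cos(k * err_t))
    mN <- mean(cos(k * dev_nt))
    Ck <- mean(cos(k * sep_tn))
    Gk <- if (length(sep_nn)) mean(cos(k * sep_nn)) else 0
    beta_k <- (1 + (N - 2) * Gk) / (N - 1)
    A <- matrix(c(1, Ck, Ck, beta_k), 2, 2, byrow = TRUE)
    sol <- tryCatch(solve(A, c(mT, mN)), error = function(e) c(NA_real_, NA_real_))
    u[k] <- sol[1]; v[k] <- sol[2]
  }
  unreliable <- anyNA(u) || anyNA(v) || abs(u[1]) < 0.02
  w0 <- window_start
  weight_from <- function(coefs) 2 * sum(coefs * sin(ks * w0) / ks) / (pi - w0)
  p_t <- weight_from(u)
  p_n <- weight_from(v)
  p_u <- 1 - p_t - p_n
  L <- if (abs(p_t) > 1e-6) u[1] / p_t else NA_real_
  structure(list(p_target = p_t, p_nontarget = p_n, p_uniform = p_u,
                 component_resultant = L, n_trials = n, unreliable = unreliable),
            class = "resultant_estimate")
}

#' @export
print.resultant_estimate <- function(x, ...) {
  cat(sprintf("<resultant_estimate> p_target %.3f  p_nontarget %.3f  p_uniform %.3f\n",
              x$p_target, x$p_nontarget, x$p_uniform))
  cat(sprintf("  component resultant length %.3f on %d pooled trials%s\n",
              x$component_resultant, x$n_trials,
              if (x$unreliable) "  (flagged unreliable)" else ""))
  invisible(x)
}

#' Per-level swap estimates
#'
#' Convenience driver applying one estimator per condition level and
#' returning a tidy table.
#'
#' @param responses A `swap_responses` data frame.
#' @param method `"nearest_item"`, `"mixture"` or `"resultant_vector"`.
#' @param ... Passed to the underlying estimator.
#' @return Data frame with columns `method`, `level`, `proportion`,
#'   `n_trials`.
#' @export
estimate_swaps <- function(responses,
                           method = c("nearest_item", "mixture", "resultant_vector"),
                           ...) {
  method <- match.arg(method)
  levels_ <- unique(responses$level)
  rows <- lapply(levels_, function(lv) {
    sub <- responses[responses$level == lv, , drop = FALSE]
    attr(sub, "config") <- trial_config(responses)
    class(sub) <- class(responses)
    p <- switch(method,
      nearest_item = nearest_item_swaps(sub)$proportion,
      mixture = fit_mixture(sub, ...)$p_nontarget,
      resultant_vector = resultant_vector_estimate(sub, ...)$p_nontarget)
    data.frame(method = method, level = lv, proportion = p, n_trials = nrow(sub))
  })
  do.call(rbind, rows)
}

#' Non-target MAD by cue distance
#'
#' For each non-target, computes the mean absolute deviation of responses
#' from that non-target's report feature, binned by the non-target's absolute
#' cue-feature distance from the cued (target) value. MADs below the no-swap
#' reference \eqn{\pi/2} (exact when report features are unconstrained and
#' uniform) indicate swaps concentrated at that cue distance.
#'
#' The default binning adapts to the spatial layout: for fixed/rotated
#' equispaced arrays the occupied distances are discrete (60, 120, 180
#' degrees for six items) and each becomes its own bin; otherwise seven
#' equal-width bins spanning 34 to 180 degrees are used.
#'
#' @param responses A `swap_responses` data frame.
#' @param bins Optional numeric vector of bin edges in radians (increasing).
#' @return Data frame with `bin`, `lo_deg`, `hi_deg`, `mad`, `n`
#'   (`mad` is `NA` for empty bins).
#' @export
mad_by_distance <- function(responses, bins = NULL) {
  stopifnot(inherits(responses, "swap_responses"))
  cfg <- trial_config(responses)
  dist_ <- as.vector(nontarget_cue_distances(responses))
  dev <- as.vector(nontarget_deviations(responses))
  if (is.null(bins)) {
    if (!is.null(cfg) && cfg$spatial_mode %in% c("fixed", "rotated")) {
      # discrete distances: snap to multiples of the equispaced arc
      step <- 2 * pi / cfg$set_size
      lv <- sort(unique(round(dist_ / step))) * step
      bins <- c(lv - step / 4, max(lv) + step / 4)
    } else {
      bins <- seq(34, 180, length.out = 8) * pi / 180
    }
  }
  idx <- findInterval(dist_, bins, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx <= (length(bins) - 1L)
  out <- data.frame(bin = seq_len(length(bins) - 1L),
                    lo_deg = bins[-length(bins)] * 180 / pi,
                    hi_deg = bins[-1] * 180 / pi)
  out$n <- as.vector(tabulate(idx[keep], nbins = nrow(out)))
  out$mad <- vapply(seq_len(nrow(out)), function(b) {
    d <- dev[keep & idx == b]
    if (length(d)) circ_mad(d) else NA_real_
  }, numeric(1))
  out
}
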