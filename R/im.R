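# Interference model: responses arise from cue-based retrieval (items
# activated by an exponential function of cue-feature distance), cue-
# independent retrieval (equal activation of all items), and uniform
# background noise; one item may sit in the focus of attention, which boosts
# its report precision and damps the noise components when it is the target.

#' Interference model parameters
#'
#' @param kappa Report precision (concentration) for items outside the focus
#'   of attention.
#' @param kappa_f Report precision for the target when it is in the focus.
#' @param A_a Weight of cue-independent retrieval (>= 0; the partial model
#'   variant fixes it at zero).
#' @param A_b Weight of the uniform background-noise component (>= 0).
#' @param s Width (radians) of the exponential similarity gradient
#'   \eqn{\exp(-|d|/s)} that governs cue-based item selection.
#' @param r Proportional reduction of `A_a` and `A_b` when the target is in
#'   the focus of attention, in `[0, 1]`.
#' @param p_focus_target Probability that the focused item is the target;
#'   defaults to 1/set size (no item is privileged by simultaneous
#'   presentation) and is filled in from the trials when `NULL`.
#' @return An `im_params` list. The cue-based retrieval weight of the target
#'   is fixed at one (its cue distance is zero).
#' @export
im_params <- function(kappa, kappa_f, A_a = 0, A_b = 0.1, s = 0.3, r = 1,
                      p_focus_target = NULL) {
  stopifnot(kappa > 0, kappa_f > 0, A_a >= 0, A_b >= 0, s > 0, r >= 0, r <= 1)
  structure(list(kappa = kappa, kappa_f = kappa_f, A_a = A_a, A_b = A_b,
                 s = s, r = r, p_focus_target = p_focus_target),
            class = "im_params")
}

#' @export
print.im_params <- function(x, ...) {
  cat(sprintf("<im_params> kappa %.2f  kappa_f %.2f  A_a %.3f  A_b %.3f  s %.3f  r %.2f\n",
              x$kappa, x$kappa_f, x$A_a, x$A_b, x$s, x$r))
  invisible(x)
}

# per-trial component weights for the two focus states; rows are trials.
# Returns list(w = cue-based weights (n x N), pf = P(target focused)).
im_weights <- function(trials, params) {
  cf <- cue_features(trials)
  n <- nrow(cf); N <- ncol(cf)
  cue_val <- cf[cbind(seq_len(n), trials$target_index)]
  d <- abs(wrap_angle(cf - cue_val))
  w <- exp(-d / params$s)
  pf <- if (is.null(params$p_focus_target)) 1 / N else params$p_focus_target
  list(w = w, pf = pf, n = n, N = N)
}

#' Interference model response density
#'
#' Mixture density over responses for each trial, marginalized over whether
#' the target is in the focus of attention:
#' \deqn{p_f(x) = \frac{\sum_j (w_j + a_j) f(x; r_j, \kappa_j) + b/2\pi}{\sum_j (w_j + a_j) + b}}
#' with cue-based weights \eqn{w_j = \exp(-|d_j|/s)} (the target's distance
#' is zero so its weight is one), cue-independent weight \eqn{a_j = A_a}
#' (times `r` in the target-focused state), background \eqn{b = A_b} (times
#' `r` likewise), and report concentration `kappa` (`kappa_f` for the target
#' in the focused state). The `"partial"` variant forces `A_a = 0`.
#'
#' @param trials A `swap_trials` data frame (single cue dimension).
#' @param params [im_params()].
#' @param variant `"full"` or `"partial"`.
#' @param at Angles at which to evaluate: either a vector (evaluated for
#'   every trial, returning a matrix trials x angles) or the string
#'   `"response"` to evaluate at each trial's observed response.
#' @return Density matrix (trials x angles) or vector when `at =
#'   "response"`.
#' @export
im_response_density <- function(trials, params, variant = c("full", "partial"),
                                at = "response") {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "im_params"))
  A_a <- if (variant == "partial") 0 else params$A_a
  iw <- im_weights(trials, params)
  rp <- report_features(trials)
  n <- iw$n; N <- iw$N
  ti <- cbind(seq_len(n), trials$target_index)

  eval_state <- function(x_mat, focused) {
    # x_mat: n x P matrix of evaluation points
    a <- if (focused) A_a * params$r else A_a
    b <- if (focused) params$A_b * params$r else params$A_b
    Z <- rowSums(iw$w) + N * a + b
    dens <- matrix(b / (2 * pi), n, ncol(x_mat))
    for (j in seq_len(N)) {
      kj <- rep(params$kappa, n)
      if (focused) kj[trials$target_index == j] <- params$kappa_f
      dens <- dens + (iw$w[, j] + a) *
        exp(kj * (cos(x_mat - rp[, j]) - 1)) /
        (2 * pi * besselI(kj, 0, expon.scaled = TRUE))
    }
    dens / Z
  }

  x_mat <- if (identical(at, "response")) {
    stopifnot("response" %in% names(trials))
    matrix(trials$response, n, 1L)
  } else {
    matrix(at, n, length(at), byrow = TRUE)
  }
  out <- iw$pf * eval_state(x_mat, TRUE) + (1 - iw$pf) * eval_state(x_mat, FALSE)
  if (identical(at, "response")) as.vector(out) else out
}

#' Interference model log-likelihood
#'
#' Sum of log response densities for one homogeneous cell (a single cue
#' dimension and condition level); the model is fit to each report condition
#' and level independently, so mixed cells are an error.
#'
#' @param responses A `swap_responses` data frame restricted to one cell.
#' @param params [im_params()].
#' @param variant `"full"` or `"partial"`.
#' @return Scalar log-likelihood.
#' @export
im_loglik <- function(responses, params, variant = c("full", "partial")) {
  if (length(unique(responses$level)) > 1L || length(unique(responses$cue_dim)) > 1L) {
    stop("im_loglik expects a single (cue dimension x level) cell")
  }
  d <- im_response_density(responses, params, variant, at = "response")
  sum(log(pmax(d, 1e-300)))
}

# simulate responses from the interference model (used by
# simulate_responses(model = "im"))
im_simulate <- function(trials, params) {
  stopifnot(inherits(params, "im_params"))
  iw <- im_weights(trials, params)
  rp <- report_features(trials)
  n <- iw$n; N <- iw$N
  focused <- stats::runif(n) < iw$pf
  a <- ifelse(focused, params$A_a * params$r, params$A_a)
  b <- ifelse(focused, params$A_b * params$r, params$A_b)
  probs <- cbind(iw$w + a, b)          # n x (N+1); last column = uniform
  pick <- numeric(n)
  u <- stats::runif(n) * rowSums(probs)
  cum <- t(apply(probs, 1, cumsum))
  pick <- max.col(cum >= u, ties.method = "first")
  selected <- ifelse(pick > N, NA_integer_, pick)
  kappa_i <- ifelse(!is.na(selected) & focused & selected == trials$target_index,
                    params$kappa_f, params$kappa)
  response <- stats::runif(n, -pi, pi)
  hit <- which(!is.na(selected))
  if (length(hit)) {
    centres <- rp[cbind(hit, selected[hit])]
    err <- numeric(length(hit))
    for (kv in unique(kappa_i[hit])) {
      sel <- kappa_i[hit] == kv
      err[sel] <- vm_sample(sum(sel), 0, kv)
    }
    response[hit] <- wrap_angle(centres + err)
  }
  list(response = response, selected = selected)
}

#' Fit the interference model per cell
#'
#' Fits the six interference-model parameters (five for the `"partial"`
#' variant, which fixes the cue-independent weight at zero) to each
#' (cue dimension x level) cell independently by Nelder-Mead on transformed
#' parameters, and aggregates log-likelihood and parameter counts across
#' cells. With three levels and both report conditions this gives 36 free
#' parameters for the full variant and 30 for the partial one.
#'
#' @param responses A `swap_responses` data frame.
#' @param variant `"full"` or `"partial"`.
#' @param n_restarts Starting points per cell.
#' @param maxit Nelder-Mead iteration cap.
#' @return A `swap_fit` whose `params` is the list of per-cell fits
#'   (`$cells`), with aggregate `loglik`, `n_params`, `aic`, `bic`.
#' @export
fit_im <- function(responses, variant = c("full", "partial"),
                   n_restarts = 3L, maxit = 500L) {
  variant <- match.arg(variant)
  cells <- split(seq_len(nrow(responses)),
                 list(responses$cue_dim, responses$level), drop = TRUE)
  fits <- list()
  total_ll <- 0
  total_k <- 0L
  all_conv <- TRUE
  for (nm in names(cells)) {
    sub <- responses[cells[[nm]], , drop = FALSE]
    attr(sub, "config") <- trial_config(responses)
    class(sub) <- class(responses)
    k_free <- if (variant == "full") 6L else 5L
    unpack <- function(th) {
      if (variant == "full") {
        im_params(kappa = exp(th[1]), kappa_f = exp(th[1]) + exp(th[2]),
                  A_a = exp(th[3]), A_b = exp(th[4]), s = exp(th[5]),
                  r = stats::plogis(th[6]))
      } else {
        im_params(kappa = exp(th[1]), kappa_f = exp(th[1]) + exp(th[2]),
                  A_a = 0, A_b = exp(th[3]), s = exp(th[4]),
                  r = stats::plogis(th[5]))
      }
    }
    negll <- function(th) {
      if (any(!is.finite(th)) || any(abs(th) > 15)) return(1e10)
      -im_loglik(sub, unpack(th), variant)
    }
    starts <- if (variant == "full") {
      list(c(log(4), log(4), log(0.05), log(0.1), log(0.3), 0),
           c(log(10), log(2), log(0.3), log(0.3), log(0.8), 1),
           c(log(2), log(8), log(0.01), log(0.05), log(0.15), -1))
    } else {
      list(c(log(4), log(4), log(0.1), log(0.3), 0),
           c(log(10), log(2), log(0.3), log(0.8), 1),
           c(log(2), log(8), log(0.05), log(0.15), -1))
    }
    best <- NULL
    conv <- FALSE
    for (s0 in starts[seq_len(min(n_restarts, length(starts)))]) {
      opt <- stats::optim(s0, negll, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-8))
      conv <- conv || opt$convergence == 0
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    all_conv <- all_conv && conv
    fits[[nm]] <- fit_result(model = paste0("im_", variant),
                             params = unpack(best$par), loglik = -best$value,
                             n_params = k_free, n_obs = nrow(sub),
                             converged = conv)
    total_ll <- total_ll + fits[[nm]]$loglik
    total_k <- total_k + k_free
  }
  out <- fit_result(model = paste0("im_", variant), params = list(cells = fits),
                    loglik = total_ll, n_params = total_k,
                    n_obs = nrow(responses), converged = all_conv)
  out
}
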