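# Neural binding model: population coding with Poisson spikes, where each
# spike is one noisy von Mises sample of an item's feature values. All spikes
# carry location information; a per-level fraction (the conjunction coding
# parameter) additionally carries the manipulated feature. Recall is ML
# decoding (resultant direction) of each item's features; the item whose
# decoded cue feature lands closest to the cue is selected and its decoded
# report feature is the response. Swaps arise solely from cue-dimension
# decode variability.

#' Neural binding model parameters
#'
#' @param kappa_loc Concentration of the location tuning/sample noise.
#' @param kappa_feat Concentration of the manipulated-feature (orientation /
#'   direction) sample noise.
#' @param gain Mean total spike count per memory array (shared across items).
#' @param conjunction Named numeric vector in `[0,1]`: per condition level,
#'   the fraction of spikes that carry the manipulated feature. All spikes
#'   carry location.
#' @return An `nbm_params` list.
#' @export
nbm_params <- function(kappa_loc, kappa_feat, gain, conjunction) {
  stopifnot(kappa_loc > 0, kappa_feat > 0, gain > 0,
            all(conjunction >= 0), all(conjunction <= 1),
            !is.null(names(conjunction)))
  structure(list(kappa_loc = kappa_loc, kappa_feat = kappa_feat,
                 gain = gain, conjunction = conjunction),
            class = "nbm_params")
}

#' @export
print.nbm_params <- function(x, ...) {
  cat(sprintf("<nbm_params> kappa_loc %.2f  kappa_feat %.2f  gain %.1f\n",
              x$kappa_loc, x$kappa_feat, x$gain))
  cat("  conjunction:", paste(sprintf("%s=%.2f", names(x$conjunction), x$conjunction),
                              collapse = "  "), "\n")
  invisible(x)
}

# which feature dimension plays cue/report for a block of trials, and the
# per-item spike-count model implied: total spikes per item are iid
# Poisson(gain/N) (Poisson total + uniform allocation), feature-carrying
# spikes are a Binomial thinning with the conjunction value, hence
# independent Poisson(gain*c/N) by Poisson splitting.
nbm_roles <- function(cue_dim) {
  if (cue_dim == "location") {
    list(cue_uses = "all", rep_uses = "feat")   # report the manipulated feature
  } else {
    list(cue_uses = "feat", rep_uses = "all")   # report location
  }
}

# decode the resultant direction of grouped von Mises samples; groups with
# zero samples decode uniformly
decode_groups <- function(centers, counts, kappa) {
  k <- length(counts)
  total <- sum(counts)
  out <- stats::runif(k, -pi, pi)    # zero-spike decodes
  if (total > 0) {
    gid <- rep.int(seq_len(k), counts)
    smp <- vm_sample(total, 0, kappa)
    cs <- rowsum(cbind(cos(smp), sin(smp)), gid)
    nz <- which(counts > 0)
    out[nz] <- atan2(cs[, 2], cs[, 1])
  }
  wrap_angle(out + centers)
}

#' Simulate trials under the neural binding model
#'
#' Generative simulation of the model: per item, total spikes are
#' Poisson(gain / set size); each spike yields a location sample, and with
#' probability equal to the level's conjunction value also a feature sample.
#' Features are decoded as the resultant direction of their samples (uniform
#' when no samples), the item whose decoded cue value is nearest the cue is
#' selected, and its decoded report value is returned as the response.
#'
#' @param trials A `swap_trials` data frame.
#' @param params An [nbm_params()] object covering every level present.
#' @return List with `response`, `selected` (chosen item), and a
#'   `diagnostics` data frame (per-trial cue-dimension spike counts for
#'   target and selected item, swap flag, Fisher informations).
#' @export
nbm_simulate <- function(trials, params) {
  stopifnot(inherits(params, "nbm_params"))
  miss <- setdiff(unique(trials$level), names(params$conjunction))
  if (length(miss)) stop("no conjunction value for level(s): ", paste(miss, collapse = ", "))
  n <- nrow(trials)
  cf <- cue_features(trials)
  rp <- report_features(trials)
  N <- ncol(cf)
  lambda <- params$gain / N
  cvec <- params$conjunction[trials$level]
  roles <- nbm_roles(trials$cue_dim[1])
  if (length(unique(trials$cue_dim)) > 1)
    stop("nbm_simulate expects a single cue dimension per call")

  m_all <- matrix(stats::rpois(n * N, lambda), n, N)
  m_feat <- matrix(stats::rbinom(n * N, as.vector(m_all), rep(cvec, N)), n, N)

  m_cue <- if (roles$cue_uses == "all") m_all else m_feat
  m_rep <- if (roles$rep_uses == "all") m_all else m_feat
  k_cue <- if (roles$cue_uses == "all") params$kappa_loc else params$kappa_feat
  k_rep <- if (roles$rep_uses == "all") params$kappa_loc else params$kappa_feat

  dec_cue <- matrix(decode_groups(as.vector(cf), as.vector(m_cue), k_cue), n, N)
  dec_rep <- matrix(decode_groups(as.vector(rp), as.vector(m_rep), k_rep), n, N)

  cue_val <- cf[cbind(seq_len(n), trials$target_index)]
  dist_cue <- abs(wrap_angle(dec_cue - cue_val))
  selected <- max.col(-dist_cue, ties.method = "first")
  response <- dec_rep[cbind(seq_len(n), selected)]

  idx_t <- cbind(seq_len(n), trials$target_index)
  idx_s <- cbind(seq_len(n), selected)
  diagnostics <- data.frame(
    level = trials$level,
    is_swap = selected != trials$target_index,
    m_cue_target = m_cue[idx_t],
    m_cue_selected = m_cue[idx_s],
    fisher_cue_target = fisher_info_vm(m_cue[idx_t], k_cue),
    fisher_cue_selected = fisher_info_vm(m_cue[idx_s], k_cue)
  )
  list(response = response, selected = selected, diagnostics = diagnostics)
}

# ---- decode-error densities -------------------------------------------------

# The decode error of m von Mises samples is, conditional on the sample
# resultant length R, von Mises with concentration kappa * R. So the decode
# density is a mixture over the distribution of R under the von Mises
# measure. R draws for every m at once come from a single fixed matrix of
# uniforms pushed through the von Mises quantile function (column-wise
# cumulative resultants), which makes likelihoods deterministic and smooth
# in kappa (common random numbers).
.swapkit_cache <- new.env(parent = emptyenv())

fixed_uniform_matrix <- function(n_draws = 4000L, m_max = 120L) {
  key <- sprintf("unif_%d_%d", n_draws, m_max)
  hit <- get0(key, envir = .swapkit_cache)
  if (!is.null(hit)) return(hit)
  seed_keep <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, envir = globalenv())
  }, add = TRUE)
  set.seed(772001L)
  u <- matrix(stats::runif(n_draws * m_max), n_draws, m_max)
  assign(key, u, envir = .swapkit_cache)
  u
}

# histograms of the sample resultant length R_m for m = 0..m_max von Mises
# samples at concentration kappa; returns list of (R midpoints, weights)
resultant_length_hists <- function(m_max, kappa, n_draws = 4000L,
                                   n_bins = 48L, cdf_grid = 4096L) {
  if (m_max > 120L) stop("spike count truncation exceeds tabulated range")
  u <- fixed_uniform_matrix(n_draws)[, seq_len(max(m_max, 1L)), drop = FALSE]
  x <- -pi + 2 * pi * (seq_len(cdf_grid) - 0.5) / cdf_grid
  cdf <- cumsum(vm_pdf(x, 0, kappa)) * (2 * pi / cdf_grid)
  cdf <- cdf / cdf[cdf_grid]
  th <- matrix(stats::approx(c(0, cdf), c(-pi, x), xout = u, ties = "ordered")$y,
               n_draws, ncol(u))
  Cc <- cos(th[, seq_len(max(m_max, 1L)), drop = FALSE])
  Ss <- sin(th[, seq_len(max(m_max, 1L)), drop = FALSE])
  for (j in seq_len(ncol(Cc))[-1]) {          # column-wise cumulative sums
    Cc[, j] <- Cc[, j - 1L] + Cc[, j]
    Ss[, j] <- Ss[, j - 1L] + Ss[, j]
  }
  Rm <- sqrt(Cc^2 + Ss^2)
  out <- vector("list", m_max + 1L)
  out[[1]] <- list(R = 0, w = 1)                     # m = 0: no information
  for (m in seq_len(m_max)) {
    if (m == 1L) { out[[2]] <- list(R = 1, w = 1); next }
    br <- seq(0, m, length.out = n_bins + 1L)
    cnt <- tabulate(pmin(pmax(findInterval(Rm[, m], br, rightmost.closed = TRUE), 1L),
                         n_bins), n_bins)
    keep <- cnt > 0
    out[[m + 1L]] <- list(R = ((br[-1] + br[-length(br)]) / 2)[keep],
                          w = (cnt / n_draws)[keep])
  }
  out
}

#' Density of the decoding error for m spikes
#'
#' Distribution of the deviation of the maximum-likelihood (resultant
#' direction) decode from the true feature value, for `m` independent von
#' Mises samples with concentration `kappa`. `m = 0` is circular uniform
#' (no information), `m = 1` is exactly von Mises, and for larger `m` the
#' density is the mixture \eqn{f(\theta) = E_R[\mathrm{vm}(\theta; \kappa R)]}
#' over the distribution of the sample resultant length `R` (conditional on
#' `R` the resultant direction is von Mises with concentration
#' \eqn{\kappa R}). `R` is tabulated from a fixed quantile-transformed
#' sample, so repeated evaluations are identical and vary smoothly with
#' `kappa`.
#'
#' @param m Spike count (non-negative integer).
#' @param kappa Concentration (positive).
#' @param grid_size Number of equally spaced evaluation points on
#'   \eqn{(-\pi, \pi]}.
#' @return List with `theta` (grid) and `density`.
#' @export
decode_error_density <- function(m, kappa, grid_size = 720L) {
  if (m < 0) stop("m must be non-negative")
  if (kappa <= 0) stop("kappa must be positive")
  theta <- -pi + 2 * pi * (seq_len(grid_size) - 1L) / grid_size
  list(theta = theta, density = decode_density_rows(m, kappa, theta)[m + 1L, ])
}

# matrix of decode-error densities for m = 0..m_max, evaluated on the grid.
# Each row is the R-mixture of von Mises densities vm(theta; kappa * R),
# exponentially scaled for stability.
decode_density_rows <- function(m_max, kappa, theta) {
  hists <- resultant_length_hists(m_max, kappa)
  out <- matrix(NA_real_, m_max + 1L, length(theta))
  cm1 <- cos(theta) - 1
  for (m in 0:m_max) {
    h <- hists[[m + 1L]]
    # per-R von Mises kernel, exponentially scaled:
    # vm(theta; kR) = e^{kR(cos t - 1)} / (2 pi I0(kR) e^{-kR})
    i0s <- besselI(h$R * kappa, 0, expon.scaled = TRUE)
    num <- exp(outer(h$R * kappa, cm1)) * (h$w / i0s)
    out[m + 1L, ] <- colSums(matrix(num, length(h$R))) / (2 * pi * sum(h$w))
  }
  out
}

# ---- exact likelihood machinery --------------------------------------------

# angle -> grid index in 0..G-1 for the grid theta_g = -pi + 2*pi*g/G
angle_index <- function(x, G) {
  as.integer(round((wrap_angle(x) + pi) * G / (2 * pi))) %% G
}

# survival matrix: SURV[d+1, a+1] = P(|wrap(delta_d + eps)| > a * 2pi/G)
# where eps has probability mass p over the grid (marginal cue decode error)
# and delta_d = -pi + 2*pi*d/G. Built from wrapped prefix sums.
build_survival <- function(p, G) {
  half <- G %/% 2L
  Qc <- c(0, cumsum(p))               # Qc[i + 2] = P(idx <= i), Qc[1] = 0
  arc_mass <- function(lo, hi) {      # inclusive index arcs, mod G
    lo <- lo %% G; hi <- hi %% G
    straddle <- lo > hi
    ifelse(straddle,
           (Qc[G + 1L] - Qc[lo + 1L]) + Qc[hi + 2L],
           Qc[hi + 2L] - Qc[lo + 1L])
  }
  d_idx <- rep(0:(G - 1L), times = half + 1L)
  a_idx <- rep(0:half, each = G)
  # eps in [-delta - a, -delta + a]; index of -delta is (G - d) mod G
  ctr <- (G - d_idx) %% G
  S <- 1 - arc_mass(ctr - a_idx, ctr + a_idx)
  S[a_idx == half] <- 0               # radius pi spans the whole circle
  matrix(pmin(pmax(S, 0), 1), G, half + 1L)
}

#' Response density of the neural binding model for one memory array
#'
#' Exact (to grid resolution) marginal density of the response for a single
#' trial: per-item spike counts are independent Poisson by Poisson splitting,
#' so the density marginalizes counts by truncated enumeration; selection
#' probabilities integrate each item's cue decode-error density against the
#' competitors' survival functions; the response is the selected item's
#' report decode. The density integrates to one on the grid, and the implied
#' per-item selection probabilities sum to one.
#'
#' @param trial One-row `swap_trials` data frame.
#' @param params [nbm_params()].
#' @param grid_size Angular grid resolution.
#' @return List with `theta`, `density` and `selection_prob` (per item).
#' @export
nbm_response_density <- function(trial, params, grid_size = 720L) {
  stopifnot(nrow(trial) == 1L)
  bw <- nbm_block_weights(trial, params, grid_size)
  G <- bw$G
  theta <- -pi + 2 * pi * (0:(G - 1L)) / G
  rp <- report_features(trial)[1, ]
  dens <- numeric(G)
  for (i in seq_along(rp)) {
    sh <- angle_index(theta - rp[i], G) + 1L
    dens <- dens + as.vector(bw$J[i, , drop = FALSE] %*% bw$Frep[, sh, drop = FALSE])
  }
  list(theta = theta, density = dens, selection_prob = bw$sel_prob[1, ])
}

# shared machinery: given a block of trials with a single (cue_dim, level),
# return the per-trial x item x report-count selection weights J and the
# report density table Frep. J sums to ~1 over (item, count) per trial and is
# renormalized exactly.
nbm_block_weights <- function(trials, params, grid_size = 720L, eps_tail = 1e-7) {
  G <- as.integer(grid_size)
  n <- nrow(trials)
  cf <- cue_features(trials)
  N <- ncol(cf)
  lambda <- params$gain / N
  cvl <- params$conjunction[[trials$level[1]]]
  roles <- nbm_roles(trials$cue_dim[1])
  k_cue <- if (roles$cue_uses == "all") params$kappa_loc else params$kappa_feat
  k_rep <- if (roles$rep_uses == "all") params$kappa_loc else params$kappa_feat

  lam_cue <- if (roles$cue_uses == "all") lambda else lambda * cvl
  Mc <- min(max(stats::qpois(1 - eps_tail, lam_cue), 2L), 110L)
  Mr <- min(max(stats::qpois(1 - eps_tail, lambda), 2L), 110L)
  pc <- stats::dpois(0:Mc, lam_cue); pc <- pc / sum(pc)

  theta <- -pi + 2 * pi * (0:(G - 1L)) / G
  Fcue <- decode_density_rows(Mc, k_cue, theta)
  Frep <- decode_density_rows(Mr, k_rep, theta)

  # marginal cue decode-error mass over the grid
  p_marg <- as.vector(pc %*% Fcue) * (2 * pi / G)
  p_marg <- p_marg / sum(p_marg)
  SURV <- build_survival(p_marg, G)

  cue_val <- cf[cbind(seq_len(n), trials$target_index)]
  gdelta <- matrix(angle_index(wrap_angle(cf - cue_val), G), n, N)

  s <- nbm_sel_kernel(gdelta, SURV, Fcue, 2 * pi / G)   # (n*N) x (Mc+1)

  # joint selection x report-count weights
  if (roles$cue_uses == "feat") {
    # cue counts F ~ Poi(lambda c); report counts m = F + G', G' ~ Poi(lambda(1-c))
    pg <- stats::dpois(0:Mr, lambda * (1 - cvl))
    Tm <- matrix(0, Mc + 1L, Mr + 1L)
    for (f in 0:Mc) {
      r <- f:Mr
      if (length(r)) Tm[f + 1L, r + 1L] <- pc[f + 1L] * pg[r - f + 1L]
    }
  } else {
    # cue counts m ~ Poi(lambda); report counts F | m ~ Bin(m, c)
    Tm <- pc * outer(0:Mc, 0:Mr, function(m, r) stats::dbinom(r, m, cvl))
  }
  J <- s %*% Tm                                          # (n*N) x (Mr+1)
  tot <- rowsum(rowSums(J), rep(seq_len(n), each = N))   # per-trial mass
  J <- J / rep(tot[, 1], each = N)
  list(J = J, Frep = Frep, G = G, N = N, n = n,
       sel_prob = matrix(rowSums(J), n, N, byrow = TRUE))
}

# density of observed responses for one homogeneous block; J rows are
# trial-major with item minor (row (t-1)*N + i)
nbm_block_density_at <- function(trials, params, grid_size = 720L) {
  bw <- nbm_block_weights(trials, params, grid_size)
  rp <- report_features(trials)
  n <- bw$n; N <- bw$N; G <- bw$G
  dens <- numeric(n)
  for (i in seq_len(N)) {
    sh <- angle_index(trials$response - rp[, i], G) + 1L
    D <- bw$Frep[, sh, drop = FALSE]                       # (Mr+1) x n
    Ji <- bw$J[(seq_len(n) - 1L) * N + i, , drop = FALSE]  # n x (Mr+1)
    dens <- dens + rowSums(Ji * t(D))
  }
  dens
}

#' Log-likelihood of responses under the neural binding model
#'
#' Sums log response densities over all trials, splitting the data into
#' homogeneous (cue dimension x level) blocks. Tuning concentrations and
#' gain are shared across all blocks; the conjunction value varies by level
#' only.
#'
#' @param responses A `swap_responses` data frame.
#' @param params [nbm_params()].
#' @param grid_size Angular grid resolution.
#' @return Scalar log-likelihood.
#' @export
nbm_loglik <- function(responses, params, grid_size = 720L) {
  if (any(responses$response <= -pi | responses$response > pi)) {
    stop("responses must lie in (-pi, pi]")
  }
  ll <- 0
  for (cd in unique(responses$cue_dim)) {
    for (lv in unique(responses$level)) {
      sub <- responses[responses$cue_dim == cd & responses$level == lv, , drop = FALSE]
      if (!nrow(sub)) next
      attr(sub, "config") <- trial_config(responses)
      class(sub) <- class(responses)
      d <- nbm_block_density_at(sub, params, grid_size)
      ll <- ll + sum(log(pmax(d, 1e-300)))
    }
  }
  ll
}

#' Maximum-likelihood fit of the neural binding model
#'
#' Fits the shared tuning concentrations and gain plus one conjunction value
#' per condition level (six free parameters for a three-level design) by
#' Nelder-Mead search on transformed parameters (log for concentrations and
#' gain, logit for conjunction values), from several dispersed starting
#' points. The likelihood is deterministic, so refits from the returned
#' optimum cannot decrease it.
#'
#' @param responses A `swap_responses` data frame spanning the levels to fit.
#' @param n_restarts Number of starting points.
#' @param grid_size Angular grid resolution for the likelihood.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param init Optional `nbm_params` used as one of the starts.
#' @return A `swap_fit` (see [fit_result()]) with `params` an
#'   [nbm_params()], plus `loglik`, `aic`, `bic`, `converged`.
#' @export
fit_nbm <- function(responses, n_restarts = 3L, grid_size = 720L,
                    maxit = 400L, init = NULL) {
  levels_ <- sort(unique(responses$level))
  L <- length(levels_)
  unpack <- function(th) {
    cj <- stats::plogis(th[3 + seq_len(L)])
    names(cj) <- levels_
    nbm_params(exp(th[1]), exp(th[2]), exp(th[3]), cj)
  }
  negll <- function(th) {
    # box bounds keep concentrations and gain in a numerically safe range
    if (any(!is.finite(th)) || any(abs(th[1:2]) > log(300)) ||
        th[3] < log(0.5) || th[3] > log(400)) return(1e10)
    -nbm_loglik(responses, unpack(th), grid_size)
  }
  starts <- list(
    c(log(8), log(4), log(30), rep(0, L)),
    c(log(15), log(8), log(60), rep(1, L)),
    c(log(4), log(2), log(15), rep(-1, L))
  )
  if (!is.null(init)) {
    starts <- c(list(c(log(init$kappa_loc), log(init$kappa_feat), log(init$gain),
                       stats::qlogis(pmin(pmax(init$conjunction[levels_], 1e-3), 1 - 1e-3)))),
                starts)
  }
  best <- NULL
  any_conv <- FALSE
  for (s in starts[seq_len(min(n_restarts, length(starts)))]) {
    opt <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7))
    any_conv <- any_conv || opt$convergence == 0
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value)) stop("all nbm fit restarts failed")
  fit_result(model = "nbm", params = unpack(best$par), loglik = -best$value,
             n_params = 3L + L, n_obs = nrow(responses),
             converged = any_conv)
}

#' Zero-spike diagnostics of the neural binding model
#'
#' Mass simulation of the model at given parameters, reporting how often the
#' target (or the reported non-target) carried zero spikes in the cue
#' dimension, conditioned on the trial outcome. The unconditional zero-count
#' probability has the closed form \eqn{E[(1-c)^{m_i}] = \exp(-\lambda c)}
#' for a feature cue (with \eqn{\lambda} the per-item spike rate) and
#' \eqn{\exp(-\lambda)} for a location cue, which the simulation estimate is
#' validated against.
#'
#' @param trials A `swap_trials` data frame (the trial population to
#'   simulate; replicate rows for more precision).
#' @param params [nbm_params()].
#' @param n_rep How many times to simulate the population.
#' @param seed Optional seed.
#' @return Data frame per level: conditional probabilities
#'   `p_zero_target_given_swap`, `p_zero_selected_given_swap`,
#'   `p_zero_target_given_correct` (`NA` when the conditioning event never
#'   occurred), the simulated and analytic marginal zero-spike probability,
#'   and counts.
#' @export
zero_spike_conditionals <- function(trials, params, n_rep = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  roles <- nbm_roles(trials$cue_dim[1])
  lambda <- params$gain / trials$set_size[1]
  dg <- do.call(rbind, lapply(seq_len(n_rep), function(r) nbm_simulate(trials, params)$diagnostics))
  out <- lapply(split(dg, dg$level), function(d) {
    lv <- d$level[1]
    lam_c <- if (roles$cue_uses == "all") lambda else lambda * params$conjunction[[lv]]
    swaps <- d[d$is_swap, , drop = FALSE]
    corr <- d[!d$is_swap, , drop = FALSE]
    data.frame(
      level = lv,
      p_zero_target_given_swap = if (nrow(swaps)) mean(swaps$m_cue_target == 0) else NA_real_,
      p_zero_selected_given_swap = if (nrow(swaps)) mean(swaps$m_cue_selected == 0) else NA_real_,
      p_zero_target_given_correct = if (nrow(corr)) mean(corr$m_cue_target == 0) else NA_real_,
      p_zero_marginal_sim = mean(d$m_cue_target == 0),
      p_zero_marginal_analytic = exp(-lam_c),
      n_swap = nrow(swaps), n_trials = nrow(d))
  })
  rownames_out <- do.call(rbind, out)
  rownames(rownames_out) <- NULL
  rownames_out
}

#' Model-based precision by trial outcome
#'
#' Mean cue-dimension Fisher information of the target item and of the
#' selected non-target, conditioned on whether the trial produced a swap,
#' from mass simulation at the given parameters. The unconditional mean has
#' the closed form \eqn{E[m] \kappa A(\kappa)} with \eqn{E[m]} the mean
#' cue-dimension spike count per item.
#'
#' @inheritParams zero_spike_conditionals
#' @return Data frame per level with mean Fisher informations
#'   `fi_target_correct`, `fi_target_swap`, `fi_selected_swap`, the
#'   simulated and analytic unconditional means, and counts.
#' @export
precision_by_outcome <- function(trials, params, n_rep = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  roles <- nbm_roles(trials$cue_dim[1])
  lambda <- params$gain / trials$set_size[1]
  k_cue <- if (roles$cue_uses == "all") params$kappa_loc else params$kappa_feat
  dg <- do.call(rbind, lapply(seq_len(n_rep), function(r) nbm_simulate(trials, params)$diagnostics))
  out <- lapply(split(dg, dg$level), function(d) {
    lv <- d$level[1]
    lam_c <- if (roles$cue_uses == "all") lambda else lambda * params$conjunction[[lv]]
    swaps <- d[d$is_swap, , drop = FALSE]
    corr <- d[!d$is_swap, , drop = FALSE]
    data.frame(
      level = lv,
      fi_target_correct = if (nrow(corr)) mean(corr$fisher_cue_target) else NA_real_,
      fi_target_swap = if (nrow(swaps)) mean(swaps$fisher_cue_target) else NA_real_,
      fi_selected_swap = if (nrow(swaps)) mean(swaps$fisher_cue_selected) else NA_real_,
      fi_marginal_sim = mean(d$fisher_cue_target),
      fi_marginal_analytic = lam_c * k_cue * bessel_ratio(k_cue),
      n_swap = nrow(swaps), n_trials = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
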