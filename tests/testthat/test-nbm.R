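# Neural binding model: decode densities, response density, likelihood, fit
# plumbing, diagnostics.

test_that("decode-error density handles the exact small-count cases", {
  d0 <- decode_error_density(0, 5)
  expect_equal(d0$density, rep(1 / (2 * pi), 720))
  d1 <- decode_error_density(1, 3.2)
  expect_equal(d1$density, vm_pdf(d1$theta, 0, 3.2), tolerance = 1e-12)
  expect_error(decode_error_density(-1, 2))
  expect_error(decode_error_density(2, 0))
})

test_that("decode-error density at zero matches a fresh-seed Monte Carlo oracle", {
  m <- 4; kap <- 2
  de <- decode_error_density(m, kap)
  set.seed(20260923)
  nsim <- 2e6
  th <- matrix(vm_sample(nsim * m, 0, kap), nsim, m)
  dec <- atan2(rowSums(sin(th)), rowSums(cos(th)))
  # oracle density at 0 from a narrow window, quadratic-corrected by fitting
  # the window histogram
  win <- 0.06
  oracle <- mean(abs(dec) < win) / (2 * win)
  expect_lt(abs(de$density[361] - oracle) / oracle, 0.02)
})

test_that("response density is normalized and consistent with the simulator", {
  cfg <- task_orientation_location("location", 4L)
  tr <- generate_trials(cfg, seed = 71)
  p <- nbm_params(10, 4, 24, c(low = 0.3, medium = 0.6, high = 0.9))
  for (row in c(2, 9)) {
    one <- keep_level(tr[row, , drop = FALSE], tr$level[row])
    nd <- nbm_response_density(one, p)
    expect_equal(sum(nd$density) * 2 * pi / 720, 1, tolerance = 1e-6)
    expect_equal(sum(nd$selection_prob), 1, tolerance = 1e-6)
    big <- one[rep(1, 20000), , drop = FALSE]
    attr(big, "config") <- cfg; class(big) <- class(tr)
    sim <- simulate_responses(big, "nbm", p, seed = 72 + row)
    swap_sim <- mean(sim$ground_truth_selected != one$target_index)
    swap_dens <- 1 - nd$selection_prob[one$target_index]
    se <- sqrt(swap_sim * (1 - swap_sim) / 20000)
    expect_lt(abs(swap_dens - swap_sim), 3 * se + 0.005)
  }
})

test_that("log-likelihood is additive, deterministic, and peaked near truth", {
  p <- nbm_params(10, 4, 24, c(low = 0.3, medium = 0.6, high = 0.9))
  tr <- generate_trials(task_orientation_location("location", 60L), seed = 75)
  rs <- simulate_responses(tr, "nbm", p, seed = 76)
  ll <- nbm_loglik(rs, p)
  expect_identical(nbm_loglik(rs, p), ll)
  doubled <- rbind(as.data.frame(rs), as.data.frame(rs))
  class(doubled) <- class(rs)
  expect_equal(nbm_loglik(doubled, p), 2 * ll, tolerance = 1e-10)
  worse <- nbm_params(10, 4, 240, c(low = 0.3, medium = 0.6, high = 0.9))
  expect_gt(ll, nbm_loglik(rs, worse))
  bad <- rs; bad$response[1] <- 4
  expect_error(nbm_loglik(bad, p))
})

test_that("zero conjunction on the cue dimension makes selection uniform", {
  cfg <- task_orientation_location("location", 2000L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 77)
  p <- nbm_params(10, 4, 30, c(all = 0))
  rs <- simulate_responses(tr, "nbm", p, seed = 78)
  sw <- mean(rs$ground_truth_selected != rs$target_index)
  se <- sqrt(5 / 6 * 1 / 6 / nrow(rs))
  expect_lt(abs(sw - 5 / 6), 3 * se)
  # all-levels marginal zero-count probability is exactly 1 at c = 0
  z <- zero_spike_conditionals(tr[1:200, ], p, n_rep = 2L, seed = 79)
  expect_equal(z$p_zero_marginal_analytic, 1)
  expect_equal(z$p_zero_marginal_sim, 1)
})

test_that("zero-spike conditionals match the analytic marginal", {
  cfg <- task_orientation_location("location", 300L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 80)
  p <- nbm_params(10, 4, 24, c(all = 0.5))
  z <- zero_spike_conditionals(tr, p, n_rep = 25L, seed = 81)
  n_eff <- z$n_trials
  se <- sqrt(z$p_zero_marginal_analytic * (1 - z$p_zero_marginal_analytic) / n_eff)
  expect_lt(abs(z$p_zero_marginal_sim - z$p_zero_marginal_analytic), 3 * se)
  expect_equal(z$p_zero_marginal_analytic, exp(-24 / 6 * 0.5))
})

test_that("precision diagnostics reproduce the closed-form unconditional mean", {
  cfg <- task_orientation_location("location", 400L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 82)
  p <- nbm_params(10, 4, 24, c(all = 0.5))
  pr <- precision_by_outcome(tr, p, n_rep = 25L, seed = 83)
  expect_equal(pr$fi_marginal_analytic,
               (24 / 6 * 0.5) * 4 * besselI(4, 1, TRUE) / besselI(4, 0, TRUE))
  expect_lt(abs(pr$fi_marginal_sim - pr$fi_marginal_analytic) /
              pr$fi_marginal_analytic, 0.05)
  # zero conjunction: no cue information at all
  pr0 <- precision_by_outcome(tr, nbm_params(10, 4, 24, c(all = 0)),
                              n_rep = 2L, seed = 84)
  expect_equal(pr0$fi_marginal_sim, 0)
})

test_that("noiseless limit concentrates responses on the target", {
  cfg <- task_orientation_location("location", 150L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 85)
  p <- nbm_params(500, 500, 4000, c(all = 1))
  rs <- simulate_responses(tr, "nbm", p, seed = 86)
  expect_equal(mean(rs$ground_truth_selected != rs$target_index), 0)
  expect_lt(stats::sd(rs$error_to_target), 0.03)
})
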