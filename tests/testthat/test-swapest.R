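# Swap-frequency estimators and the randomization correction.

test_that("nearest-item classification is exact on constructed cases", {
  tr <- make_two_item_trial(rep_ = c(0.4, -2.1))
  at_target <- with_responses(tr, 0.4)
  expect_false(nearest_item_swaps(at_target)$labels)
  at_nontarget <- with_responses(tr, -2.1)
  expect_true(nearest_item_swaps(at_nontarget)$labels)
  dup <- make_two_item_trial(rep_ = c(1, 1))
  expect_error(nearest_item_swaps(with_responses(dup, 1)), "duplicate")
})

test_that("nearest-item estimate tracks the generating non-target rate", {
  cfg <- task_orientation_location("location", 2500L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 31)
  rs <- simulate_responses(tr, "mixture",
                           list(p_target = 0.7, p_nontarget = 0.3,
                                p_uniform = 0, kappa = 50), seed = 32)
  est <- nearest_item_swaps(rs)
  se <- sqrt(0.3 * 0.7 / nrow(rs))
  expect_lt(abs(est$proportion - 0.3), 3 * se)
  # with near-noiseless report decoding the labels equal the ground truth
  truth <- rs$ground_truth_selected != rs$target_index
  expect_gt(mean(est$labels == truth), 0.99)
})

test_that("mixture EM recovers weights, flags degenerate data sensibly", {
  cfg <- task_orientation_location("location", 500L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 33)
  rs <- simulate_responses(tr, "target_only", list(kappa = 8), seed = 34)
  fm <- fit_mixture(rs, n_restarts = 6L)
  expect_gte(fm$p_target, 0.95)
  expect_equal(fm$p_target + fm$p_nontarget + fm$p_uniform, 1, tolerance = 1e-8)
  # pure uniform data: the fit is degenerate (a zero-concentration von Mises
  # is itself uniform), so either the guessing weight dominates or kappa
  # collapses; the fitted density must be flat either way
  set.seed(101)
  ru <- with_responses(tr, runif(nrow(tr), -pi, pi))
  attr(ru, "config") <- cfg
  fu <- fit_mixture(ru, n_restarts = 6L)
  expect_true(fu$p_uniform > 0.9 || fu$kappa < 0.2)
  expect_lt(abs(fu$loglik - nrow(ru) * log(1 / (2 * pi))), 8)
  expect_true(is.finite(fu$kappa))
})

test_that("randomization profile: flat and pi/2 without separations, dip with", {
  # no minimum separation: inert values are uniform, expected MAD = pi/2
  cfg0 <- task_spatial_cue("random")
  tr0 <- generate_trials(cfg0, 400L, seed = 35)
  rs0 <- simulate_responses(tr0, "target_only", list(kappa = 8), seed = 36)
  pr0 <- expected_nontarget_profile(rs0, n_iter = 300L, seed = 37)
  n_draws <- pr0$n_trials * 300L
  expect_lt(abs(pr0$mad_expected - pi / 2), 3 * 0.91 / sqrt(n_draws / 5))
  expect_lt(max(abs(pr0$expected - 1 / (2 * pi))), 0.02)
  # concentrated responses + minimum separation: central dip in expected
  cfg1 <- task_orientation_location("location", 800L)
  cfg1$levels <- "all"
  tr1 <- generate_trials(cfg1, seed = 38)
  rs1 <- simulate_responses(tr1, "target_only", list(kappa = 12), seed = 39)
  pr1 <- expected_nontarget_profile(rs1, n_iter = 300L, seed = 40)
  centre <- pr1$expected[19]                  # bin containing zero
  flank <- mean(pr1$expected[c(10, 28)])
  expect_lt(centre, flank)
  # corrected histogram on no-swap data: within ~4 SE of zero in every bin
  # (observed histogram has 4000 pooled deviations here)
  se_bin <- sqrt(max(pr1$observed) / (4000 * diff(pr1$bin_edges)[1]))
  expect_lt(max(abs(pr1$corrected)), 4 * se_bin)
  expect_gt(pr1$mad_expected, pi / 2)         # dip pushes expected MAD up
})

test_that("resultant-vector estimator: null calibration and flags", {
  cfg <- task_orientation_location("location", 3000L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 41)
  rs <- simulate_responses(tr, "target_only", list(kappa = 6), seed = 42)
  est <- resultant_vector_estimate(rs)
  # no-swap data: non-target weight within 3 SE of zero (sampling SE of the
  # estimator is ~0.08 at n = 3000 under this separation structure)
  expect_lt(abs(est$p_nontarget), 0.25)
  expect_gt(est$p_target, 0.8)
  expect_equal(est$p_target + est$p_nontarget + est$p_uniform, 1,
               tolerance = 1e-10)
})

test_that("mixture and resultant-vector estimates agree on common data", {
  cfg <- task_spatial_cue("random")
  tr <- generate_trials(cfg, 8000L, seed = 46)
  rs <- simulate_responses(tr, "mixture",
                           list(p_target = 0.55, p_nontarget = 0.3,
                                p_uniform = 0.15, kappa = 10), seed = 47)
  set.seed(48)
  fm <- fit_mixture(rs, n_restarts = 4L)
  rv <- resultant_vector_estimate(rs)
  # joint sampling error is dominated by the resultant method (~0.03 here)
  expect_lt(abs(fm$p_nontarget - rv$p_nontarget), 0.12)
  expect_lt(abs(fm$p_target - rv$p_target), 0.12)
})

test_that("MAD-by-distance finds swaps only where they were injected", {
  cfg <- task_spatial_cue("random")
  tr <- generate_trials(cfg, 3000L, seed = 43)
  # swaps only toward the spatially nearest non-target on 40% of trials
  cf <- cue_features(tr); rp <- report_features(tr)
  n <- nrow(tr)
  cue_val <- cf[cbind(seq_len(n), tr$target_index)]
  d <- abs(wrap_angle(cf - cue_val)); d[cbind(seq_len(n), tr$target_index)] <- Inf
  nearest_nt <- max.col(-d, ties.method = "first")
  swap <- runif(n) < 0.4
  pick <- ifelse(swap, nearest_nt, tr$target_index)
  resp <- wrap_angle(rp[cbind(seq_len(n), pick)] + vm_sample(n, 0, 20))
  rs <- with_responses(tr, resp, pick)
  attr(rs, "config") <- cfg
  prof <- mad_by_distance(rs)
  expect_equal(nrow(prof), 7L)
  expect_lt(prof$mad[1], pi / 2 - 0.05)       # clear dip where swaps go
  se <- 0.91 / sqrt(prof$n)
  expect_true(all(abs(prof$mad[4:7] - pi / 2) < 3 * se[4:7]))
  # fixed-layout arrays occupy exactly the three discrete distances
  cfg_f <- task_spatial_cue("fixed")
  tr_f <- generate_trials(cfg_f, 300L, seed = 44)
  rs_f <- simulate_responses(tr_f, "target_only", list(kappa = 6), seed = 45)
  prof_f <- mad_by_distance(rs_f)
  expect_equal(nrow(prof_f), 3L)
  expect_equal(prof_f$n, c(2, 2, 1) * 300)
})
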