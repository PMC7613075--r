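# Synthetic trial generation: constraints, layouts, response simulation, I/O.

test_that("infeasible separation constraints are rejected before sampling", {
  expect_error(experiment_config(6, min_sep_cue = 61 * pi / 180),
               "infeasible")
  expect_silent(experiment_config(6, min_sep_cue = 59 * pi / 180))
})

test_that("generated arrays respect minimum separations and are reproducible", {
  cfg <- task_orientation_location("location", 60L)
  a <- generate_trials(cfg, seed = 5)
  b <- generate_trials(cfg, seed = 5)
  expect_identical(a, b)
  # orientation (cue) separations >= 30 deg scaled, location (report) >= 30 deg
  cf <- cue_features(a); rp <- report_features(a)
  min_pair_dist <- function(m) {
    prs <- utils::combn(ncol(m), 2)
    mins <- rep(Inf, nrow(m))
    for (p in seq_len(ncol(prs))) {
      mins <- pmin(mins, abs(wrap_angle(m[, prs[1, p]] - m[, prs[2, p]])))
    }
    mins
  }
  expect_true(all(min_pair_dist(cf) >= cfg$min_sep_cue - 1e-12))
  expect_true(all(min_pair_dist(rp) >= cfg$min_sep_rep - 1e-12))
  expect_true(all(a$target_index >= 1 & a$target_index <= 6))
})

test_that("single-feature marginals are uniform under constrained sampling", {
  cfg <- task_direction_location("location", 4000L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 9)
  x <- cue_features(tr)[, 2]
  h <- tabulate(findInterval(x, seq(-pi, pi, length.out = 37),
                             rightmost.closed = TRUE), 36)
  p <- stats::chisq.test(h)$p.value
  expect_gt(p, 1e-3)
})

test_that("spatial layouts: fixed is constant, rotated preserves separations", {
  fx <- generate_spatial_config("fixed", 5L, 6L)
  expect_equal(dim(fx), c(5L, 6L))
  expect_true(all(apply(fx, 2, function(col) all(col == col[1]))))
  gaps <- sort(abs(wrap_angle(fx[1, ] - fx[1, c(2:6, 1)])))
  expect_equal(gaps, rep(pi / 3, 6))
  set.seed(14)
  rt <- generate_spatial_config("rotated", 200L, 6L)
  sep_multiset <- function(row) sort(round(abs(wrap_angle(outer(row, row, "-"))), 10))
  ref <- sep_multiset(rt[1, ])
  for (i in c(2, 57, 200)) expect_equal(sep_multiset(rt[i, ]), ref)
  set.seed(15)
  rd <- generate_spatial_config("random", 300L, 6L, 36 * pi / 180)
  prs <- utils::combn(6, 2)
  for (p in seq_len(ncol(prs))) {
    expect_true(all(abs(wrap_angle(rd[, prs[1, p]] - rd[, prs[2, p]])) >=
                      36 * pi / 180 - 1e-12))
  }
})

test_that("target_only simulation with huge concentration reproduces the target", {
  cfg <- task_orientation_location("location", 50L)
  tr <- generate_trials(cfg, seed = 21)
  rs <- simulate_responses(tr, "target_only", list(kappa = 1e5), seed = 22)
  expect_lt(max(abs(rs$error_to_target)), 0.05)
  expect_true(all(rs$ground_truth_selected == rs$target_index))
  expect_equal(nearest_item_swaps(rs)$proportion, 0)
})

test_that("mixture simulation hits the requested component rates", {
  cfg <- task_orientation_location("location", 4000L)
  cfg$levels <- "all"
  tr <- generate_trials(cfg, seed = 23)
  w <- c(0.6, 0.3, 0.1)
  rs <- simulate_responses(tr, "mixture",
                           list(p_target = w[1], p_nontarget = w[2],
                                p_uniform = w[3], kappa = 8), seed = 24)
  n <- nrow(rs)
  f_t <- mean(!is.na(rs$ground_truth_selected) &
                rs$ground_truth_selected == rs$target_index)
  f_nt <- mean(!is.na(rs$ground_truth_selected) &
                 rs$ground_truth_selected != rs$target_index)
  f_u <- mean(is.na(rs$ground_truth_selected))
  for (i in 1:3) {
    se <- sqrt(w[i] * (1 - w[i]) / n)
    expect_lt(abs(c(f_t, f_nt, f_u)[i] - w[i]), 3 * se)
  }
  expect_error(simulate_responses(tr, "mixture",
                                  list(p_target = 0.9, p_nontarget = 0.3,
                                       p_uniform = 0.1, kappa = 8)))
})

test_that("trial tables roundtrip through TSV", {
  cfg <- task_direction_location("location", 8L)
  tr <- generate_trials(cfg, seed = 25)
  rs <- simulate_responses(tr, "target_only", list(kappa = 4), seed = 26)
  path <- tempfile(fileext = ".tsv")
  write_trials(rs, path)
  back <- read_trials(path)
  expect_s3_class(back, "swap_responses")
  expect_equal(back$response, round(rs$response, 6))
  expect_equal(cue_features(back), round(cue_features(rs), 6),
               ignore_attr = TRUE)
  unlink(path)
})
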