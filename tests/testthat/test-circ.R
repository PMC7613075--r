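# Circular-statistics core: wrapping, distances, resultants, densities.

test_that("wrap_angle maps onto (-pi, pi] with the boundary at +pi", {
  expect_identical(wrap_angle(0), 0)
  expect_equal(wrap_angle(3 * pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(6), 6 - 2 * pi)
  # idempotence and range over many values
  x <- seq(-50, 50, length.out = 4001)
  w <- wrap_angle(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_angle(w), w)
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_error(wrap_angle(Inf))
  expect_error(wrap_angle(NA_real_))
})

test_that("circ_dist is a signed wrapped difference and antisymmetric", {
  expect_equal(circ_dist(pi / 4, pi / 4), 0)
  expect_equal(circ_dist(pi, -pi), 0)
  expect_equal(circ_dist(3, -3), wrap_angle(6))
  set.seed(1)
  a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
  s <- wrap_angle(circ_dist(a, b) + circ_dist(b, a))
  off_boundary <- abs(abs(circ_dist(a, b)) - pi) > 1e-8
  expect_true(all(abs(s[off_boundary]) < 1e-12))
})

test_that("resultant vector length and direction behave as expected", {
  for (n in c(2, 3, 7, 360)) {
    eq <- wrap_angle(2 * pi * (0:(n - 1)) / n)
    expect_lt(circ_resultant(eq)$length, 1e-10)
  }
  r1 <- circ_resultant(1.2)
  expect_equal(r1$length, 1)
  expect_equal(r1$direction, 1.2)
  r3 <- circ_resultant(c(0, 0, pi))
  expect_equal(r3$length, 1 / 3)
  expect_equal(r3$direction, 0)
  # weighted: mixture resultant is the weighted sum of component resultants
  rw <- circ_resultant(c(0, pi / 2), weights = c(3, 1))
  expect_equal(rw$length, sqrt(0.75^2 + 0.25^2))
  expect_error(circ_resultant(numeric(0)))
  expect_error(circ_resultant(c(0, 1), weights = c(0, 0)))
})

test_that("circ_sd matches sqrt(-2 log A(kappa)) for von Mises samples", {
  expect_equal(circ_sd(rep(0.7, 5)), 0)
  expect_identical(circ_sd(c(0, pi)), Inf)
  set.seed(7)
  for (kap in c(0.5, 1, 2, 5)) {
    x <- vm_sample(2e5, 0, kap)
    oracle <- sqrt(-2 * log(besselI(kap, 1, TRUE) / besselI(kap, 0, TRUE)))
    expect_equal(circ_sd(x), oracle, tolerance = 0.02)
  }
})

test_that("circ_mad is the mean absolute wrapped deviation", {
  expect_equal(circ_mad(rep(0, 10)), 0)
  expect_equal(circ_mad(c(pi / 2, -pi / 2)), pi / 2)
  set.seed(8)
  u <- runif(2e5, -pi, pi)
  se <- sd(abs(u)) / sqrt(length(u))
  expect_lt(abs(circ_mad(u) - pi / 2), 3 * se)
  expect_error(circ_mad(numeric(0)))
})

test_that("vm_pdf is a normalized symmetric density with uniform limit", {
  expect_equal(vm_pdf(2.2, 0, 0), 1 / (2 * pi))
  expect_equal(vm_pdf(0, 0, 1), exp(1) / (2 * pi * besselI(1, 0)))
  d <- 0.83
  expect_equal(vm_pdf(1 + d, 1, 3), vm_pdf(1 - d, 1, 3))
  th <- -pi + 2 * pi * (0:4095) / 4096
  for (kap in c(0, 0.5, 4, 50)) {
    expect_lt(abs(sum(vm_pdf(th, 0.3, kap)) * 2 * pi / 4096 - 1), 1e-8)
  }
  expect_error(vm_pdf(0, 0, -1))
})

test_that("vm_sample is reproducible, concentrated at high kappa, uniform at zero", {
  set.seed(11); a <- vm_sample(500, 1, 3)
  set.seed(11); b <- vm_sample(500, 1, 3)
  expect_identical(a, b)
  set.seed(12)
  x <- vm_sample(1000, 0.5, 5e4)
  expect_lt(max(abs(circ_dist(x, 0.5))), 0.05)
  set.seed(13)
  u <- vm_sample(1e5, 0, 0)
  ks <- suppressWarnings(stats::ks.test(u, "punif", -pi, pi))
  expect_gt(ks$p.value, 1e-4)
  expect_error(vm_sample(-1, 0, 1))
  expect_error(vm_sample(10, 0, -2))
})

test_that("orientation scaling doubles the native 180-degree space", {
  expect_equal(scale_orientation(0), 0)
  expect_equal(scale_orientation(90), pi)
  expect_equal(scale_orientation(-45), -pi / 2)
  # distances double too (mod the full circle)
  expect_equal(abs(circ_dist(scale_orientation(10), scale_orientation(25))),
               2 * 15 * pi / 180)
})

test_that("von Mises Fisher information has the right form and limits", {
  expect_equal(fisher_info_vm(0, 3), 0)
  expect_equal(fisher_info_vm(3, 0), 0)
  expect_equal(fisher_info_vm(3, 2), 3 * 2 * besselI(2, 1, TRUE) / besselI(2, 0, TRUE))
  # A(kappa) -> 1: information approaches m * kappa
  expect_equal(fisher_info_vm(5, 500) / (5 * 500), 1, tolerance = 2e-3)
  expect_error(fisher_info_vm(-1, 2))
})
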