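#' Wrap angles to (-pi, pi]
#'
#' All angular quantities in swapkit live on the half-open interval
#' \eqn{(-\pi, \pi]}. `wrap_angle()` maps any finite angle (radians) to this
#' interval; the boundary maps to \eqn{+\pi}, never \eqn{-\pi}, so every
#' direction has a unique representation.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector congruent to `x` modulo \eqn{2\pi}, in
#'   \eqn{(-\pi, \pi]}.
#' @examples
#' wrap_angle(3 * pi)   # pi, not -pi
#' wrap_angle(6)        # 6 - 2*pi
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("wrap_angle() requires finite numeric input")
  }
  w <- x - 2 * pi * floor(x / (2 * pi) + 0.5)
  # floor(+0.5) sends odd multiples of pi to -pi; fold them back to +pi
  w[w <= -pi] <- pi
  w
}

#' Signed circular distance
#'
#' Signed angular deviation `a - b` wrapped to \eqn{(-\pi, \pi]}. Used
#' throughout for the deviation between a response and a stored feature value.
#'
#' @param a,b Numeric vectors of angles in radians (recycled).
#' @return Signed deviations in \eqn{(-\pi, \pi]}.
#' @export
circ_dist <- function(a, b) {
  wrap_angle(a - b)
}

#' Mean resultant vector
#'
#' Length and direction of the (optionally weighted) mean resultant vector of
#' a set of angles. The length lies in \eqn{[0, 1]}: 1 for a point mass, 0 for
#' a uniform (or balanced) set of directions. The direction is the circular
#' mean. The resultant of a mixture of circular distributions is the weighted
#' sum of the component resultants, which is what the resultant-vector swap
#' estimator exploits.
#'
#' @param angles Numeric vector of angles in radians (at least one).
#' @param weights Optional non-negative weights, same length as `angles`, not
#'   all zero.
#' @return A list with elements `length` (in \eqn{[0,1]}) and `direction`
#'   (radians in \eqn{(-\pi, \pi]}; 0 when the length is numerically zero).
#' @export
circ_resultant <- function(angles, weights = NULL) {
  if (length(angles) == 0L) stop("circ_resultant() requires at least one angle")
  if (anyNA(angles) || any(!is.finite(angles))) stop("non-finite angles")
  if (is.null(weights)) {
    c_ <- mean(cos(angles))
    s_ <- mean(sin(angles))
  } else {
    if (length(weights) != length(angles)) stop("weights length mismatch")
    if (any(weights < 0)) stop("weights must be non-negative")
    sw <- sum(weights)
    if (sw <= 0) stop("weights must not all be zero")
    c_ <- sum(weights * cos(angles)) / sw
    s_ <- sum(weights * sin(angles)) / sw
  }
  len <- sqrt(c_^2 + s_^2)
  len <- min(len, 1)
  dir <- if (len < .Machine$double.eps) 0 else atan2(s_, c_)
  list(length = len, direction = wrap_angle(dir))
}

#' Circular standard deviation
#'
#' \eqn{\sqrt{-2 \log R}} where \eqn{R} is the mean resultant length. Returns
#' `Inf` when \eqn{R = 0} (the uniform limit); callers that cannot use an
#' infinite spread should filter.
#'
#' @param angles Numeric vector of angles in radians.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
circ_sd <- function(angles) {
  r <- circ_resultant(angles)$length
  if (r < 1e-12) return(Inf)      # numerically zero resultant: uniform limit
  sqrt(-2 * log(r))
}

#' Circular mean absolute deviation
#'
#' Mean of the absolute wrapped deviations; lies in \eqn{[0, \pi]}. For
#' deviations uniform on the circle the expected value is \eqn{\pi/2}, which
#' is the no-swap reference level in the distance-binned non-target analysis.
#'
#' @param deviations Numeric vector of deviations in radians.
#' @return Scalar in \eqn{[0, \pi]}.
#' @export
circ_mad <- function(deviations) {
  if (length(deviations) == 0L) stop("circ_mad() requires at least one value")
  mean(abs(wrap_angle(deviations)))
}

#' von Mises density
#'
#' Density of the von Mises (circular normal) distribution with mean
#' direction `mu` and concentration `kappa`,
#' \deqn{f(x) = \exp(\kappa \cos(x - \mu)) / (2\pi I_0(\kappa)).}
#' `kappa = 0` gives the circular uniform density \eqn{1/(2\pi)}. For large
#' `kappa` the Bessel factor is evaluated with exponential scaling to avoid
#' overflow.
#'
#' @param x Numeric vector of angles in radians.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, non-negative scalar.
#' @return Density values.
#' @export
vm_pdf <- function(x, mu = 0, kappa = 1) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    stop("kappa must be a non-negative scalar")
  }
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Draws using the Best-Fisher (1979) rejection envelope; `kappa = 0` falls
#' back to uniform sampling. Uses the R session RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param n Number of draws (non-negative integer).
#' @param mu Mean direction (radians).
#' @param kappa Concentration, non-negative scalar.
#' @return `n` angles in \eqn{(-\pi, \pi]}.
#' @export
vm_sample <- function(n, mu = 0, kappa = 1) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) stop("n must be >= 0")
  n <- as.integer(n)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    stop("kappa must be a non-negative scalar")
  }
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return(wrap_angle(stats::runif(n, -pi, pi)))
  # Best & Fisher wrapped-Cauchy envelope
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    m <- length(need)
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      u3 <- stats::runif(sum(ok))
      out[need[ok]] <- sign(u3 - 0.5) * acos(f[ok])
    }
    need <- need[!ok]
  }
  wrap_angle(out + mu)
}

#' Scale an orientation into the full circular space
#'
#' Orientation is periodic over 180 degrees; doubling maps the native
#' orientation space onto the full \eqn{(-\pi, \pi]} circle so orientations
#' and locations can be analyzed with the same circular machinery. Input is in
#' degrees of the native 180-degree space.
#'
#' @param theta Numeric vector of orientations in degrees.
#' @return Angles in \eqn{(-\pi, \pi]} radians (doubled space).
#' @examples
#' scale_orientation(90)   # pi
#' scale_orientation(-45)  # -pi/2
#' @export
scale_orientation <- function(theta) {
  wrap_angle(2 * theta * pi / 180)
}

#' Fisher information of a von Mises mean-direction estimate
#'
#' For `m` independent von Mises samples with known concentration `kappa`,
#' the Fisher information for the mean direction is
#' \eqn{m \kappa I_1(\kappa) / I_0(\kappa)}. This is the precision measure
#' used for the model-based diagnostics of decoded feature quality.
#'
#' @param m Sample (spike) count, non-negative.
#' @param kappa Concentration, non-negative.
#' @return Non-negative Fisher information; 0 when `m = 0` or `kappa = 0`.
#' @export
fisher_info_vm <- function(m, kappa) {
  if (any(m < 0) || any(kappa < 0)) stop("m and kappa must be non-negative")
  m * kappa * bessel_ratio(kappa)
}

# A(kappa) = I1(kappa)/I0(kappa), computed with exponential scaling so large
# kappa does not overflow. Vectorized over kappa.
bessel_ratio <- function(kappa) {
  r <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  r[kappa == 0] <- 0
  r
}

# Inverse of A(kappa): the standard piecewise approximation used for the
# kappa update in von Mises EM (Fisher 1993), followed by a couple of Newton
# refinements on A(kappa) = r.
a1_inv <- function(r) {
  r <- max(0, min(r, 1 - 1e-12))
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  for (i in 1:3) {
    a <- bessel_ratio(k)
    # dA/dkappa = 1 - A^2 - A/kappa
    da <- 1 - a^2 - ifelse(k > 0, a / k, 0.5)
    if (!is.finite(da) || da <= 0) break
    k <- max(k - (a - r) / da, 1e-8)
  }
  k
}

# Wrapped Laplace density/sampler (used as a non-von-Mises error shape in
# generator and validation work). rate is the exponential decay per radian.
wrapped_laplace_sample <- function(n, mu = 0, rate = 3) {
  if (rate <= 0) stop("rate must be positive")
  raw <- stats::rexp(n, rate) * sign(stats::runif(n) - 0.5)
  wrap_angle(raw + mu)
}
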