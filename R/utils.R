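# Internal numerical helpers shared across modules.

# Discrete Gaussian kernel, truncated at +/- 3 sigma, unit sum.
.gauss_kernel <- function(sigma_s, dt) {
  stopifnot(sigma_s > 0, dt > 0)
  half <- max(1L, ceiling(3 * sigma_s / dt))
  t <- (-half:half) * dt
  k <- exp(-t^2 / (2 * sigma_s^2))
  k / sum(k)
}

# Derivative-of-Gaussian kernel, normalized so that convolution with a ramp
# a*t returns a exactly (moment condition sum_j k_j * (-j*dt) = 1).
.dog_kernel <- function(sigma_s, dt) {
  stopifnot(sigma_s > 0, dt > 0)
  half <- max(2L, ceiling(3 * sigma_s / dt))
  t <- (-half:half) * dt
  k <- -t * exp(-t^2 / (2 * sigma_s^2))
  k <- k - mean(k)                      # enforce zero response to constants
  scale <- sum(k * (-t))
  k / scale
}

# Convolution with edge renormalization: the kernel mass falling outside the
# signal is dropped and the remainder rescaled, so constants map to constants
# right up to the boundary.
.conv_renorm <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  den <- stats::filter(wp, kernel, method = "convolution", sides = 2)
  out <- (num / den)[(half + 1L):(half + n)]
  as.numeric(out)
}

# Convolution with odd (antisymmetric) reflection padding, for derivative
# kernels: the local slope continues across the boundary, so ramps map to
# their exact slope everywhere, including the edges.
.conv_edge_replicate <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  hl <- min(half, n - 1L)
  left <- 2 * x[1] - x[seq(hl + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - hl)]
  if (hl < half) {
    left <- c(rep(left[1], half - hl), left)
    right <- c(right, rep(right[length(right)], half - hl))
  }
  out <- stats::filter(c(left, x, right), kernel, method = "convolution",
                       sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

.gauss_smooth <- function(x, sigma_s, dt) {
  if (sigma_s <= 0) return(x)
  .conv_renorm(x, .gauss_kernel(sigma_s, dt))
}

# z-score with guard for constant input
.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

.check_time_uniform <- function(time_s, tol = 1e-6) {
  dt <- diff(time_s)
  if (length(dt) == 0) stop("time grid needs at least 2 points")
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (diff(range(dt)) > tol * mean(dt)) stop("time grid is not uniform")
  mean(dt)
}

# linear interpolation across masked points; ends extended with nearest value
.interp_masked <- function(x, valid) {
  if (sum(valid) < 2) stop("fewer than 2 valid points")
  idx <- seq_along(x)
  stats::approx(idx[valid], x[valid], xout = idx, rule = 2)$y
}
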