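#' Two-channel fluorescence recording container
#'
#' @param time_s uniform volume time grid, seconds.
#' @param G GCaMP-channel fluorescence, neurons x time.
#' @param R RFP-channel fluorescence, neurons x time.
#' @param valid_mask logical neurons x time; FALSE = missing/untracked.
#' @param neuron_labels optional character labels (e.g. "AVAL").
#' @param epochs data.frame (name, start_s, end_s).
#' @return object of class \code{fluorescence_recording}.
#' @export
fluorescence_recording <- function(time_s, G, R, valid_mask = NULL,
                                   neuron_labels = NULL, epochs = NULL) {
  G <- as.matrix(G); R <- as.matrix(R)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(G), ncol(G))
  valid_mask <- as.matrix(valid_mask)
  if (!all(dim(G) == dim(R)) || !all(dim(G) == dim(valid_mask)))
    stop("G, R and valid_mask must share shape")
  if (ncol(G) != length(time_s)) stop("time axis length mismatch")
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (!is.null(neuron_labels) && length(neuron_labels) != nrow(G))
    stop("neuron_labels length mismatch")
  if (!is.null(epochs)) {
    if (any(epochs$start_s < min(time_s) - 1e-9) ||
        any(epochs$end_s > max(time_s) + 1 / 2))
      stop("epochs must lie within the recording")
  }
  structure(list(time_s = time_s, G = G, R = R, valid_mask = valid_mask,
                 neuron_labels = neuron_labels, epochs = epochs),
            class = "fluorescence_recording")
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf("<fluorescence_recording> %d neurons x %d volumes (%.1f s), %.1f%% valid\n",
              nrow(x$G), ncol(x$G), diff(range(x$time_s)),
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Fit a photobleaching model to one fluorescence trace
#'
#' Two-stage least-squares fit of \code{A*exp(-t/tau) + B}. The decay time
#' is estimated from the slow trend of the trace (a 30 s Gaussian smooth,
#' edges trimmed), where bleaching lives and fast calcium transients do
#' not, by bounded Levenberg-Marquardt; amplitude and offset are then
#' refit linearly on the raw trace at that tau. The model is marked
#' \code{applied} only when it is a reasonable description of the trend:
#' R-squared on the trend at least \code{min_r2}, tau inside
#' \code{tau_bounds}, positive amplitude, and a strictly positive fitted
#' curve. Flat or degenerate traces fail this test and are passed through
#' untouched downstream.
#'
#' @param trace fluorescence values.
#' @param time_s matching time axis.
#' @param valid logical mask of usable points.
#' @param min_r2 goodness threshold (R-squared on the slow trend) for
#'   applying the correction.
#' @param tau_bounds tau range (seconds) for which the correction is
#'   applied; default 10 s to 4x the trace duration. Slower decays are
#'   indistinguishable from linear trends on the trace and are left
#'   uncorrected (they are also too mild to matter).
#' @param trend_sigma_s Gaussian width isolating the slow trend.
#' @return object of class \code{bleach_model}: amplitude, tau, offset,
#'   goodness (trend R-squared), applied.
#' @export
fit_photobleach <- function(trace, time_s, valid = NULL, min_r2 = 0.3,
                            tau_bounds = NULL, trend_sigma_s = 30) {
  if (is.null(valid)) valid <- rep(TRUE, length(trace))
  valid <- valid & is.finite(trace)
  if (sum(valid) == 0) stop("empty trace")
  if (sum(valid) < 20) stop("need >= 20 valid points for bleach fit")
  t <- time_s[valid]; y <- trace[valid]
  dur <- diff(range(t))
  if (is.null(tau_bounds)) tau_bounds <- c(10, 4 * dur)
  opt_bounds <- c(min(1, tau_bounds[1]), max(20 * dur, tau_bounds[2]))

  # slow trend on the (nearly) uniform valid grid; trim the smoothing
  # edge-transition zones when the trace is long enough
  dt <- stats::median(diff(t))
  ys <- .gauss_smooth(y, trend_sigma_s, dt)
  # trim the kernel half-width: interior smoothing of an exponential is an
  # exactly rescaled exponential, so tau is estimated without edge bias
  ntrim <- ceiling(3 * trend_sigma_s / dt)
  keep <- if (length(y) > 2 * ntrim + 20)
    seq(ntrim + 1L, length(y) - ntrim) else seq_along(y)
  tf <- t[keep]; yf <- ys[keep]

  # stage 1: tau from the trend. Bounded Levenberg-Marquardt from several
  # tau starting points (the SSE landscape has a near-linear ridge at
  # tau -> Inf that can trap a single start); the best SSE wins.
  fit <- tryCatch({
    n_early <- max(1L, round(length(yf) * 0.05))
    y0 <- mean(yf[seq_len(n_early)])
    y1 <- mean(yf[seq(length(yf) - n_early + 1L, length(yf))])
    A0 <- max(y0 - y1, stats::sd(yf), 1e-6)
    best <- NULL
    for (tau0 in c(dur / 6, dur / 2, 2 * dur)) {
      m <- tryCatch(minpack.lm::nls.lm(
        par = c(A = A0, tau = tau0, B = y1),
        fn = function(p) yf - (p[["A"]] * exp(-tf / p[["tau"]]) + p[["B"]]),
        lower = c(A = 0, tau = opt_bounds[1], B = -Inf),
        upper = c(A = Inf, tau = opt_bounds[2], B = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                             ptol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(m) && (is.null(best) || m$deviance < best$deviance))
        best <- m
    }
    best$par
  }, error = function(e) NULL)

  if (is.null(fit)) {
    model <- list(amplitude = 0, tau = NA_real_, offset = mean(y),
                  goodness = 0, applied = FALSE)
  } else {
    tau <- fit[["tau"]]
    pred_s <- fit[["A"]] * exp(-tf / tau) + fit[["B"]]
    sst <- sum((yf - mean(yf))^2)
    r2 <- if (sst > 0) 1 - sum((yf - pred_s)^2) / sst else 0
    # stage 2: amplitude and offset refit linearly on the raw trace
    basis <- exp(-t / tau)
    ab <- tryCatch(stats::coef(stats::lm(y ~ basis)), error = function(e) NULL)
    if (is.null(ab) || any(!is.finite(ab))) {
      model <- list(amplitude = 0, tau = tau, offset = mean(y),
                    goodness = 0, applied = FALSE)
    } else {
      A <- unname(ab[2]); B <- unname(ab[1])
      full_fit <- A * exp(-time_s / tau) + B
      applied <- is.finite(r2) && r2 >= min_r2 &&
        tau >= tau_bounds[1] && tau <= tau_bounds[2] &&
        A > 0 && all(full_fit > 0)
      model <- list(amplitude = A, tau = tau, offset = B,
                    goodness = r2, applied = applied)
    }
  }
  structure(model, class = "bleach_model")
}

#' Correct a trace for photobleaching
#'
#' When the model is applied, the trace is divided by the fitted exponential
#' and then affinely rescaled to preserve the original mean and variance;
#' otherwise the trace is returned unchanged. If normalization leaves zero
#' variance (a pure exponential), the constant original-mean trace is
#' returned with a warning.
#'
#' @param trace fluorescence values.
#' @param time_s time axis.
#' @param model a \code{bleach_model}.
#' @param valid logical mask used for the mean/variance rescaling.
#' @return corrected trace.
#' @export
correct_photobleach <- function(trace, time_s, model, valid = NULL) {
  stopifnot(inherits(model, "bleach_model"))
  if (!isTRUE(model$applied)) return(trace)
  if (is.null(valid)) valid <- rep(TRUE, length(trace))
  fitval <- model$amplitude * exp(-time_s / model$tau) + model$offset
  if (any(fitval <= 0)) stop("degenerate bleach fit")
  norm <- trace / fitval
  m0 <- mean(trace[valid]); s0 <- stats::sd(trace[valid])
  m1 <- mean(norm[valid]); s1 <- stats::sd(norm[valid])
  if (!is.finite(s1) || s1 < 1e-6 * max(abs(m1), 1)) {
    warning("bleach normalization left zero variance; returning constant mean")
    return(rep(m0, length(trace)))
  }
  (norm - m1) / s1 * s0 + m0
}

#' Flag outlier timepoints in a two-channel trace
#'
#' A point is flagged when any of these holds: RFP below mean - 2 SD or
#' above mean + 5 SD; GCaMP further than 5 SD from its mean; RFP below an
#' absolute floor; the G/R ratio below a ratio floor; or the point is both
#' preceded and succeeded by missing or flagged points. Floors default to
#' 10% of the neuron's median R and 10% of its median G/R ratio.
#'
#' @param G_trace,R_trace one neuron's channel traces.
#' @param valid logical mask of tracked points (FALSE = missing).
#' @param r_floor_frac,ratio_floor_frac floor fractions of the medians.
#' @return logical outlier mask (TRUE = flagged; missing points stay FALSE
#'   here, they are already excluded by \code{valid}).
#' @export
detect_outliers <- function(G_trace, R_trace, valid = NULL,
                            r_floor_frac = 0.1, ratio_floor_frac = 0.1) {
  nt <- length(G_trace)
  if (nt == 0) return(logical(0))
  if (is.null(valid)) valid <- rep(TRUE, nt)
  g <- G_trace; r <- R_trace
  mg <- mean(g[valid]); sg <- stats::sd(g[valid])
  mr <- mean(r[valid]); sr <- stats::sd(r[valid])
  med_r <- stats::median(r[valid])
  ratio <- ifelse(r != 0, g / r, Inf)
  med_ratio <- stats::median(ratio[valid])

  out <- rep(FALSE, nt)
  out <- out | (r < mr - 2 * sr) | (r > mr + 5 * sr)
  out <- out | (abs(g - mg) > 5 * sg)
  out <- out | (r < r_floor_frac * med_r)
  out <- out | (ratio < ratio_floor_frac * med_ratio)
  out[!valid] <- FALSE

  # isolated points: preceded and succeeded by missing/outlier points
  bad <- out | !valid
  if (nt >= 3) {
    iso <- c(FALSE, bad[-c(nt - 1, nt)] & bad[-c(1, 2)], FALSE) & !bad
    out <- out | (iso & valid)
  }
  out
}

#' Interpolate masked points and Gaussian-smooth a trace
#'
#' Masked points are linearly interpolated (ends held at the nearest valid
#' value), then the trace is convolved with a Gaussian kernel truncated at
#' +/-3 sigma and renormalized at the edges so constants are preserved.
#'
#' @param trace values on a uniform grid.
#' @param valid logical mask; FALSE points are interpolated.
#' @param time_s time axis (uniform).
#' @param sigma_s smoothing kernel SD, seconds (default 0.83 s).
#' @return list: \code{trace} (smoothed), \code{interpolated} (logical mask
#'   of filled points).
#' @export
interpolate_and_smooth <- function(trace, valid, time_s, sigma_s = 0.83) {
  dt <- .check_time_uniform(time_s)
  if (sum(valid) < 2) stop("fewer than 2 valid points")
  filled <- .interp_masked(trace, valid)
  sm <- .gauss_smooth(filled, sigma_s, dt)
  list(trace = sm, interpolated = !valid)
}

#' Ratiometric motion correction of one neuron
#'
#' Computes \code{F_mc = (G - alpha*R) - mean(G - alpha*R)} where alpha
#' minimizes \code{sum((G - alpha*R)^2)} over valid points (closed form
#' \code{alpha = sum(G*R)/sum(R^2)}). The result is mean-zero over the
#' valid points.
#'
#' @param G_trace,R_trace aligned channel traces.
#' @param valid logical mask of points entering the alpha fit and the mean.
#' @return list: \code{F_mc} (full-length trace), \code{alpha}.
#' @export
motion_correct <- function(G_trace, R_trace, valid = NULL) {
  if (length(G_trace) != length(R_trace)) stop("traces must be aligned")
  if (is.null(valid)) valid <- rep(TRUE, length(G_trace))
  if (sum(valid) < 2) stop("need >= 2 valid points")
  g <- G_trace[valid]; r <- R_trace[valid]
  ssr <- sum(r^2)
  if (ssr == 0) stop("undefined alpha: R identically zero")
  alpha <- sum(g * r) / ssr
  resid <- G_trace - alpha * R_trace
  list(F_mc = resid - mean(resid[valid]), alpha = alpha)
}

#' Temporal derivative by Gaussian derivative kernel
#'
#' Convolves the trace with a derivative-of-Gaussian kernel (width
#' \code{width_s}, truncated at 3 widths, moment-normalized so a ramp maps
#' to its exact slope). By default the width is interpreted as the Gaussian
#' sigma; \code{width_is_fwhm = TRUE} interprets it as full width at half
#' maximum instead.
#'
#' @param trace values on a uniform grid.
#' @param time_s uniform time axis.
#' @param width_s kernel width, seconds (default 2.3 s).
#' @param width_is_fwhm interpret width as FWHM rather than sigma.
#' @return derivative trace, input units per second.
#' @export
temporal_derivative <- function(trace, time_s, width_s = 2.3,
                                width_is_fwhm = FALSE) {
  dt <- .check_time_uniform(time_s)
  sigma <- if (width_is_fwhm) width_s / (2 * sqrt(2 * log(2))) else width_s
  .conv_edge_replicate(trace, .dog_kernel(sigma, dt))
}

#' Maximal GCaMP Fano factor of a recording
#'
#' Max over neurons of variance/mean of the raw (pre-correction) GCaMP
#' trace, a proxy for how much calcium signal a recording carries relative
#' to its baseline. Variance is the unbiased sample estimator.
#'
#' @param G raw GCaMP matrix, neurons x time.
#' @param valid_mask optional logical mask.
#' @return scalar Fano factor.
#' @export
fano_gcamp <- function(G, valid_mask = NULL) {
  G <- as.matrix(G)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(G), ncol(G))
  f <- vapply(seq_len(nrow(G)), function(i) {
    x <- G[i, valid_mask[i, ]]
    m <- mean(x)
    if (m <= 0) stop("neuron mean <= 0: Fano factor undefined")
    stats::var(x) / m
  }, numeric(1))
  max(f)
}

#' Symmetric heatmap color limits for activity display
#'
#' The 99th percentile of |G - <G>| pooled over all neurons and timepoints,
#' with the mean taken per neuron; colormap bounds are +/- this limit, so
#' recordings with little signal relative to motion artifact appear dim.
#'
#' @param G raw GCaMP matrix, neurons x time.
#' @param prob percentile (default 0.99).
#' @return scalar limit.
#' @export
heatmap_limits <- function(G, prob = 0.99) {
  G <- as.matrix(G)
  if (length(G) == 0) stop("empty input")
  dev <- abs(sweep(G, 1, rowMeans(G)))
  as.numeric(stats::quantile(dev, prob, type = 7))
}

#' Run the full preprocessing pipeline on a recording
#'
#' Fixed stage order: per-channel photobleach correction, outlier masking
#' (including the volume-majority rule across neurons), linear interpolation
#' and Gaussian smoothing (sigma 0.83 s), ratiometric motion correction
#' (alpha fit on valid, non-interpolated points of the corrected smoothed
#' traces), and the Gaussian-derivative temporal derivative (width 2.3 s).
#'
#' @param rec a \code{fluorescence_recording}.
#' @param smooth_sigma_s smoothing kernel SD.
#' @param deriv_width_s derivative kernel width.
#' @param bleach_min_r2 bleach-fit goodness threshold.
#' @return object of class \code{neuron_activity}: \code{F_mc},
#'   \code{dFdt} (neurons x time), \code{alpha}, \code{G_smoothed} and
#'   \code{R_smoothed} (the bleach-corrected, interpolated, smoothed
#'   channels entering motion correction), \code{interpolated_mask},
#'   \code{valid_mask} (valid and not flagged), \code{time_s}, \code{qc}
#'   (per-neuron data.frame: alpha, bleach tau/goodness per channel,
#'   outlier fraction), plus the recording's labels and epochs.
#' @export
preprocess_recording <- function(rec, smooth_sigma_s = 0.83,
                                 deriv_width_s = 2.3, bleach_min_r2 = 0.1) {
  stopifnot(inherits(rec, "fluorescence_recording"))
  n <- nrow(rec$G); nt <- ncol(rec$G)
  t <- rec$time_s
  Gc <- matrix(NA_real_, n, nt); Rc <- matrix(NA_real_, n, nt)
  tau_g <- good_g <- tau_r <- good_r <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- rec$valid_mask[i, ]
    mg <- fit_photobleach(rec$G[i, ], t, v, min_r2 = bleach_min_r2)
    mr <- fit_photobleach(rec$R[i, ], t, v, min_r2 = bleach_min_r2)
    Gc[i, ] <- correct_photobleach(rec$G[i, ], t, mg, v)
    Rc[i, ] <- correct_photobleach(rec$R[i, ], t, mr, v)
    tau_g[i] <- mg$tau; good_g[i] <- mg$goodness
    tau_r[i] <- mr$tau; good_r[i] <- mr$goodness
  }

  out <- matrix(FALSE, n, nt)
  for (i in seq_len(n))
    out[i, ] <- detect_outliers(Gc[i, ], Rc[i, ], rec$valid_mask[i, ])
  # volume-majority rule: if most neurons are bad in a volume, drop it for all
  bad <- out | !rec$valid_mask
  maj <- colMeans(bad) > 0.5
  valid <- rec$valid_mask & !out
  valid[, maj] <- FALSE

  F_mc <- matrix(NA_real_, n, nt); dFdt <- matrix(NA_real_, n, nt)
  G_sm <- matrix(NA_real_, n, nt); R_sm <- matrix(NA_real_, n, nt)
  alpha <- rep(NA_real_, n)
  interp <- !valid
  for (i in seq_len(n)) {
    sg <- interpolate_and_smooth(Gc[i, ], valid[i, ], t, smooth_sigma_s)
    sr <- interpolate_and_smooth(Rc[i, ], valid[i, ], t, smooth_sigma_s)
    G_sm[i, ] <- sg$trace
    R_sm[i, ] <- sr$trace
    mc <- motion_correct(sg$trace, sr$trace, valid[i, ])
    F_mc[i, ] <- mc$F_mc
    alpha[i] <- mc$alpha
    dFdt[i, ] <- temporal_derivative(mc$F_mc, t, deriv_width_s)
  }

  qc <- data.frame(neuron = seq_len(n), alpha = alpha,
                   bleach_tau_G = tau_g, bleach_r2_G = good_g,
                   bleach_tau_R = tau_r, bleach_r2_R = good_r,
                   outlier_frac = rowMeans(out))
  structure(list(F_mc = F_mc, dFdt = dFdt, alpha = alpha,
                 G_smoothed = G_sm, R_smoothed = R_sm,
                 interpolated_mask = interp, valid_mask = valid,
                 time_s = t, qc = qc,
                 neuron_labels = rec$neuron_labels, epochs = rec$epochs),
            class = "neuron_activity")
}

#' @export
print.neuron_activity <- function(x, ...) {
  cat(sprintf("<neuron_activity> %d neurons x %d volumes; median alpha %.2f\n",
              nrow(x$F_mc), ncol(x$F_mc), stats::median(x$alpha)))
  invisible(x)
}
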