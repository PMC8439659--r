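#' Hampel filter a series
#'
#' Points deviating from the centered rolling median by more than
#' \code{n_mad} scaled MADs (1.4826 * MAD of the window) are replaced by
#' the rolling median. Window edges use the available part of the window.
#'
#' @param x numeric series.
#' @param window odd window length in samples.
#' @param n_mad rejection threshold in scaled MADs.
#' @return filtered series.
#' @export
hampel_filter <- function(x, window = 11, n_mad = 3) {
  if (window %% 2 == 0) stop("window must be odd")
  n <- length(x)
  if (window > n) stop("window longer than series")
  half <- (window - 1L) %/% 2L
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- x[lo:hi]
    med <- stats::median(w)
    s <- 1.4826 * stats::median(abs(w - med))
    if (is.finite(s) && s > 0 && abs(x[i] - med) > n_mad * s) out[i] <- med
  }
  out
}

# lab-frame point trajectory for one centerline index
.lab_point <- function(cl, idx) {
  p <- cl$points[, idx, , drop = FALSE]
  xy <- cbind(p[, 1, 1], p[, 1, 2])
  if (identical(cl$frame, "camera")) {
    sx <- stats::approx(cl$stage_time_s, cl$stage_xy[, 1], cl$frame_time_s,
                        rule = 2)$y
    sy <- stats::approx(cl$stage_time_s, cl$stage_xy[, 2], cl$frame_time_s,
                        rule = 2)$y
    xy <- xy + cbind(sx, sy)
  }
  xy
}

# arc length positions of the 100 points per frame; returns n_frames x 100
.arc_lengths <- function(points) {
  dx <- points[, -1, 1] - points[, -100, 1]
  dy <- points[, -1, 2] - points[, -100, 2]
  seg <- sqrt(dx^2 + dy^2)
  cbind(0, t(apply(seg, 1, cumsum)))
}

#' Signed crawling velocity from centerlines
#'
#' The velocity vector of a point 15% of body length behind the head tip is
#' projected onto the unit head-direction vector (from the 20% point toward
#' the 10% point). Centerline-derived positions (plus stage, when points
#' are in the camera frame) are Hampel filtered, interpolated to a common
#' 200 Hz axis, and differentiated by convolution with a derivative of a
#' Gaussian (sigma 0.5 s). Positive velocity is motion along the head
#' direction; reversals are negative.
#'
#' @param cl a \code{centerline_series}.
#' @param resample_hz common axis rate for differentiation.
#' @param deriv_sigma_s Gaussian derivative sigma.
#' @param hampel_window,hampel_nmad Hampel filter parameters.
#' @return list: \code{time_s} (200 Hz axis), \code{velocity} (mm/s).
#' @export
compute_velocity <- function(cl, resample_hz = 200, deriv_sigma_s = 0.5,
                             hampel_window = 11, hampel_nmad = 3) {
  stopifnot(inherits(cl, "centerline_series"))
  if (diff(range(cl$frame_time_s)) < 2) stop("need >= 2 s of frames")
  arcs <- .arc_lengths(cl$points)
  if (any(arcs[, 100] <= 0)) stop("degenerate centerline (zero length)")
  # indices closest to 10/15/20% of body length (per-recording mean length)
  Lbar <- mean(arcs[, 100])
  sfrac <- arcs / arcs[, 100]
  idx_of <- function(f) round(stats::median(apply(abs(sfrac - f), 1, which.min)))
  i10 <- idx_of(0.10); i15 <- idx_of(0.15); i20 <- idx_of(0.20)

  p15 <- .lab_point(cl, i15)
  p10 <- .lab_point(cl, i10)
  p20 <- .lab_point(cl, i20)

  hx <- hampel_filter(p15[, 1], hampel_window, hampel_nmad)
  hy <- hampel_filter(p15[, 2], hampel_window, hampel_nmad)

  dt <- 1 / resample_hz
  tt <- seq(min(cl$frame_time_s), max(cl$frame_time_s), by = dt)
  rx <- stats::approx(cl$frame_time_s, hx, tt, rule = 2)$y
  ry <- stats::approx(cl$frame_time_s, hy, tt, rule = 2)$y
  vx <- .conv_edge_replicate(rx, .dog_kernel(deriv_sigma_s, dt))
  vy <- .conv_edge_replicate(ry, .dog_kernel(deriv_sigma_s, dt))

  hdx <- stats::approx(cl$frame_time_s, p10[, 1] - p20[, 1], tt, rule = 2)$y
  hdy <- stats::approx(cl$frame_time_s, p10[, 2] - p20[, 2], tt, rule = 2)$y
  hn <- sqrt(hdx^2 + hdy^2)
  if (any(hn == 0)) stop("degenerate centerline (zero head direction)")
  list(time_s = tt, velocity = (vx * hdx + vy * hdy) / hn)
}

#' Mean mid-body curvature from centerlines
#'
#' Per frame: tangent angles of the centerline polyline, unwrapped, then
#' dtheta/ds by finite differences; the reported value is the mean over
#' segments whose arc position lies in 15-80% of body length, excluding
#' nose deflections and the tail tip. Sign follows the centerline's own
#' orientation (ventral bends positive by the generator's convention).
#'
#' @param cl a \code{centerline_series}.
#' @param range_frac anterior-posterior averaging range as fractions of
#'   body length.
#' @return list: \code{time_s} (frame times), \code{curvature} (1/mm).
#' @export
compute_curvature <- function(cl, range_frac = c(0.15, 0.80)) {
  stopifnot(inherits(cl, "centerline_series"))
  nf <- dim(cl$points)[1]
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- cl$points[f, , 1]; y <- cl$points[f, , 2]
    dx <- diff(x); dy <- diff(y)
    seg <- sqrt(dx^2 + dy^2)
    if (any(seg == 0)) stop("duplicated centerline points")
    theta <- atan2(dy, dx)
    dtheta <- diff(theta)
    dtheta <- (dtheta + pi) %% (2 * pi) - pi      # unwrap increments
    s_mid <- (cumsum(c(0, seg))[-(length(seg) + 1)] + seg / 2) # segment centers
    ds <- (seg[-length(seg)] + seg[-1]) / 2
    kappa <- dtheta / ds                            # at interior vertices
    s_vert <- cumsum(seg)[-length(seg)]
    L <- sum(seg)
    keep <- s_vert >= range_frac[1] * L & s_vert <= range_frac[2] * L
    if (!any(keep)) stop("averaging range contains no segments")
    out[f] <- mean(kappa[keep])
  }
  list(time_s = cl$frame_time_s, curvature = out)
}

#' Align behavior series to imaging volume times
#'
#' Linear interpolation of one or more behavior series onto the volume
#' grid; volumes outside the behavior time range are NA.
#'
#' @param time_s behavior time axis.
#' @param series named list of numeric series on that axis (e.g.
#'   \code{list(velocity = v, curvature = k)}).
#' @param volume_time_s target volume grid.
#' @return \code{behavior_trace} when both velocity and curvature are
#'   supplied; otherwise a list of interpolated series plus \code{time_s}.
#' @export
align_to_volumes <- function(time_s, series, volume_time_s) {
  if (max(time_s) < min(volume_time_s) || min(time_s) > max(volume_time_s))
    stop("no overlap between behavior and volume time ranges")
  interp <- lapply(series, function(x)
    stats::approx(time_s, x, volume_time_s, rule = 1)$y)
  if (all(c("velocity", "curvature") %in% names(interp)))
    return(behavior_trace(volume_time_s, interp$velocity, interp$curvature))
  c(list(time_s = volume_time_s), interp)
}

#' Full behavior extraction from centerlines
#'
#' Velocity and mean curvature computed from a centerline series and
#' aligned to the imaging volume grid.
#'
#' @param cl a \code{centerline_series}.
#' @param volume_time_s imaging volume times.
#' @return a \code{behavior_trace}.
#' @export
extract_behavior <- function(cl, volume_time_s) {
  v <- compute_velocity(cl)
  k <- compute_curvature(cl)
  vol_v <- stats::approx(v$time_s, v$velocity, volume_time_s, rule = 2)$y
  vol_k <- stats::approx(k$time_s, k$curvature, volume_time_s, rule = 2)$y
  behavior_trace(volume_time_s, vol_v, vol_k)
}
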