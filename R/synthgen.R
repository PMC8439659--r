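#' Configuration for the synthetic recording generator
#'
#' Builds a validated configuration describing a simulated freely-moving
#' (or moving-then-immobilized) worm recording: behavior statistics, the
#' per-neuron tuning table, the shared additive motion artifact, per-neuron
#' photobleaching, noise, and data-loss processes.
#'
#' The generator emulates the statistical structure that the downstream
#' analysis assumes: neurons tuned to velocity or body curvature through
#' their activity or its temporal derivative (with either sign, and
#' optionally responding only to a subset of behavioral events), an additive
#' motion artifact common to the GCaMP-like and RFP-like channels up to a
#' per-neuron scale factor, slow exponential photobleaching, sparse spike
#' outliers, and contiguous tracking gaps.
#'
#' @param duration_s recording length in seconds.
#' @param volume_rate_hz imaging volume rate (volumes/s).
#' @param n_neurons number of neurons (>= 2).
#' @param reversal_rate reversal events per minute.
#' @param turn_rate deep-turn events per minute.
#' @param tuning_table data.frame with one row per neuron and columns
#'   \code{behavior} ("velocity", "curvature" or "none"), \code{feature}
#'   ("activity" or "derivative"), \code{sign} (+1/-1), \code{gain}
#'   (dimensionless, 1 = typical), \code{event_subset_fraction} in [0,1]
#'   (1 = full analog tuning; < 1 = responds only at that fraction of
#'   events). \code{NULL} draws a mixed table deterministically from the seed.
#' @param artifact_amplitude artifact scale in fluorescence units (per SD of
#'   the shared artifact trace).
#' @param artifact_ratio_jitter relative SD of the independent per-channel
#'   deviation from exactly brightness-proportional artifact coupling; 0
#'   makes ratiometric correction exact in expectation (a true null for
#'   calibration studies), the default leaves a small behavior-locked
#'   residual as real tissue does.
#' @param bleach_tau_range range (seconds) from which per-neuron bleach time
#'   constants are drawn; \code{NULL} disables bleaching.
#' @param noise_sd additive Gaussian noise SD per channel, fluorescence units.
#' @param intrinsic_noise_frac SD of a neuron's intrinsic (behavior-
#'   independent) drive fluctuation, as a fraction of its tuned-drive SD.
#' @param signal_gain_global global multiplier on all calcium signals; 0
#'   emulates a GFP control animal (no activity signal, artifact only).
#' @param calcium_tau_s single-exponential calcium kernel time constant.
#' @param signal_scale fluorescence units per SD of signal at gain 1.
#' @param baseline fluorescence baseline (both channels, units).
#' @param gap_rate_per_min rate of contiguous per-neuron tracking gaps.
#' @param outlier_rate_per_min rate of injected single-point spike outliers.
#' @param immobilization_onset_s time of paralytic delivery, or \code{NA}
#'   for moving-only recordings.
#' @param transition_s duration of the annotated moving-to-immobile
#'   transition window excluded from epoch analyses.
#' @param flip_fraction fraction of non-reference neurons whose loading on
#'   the dominant latent flips sign upon immobilization.
#' @param seed integer RNG seed (mandatory; identical configs give
#'   bit-identical recordings).
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(duration_s = 480,
                         volume_rate_hz = 6,
                         n_neurons = 60,
                         reversal_rate = 3,
                         turn_rate = 2,
                         tuning_table = NULL,
                         artifact_amplitude = 15,
                         artifact_ratio_jitter = 0.1,
                         bleach_tau_range = c(600, 2000),
                         noise_sd = 1,
                         intrinsic_noise_frac = 0.5,
                         signal_gain_global = 1,
                         calcium_tau_s = 1.5,
                         signal_scale = 20,
                         baseline = 100,
                         gap_rate_per_min = 0.5,
                         outlier_rate_per_min = 0.3,
                         immobilization_onset_s = NA_real_,
                         transition_s = 90,
                         flip_fraction = 0.5,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (n_neurons < 2) stop("n_neurons must be >= 2")
  if (reversal_rate < 0 || turn_rate < 0) stop("event rates must be >= 0")
  if (noise_sd < 0 || artifact_amplitude < 0) stop("amplitudes must be >= 0")
  if (!is.na(immobilization_onset_s) &&
      (immobilization_onset_s <= 0 || immobilization_onset_s >= duration_s))
    stop("immobilization onset outside recording")
  seed <- as.integer(seed)

  if (is.null(tuning_table)) {
    set.seed(seed + 9L)
    tuning_table <- default_tuning_table(n_neurons)
  }
  validate_tuning_table(tuning_table, n_neurons)

  structure(list(
    duration_s = duration_s, volume_rate_hz = volume_rate_hz,
    n_neurons = as.integer(n_neurons),
    reversal_rate = reversal_rate, turn_rate = turn_rate,
    tuning_table = tuning_table,
    artifact_amplitude = artifact_amplitude,
    artifact_ratio_jitter = artifact_ratio_jitter,
    bleach_tau_range = bleach_tau_range,
    noise_sd = noise_sd, intrinsic_noise_frac = intrinsic_noise_frac,
    signal_gain_global = signal_gain_global,
    calcium_tau_s = calcium_tau_s, signal_scale = signal_scale,
    baseline = baseline,
    gap_rate_per_min = gap_rate_per_min,
    outlier_rate_per_min = outlier_rate_per_min,
    immobilization_onset_s = immobilization_onset_s,
    transition_s = transition_s, flip_fraction = flip_fraction,
    seed = seed
  ), class = "synth_config")
}

#' Draw a mixed default tuning table
#'
#' Roughly a third of neurons tuned to velocity, a third to curvature, the
#' rest untuned; within each tuned group half use activity and half its
#' temporal derivative, signs balanced, and one in five tuned neurons
#' responds only to half of the behavioral events (partial-event tuning).
#' Uses the current RNG state.
#'
#' @param n_neurons number of rows.
#' @return tuning table data.frame.
#' @export
default_tuning_table <- function(n_neurons) {
  behavior <- sample(c("velocity", "curvature", "none"), n_neurons,
                     replace = TRUE, prob = c(0.3, 0.3, 0.4))
  feature <- sample(c("activity", "derivative"), n_neurons, replace = TRUE)
  sgn <- sample(c(1, -1), n_neurons, replace = TRUE)
  gain <- stats::runif(n_neurons, 0.6, 1.6)
  esf <- ifelse(behavior != "none" & stats::runif(n_neurons) < 0.2, 0.5, 1)
  data.frame(behavior = behavior, feature = feature, sign = sgn,
             gain = gain, event_subset_fraction = esf,
             stringsAsFactors = FALSE)
}

validate_tuning_table <- function(tt, n_neurons) {
  if (nrow(tt) != n_neurons) stop("tuning_table length != n_neurons")
  if (!all(tt$behavior %in% c("velocity", "curvature", "none")))
    stop("tuning_table behavior must be velocity/curvature/none")
  if (!all(tt$feature %in% c("activity", "derivative")))
    stop("tuning_table feature must be activity/derivative")
  if (!all(tt$sign %in% c(-1, 1))) stop("tuning_table sign must be +/-1")
  if (any(tt$event_subset_fraction < 0 | tt$event_subset_fraction > 1))
    stop("event_subset_fraction must be in [0,1]")
  invisible(tt)
}

#' Behavior trace container
#'
#' @param time_s time axis (seconds), aligned to imaging volumes.
#' @param velocity signed body-bend velocity, mm/s.
#' @param curvature mean mid-body curvature, 1/mm (ventral positive).
#' @return object of class \code{behavior_trace}.
#' @export
behavior_trace <- function(time_s, velocity, curvature) {
  stopifnot(length(time_s) == length(velocity),
            length(time_s) == length(curvature))
  if (any(!is.finite(time_s))) stop("time must be finite")
  structure(list(time_s = time_s, velocity = velocity, curvature = curvature),
            class = "behavior_trace")
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("<behavior_trace> %d volumes, %.1f s, v in [%.3f, %.3f] mm/s\n",
              length(x$time_s), diff(range(x$time_s)),
              min(x$velocity), max(x$velocity)))
  invisible(x)
}

# Poisson event onsets over (0, duration)
.poisson_events <- function(rate_per_min, duration_s) {
  n <- stats::rpois(1, rate_per_min / 60 * duration_s)
  sort(stats::runif(n, 0, duration_s))
}

#' Generate synthetic worm behavior
#'
#' Velocity is a smoothed telegraph process: a forward baseline near
#' 0.1 mm/s with excursions to about -0.15 mm/s during Poisson-timed
#' reversal events, modulated by a bounded slow multiplicative fluctuation
#' (so that with no reversal events velocity stays strictly positive).
#' Curvature is band-limited noise plus large positive (ventral) Gaussian
#' bumps at Poisson-timed turn events.
#'
#' @param cfg a \code{synth_config}.
#' @return list with \code{behavior} (a \code{behavior_trace} on the volume
#'   grid) and \code{events} (data.frame: type, time_s, duration_s).
#' @export
generate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  dt <- 1 / cfg$volume_rate_hz
  time_s <- seq(0, cfg$duration_s - dt / 2, by = dt)
  nt <- length(time_s)

  rev_on <- .poisson_events(cfg$reversal_rate, cfg$duration_s)
  rev_dur <- pmin(pmax(stats::rexp(length(rev_on), 1 / 3), 1), 8)
  turn_on <- .poisson_events(cfg$turn_rate, cfg$duration_s)
  turn_dur <- rep(2, length(turn_on))

  v_tel <- rep(0.1, nt)
  for (k in seq_along(rev_on)) {
    idx <- time_s >= rev_on[k] & time_s < rev_on[k] + rev_dur[k]
    v_tel[idx] <- -0.15
  }
  # transition bandwidth ~1 s keeps the true process inside the passband of
  # the sigma = 0.5 s differentiation filter used for measurement, so the
  # centerline round trip can recover it
  v_tel <- .gauss_smooth(v_tel, 1.0, dt)
  eta <- .zscore(.gauss_smooth(stats::rnorm(nt), 1.5, dt))
  velocity <- v_tel * (1 + 0.15 * tanh(eta))

  curv <- 1.2 * .zscore(.gauss_smooth(stats::rnorm(nt), 1.0, dt))
  for (k in seq_along(turn_on)) {
    curv <- curv + 4 * exp(-(time_s - turn_on[k] - 1)^2 / (2 * 0.8^2))
  }
  curv <- 6 * tanh(curv / 6)   # body cannot bend past ~6/mm (no self-coiling)

  events <- data.frame(
    type = c(rep("reversal", length(rev_on)), rep("turn", length(turn_on))),
    time_s = c(rev_on, turn_on),
    duration_s = c(rev_dur, turn_dur),
    stringsAsFactors = FALSE)
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  list(behavior = behavior_trace(time_s, velocity, curv), events = events)
}

# per-neuron motion-artifact traces (neurons x time): local tissue
# deformation is dominated by fast undulatory bending (~0.45 Hz, with a
# neuron-specific phase along the body), amplitude-modulated by how much
# the animal is moving, plus a seconds-scale neuron-specific compression
# component and a small neuron-specific behavior-locked part (each
# neuron's locale deforms differently with posture, so the couplings to
# velocity and curvature vary in size and sign across neurons). Each row
# is z-scored; it largely vanishes when locomotion stops.
.artifact_matrix <- function(bt, dt, n) {
  nt <- length(bt$time_s)
  vmag <- abs(bt$velocity)
  m <- 0.1 + 0.9 * vmag / (max(vmag) + 1e-12)
  zc <- .zscore(bt$curvature)
  zv <- .zscore(bt$velocity)
  # one shared posture-distortion trace per recording: the slow,
  # behavior-locked part of the deformation is common head geometry, so
  # every neuron couples to the same trace (with its own sign and size)
  # and residual artifact cannot be averaged away across the population
  posture <- 0.45 * zc + 0.4 * zv +
    0.55 * .zscore(.gauss_smooth(stats::rnorm(nt), 3, dt))
  A <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    und <- sin(2 * pi * 0.45 * bt$time_s + stats::runif(1, 0, 2 * pi)) +
      0.4 * .zscore(.gauss_smooth(stats::rnorm(nt), 0.4, dt))
    slow <- .zscore(.gauss_smooth(stats::rnorm(nt), 2, dt))
    g <- stats::rnorm(1, 0, 0.3)
    A[i, ] <- .zscore(m * und + 0.5 * m * slow + g * posture)
  }
  A
}

# zero-phase single-exponential (calcium) smoothing: a forward and a
# backward recursive pass, each DC gain 1, so planted tuning stays
# contemporaneous with behavior (the tuning analysis is zero-lag Pearson)
.calcium_filter <- function(x, tau_s, dt) {
  a <- exp(-dt / tau_s)
  fwd <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  rev(as.numeric(stats::filter(rev(fwd) * (1 - a), a, method = "recursive")))
}

# leaky integrator: ds/dt = -s/tau + x
.leaky_integrate <- function(x, tau_s, dt) {
  a <- exp(-dt / tau_s)
  as.numeric(stats::filter(x * dt, a, method = "recursive"))
}

# per-neuron drive from a tuning spec; returns list(drive, event_subset)
.neuron_drive <- function(spec, behavior, events, dt) {
  nt <- length(behavior$time_s)
  if (spec$behavior == "none")
    return(list(drive = rep(0, nt), event_subset = numeric(0)))
  b <- if (spec$behavior == "velocity") behavior$velocity else behavior$curvature
  ev_type <- if (spec$behavior == "velocity") "reversal" else "turn"
  if (spec$event_subset_fraction >= 1) {
    return(list(drive = spec$sign * .zscore(b), event_subset = numeric(0)))
  }
  ev <- events$time_s[events$type == ev_type]
  k <- round(spec$event_subset_fraction * length(ev))
  sub <- sort(sample(ev, k))
  drive <- rep(0, nt)
  for (t0 in sub)
    drive <- drive + exp(-(behavior$time_s - t0 - 0.5)^2 / (2 * 0.7^2))
  list(drive = spec$sign * drive, event_subset = sub)
}

#' Generate a two-channel fluorescence recording from behavior
#'
#' Per neuron i the emitted channels follow
#' \deqn{G_i(t) = bleach_i(t)(baseline + gain_i s_i(t)) + a_i A(t) + \epsilon}
#' \deqn{R_i(t) = bleach'_i(t) baseline'_i + a'_i A(t) + \epsilon'}
#' where \eqn{s_i} is the z-scored calcium signal built from the neuron's
#' tuning drive convolved with a single-exponential kernel (derivative-tuned
#' neurons leak-integrate the drive so that dF/dt, not F, tracks behavior),
#' and A(t) is a shared artifact trace coupled to body bending. Contiguous
#' tracking gaps are marked in \code{valid_mask}; sparse spike outliers are
#' injected into the data and recorded only in the ground truth.
#'
#' @param behavior list as returned by \code{\link{generate_behavior}} (or a
#'   bare \code{behavior_trace}; then no partial-event tuning is possible).
#' @param cfg the \code{synth_config} used to generate the behavior.
#' @return list with \code{recording} (\code{fluorescence_recording}) and
#'   \code{truth} (ground-truth components; see Details).
#' @export
generate_recording <- function(behavior, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (inherits(behavior, "behavior_trace"))
    behavior <- list(behavior = behavior,
                     events = data.frame(type = character(0), time_s = numeric(0),
                                         duration_s = numeric(0)))
  bt <- behavior$behavior
  dt <- 1 / cfg$volume_rate_hz
  nt <- length(bt$time_s)
  if (abs(nt * dt - cfg$duration_s) > 1.5 * dt)
    stop("behavior duration does not match cfg")
  n <- cfg$n_neurons
  validate_tuning_table(cfg$tuning_table, n)
  set.seed(cfg$seed + 2L)

  # signals
  signal <- matrix(0, n, nt)
  subsets <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- cfg$tuning_table[i, ]
    d <- .neuron_drive(spec, bt, behavior$events, dt)
    subsets[[i]] <- d$event_subset
    drv <- d$drive
    if (stats::sd(drv) > 0) {
      # intrinsic trial-to-trial variability: no neuron is a clean readout
      # of behavior, so no single neuron can match the population average
      drv <- drv + cfg$intrinsic_noise_frac * stats::sd(drv) *
        .zscore(.gauss_smooth(stats::rnorm(nt), 1.5, dt))
    }
    s <- .calcium_filter(drv, cfg$calcium_tau_s, dt)
    # derivative-tuned neurons integrate the drive with a 45 s leak: the
    # integral then carries little instantaneous-behavior information of
    # its own, so the tuning lives in dF/dt where it was planted
    if (spec$feature == "derivative") s <- .leaky_integrate(s, 45, dt)
    if (stats::sd(s) > 0) s <- .zscore(s)
    signal[i, ] <- s
  }
  gain_eff <- cfg$tuning_table$gain * cfg$signal_gain_global * cfg$signal_scale

  # shared artifact from undulatory bending; per-neuron susceptibility is
  # common to the channels and scales with each channel's brightness
  # (compression changes fluorophore density, hence fluorescence, in
  # proportion), which is what makes the per-neuron alpha fit cancel it
  artifact <- .artifact_matrix(bt, dt, n)
  suscept <- stats::runif(n, 0.5, 1.5)
  baseline_r <- stats::runif(n, 0.8, 1.2) * cfg$baseline
  a_g <- cfg$artifact_amplitude * suscept
  a_r <- cfg$artifact_amplitude * suscept * (baseline_r / cfg$baseline) *
    (1 + cfg$artifact_ratio_jitter * stats::runif(n, -1, 1))

  # bleaching
  if (is.null(cfg$bleach_tau_range)) {
    tau_g <- tau_r <- rep(Inf, n)
  } else {
    tau_g <- stats::runif(n, cfg$bleach_tau_range[1], cfg$bleach_tau_range[2])
    tau_r <- stats::runif(n, cfg$bleach_tau_range[1], cfg$bleach_tau_range[2])
  }
  bleach_g <- exp(-outer(1 / tau_g, bt$time_s))
  bleach_r <- exp(-outer(1 / tau_r, bt$time_s))

  # the artifact is a fluorophore-density modulation, so it bleaches with
  # the fluorophore (it sits inside the decay envelope)
  G <- bleach_g * (cfg$baseline + gain_eff * signal + a_g * artifact) +
    matrix(stats::rnorm(n * nt, sd = cfg$noise_sd), n, nt)
  R <- bleach_r * (baseline_r + a_r * artifact) +
    matrix(stats::rnorm(n * nt, sd = cfg$noise_sd), n, nt)

  # tracking gaps (missing) per neuron + occasional whole-volume dropouts
  valid <- matrix(TRUE, n, nt)
  for (i in seq_len(n)) {
    gaps <- .poisson_events(cfg$gap_rate_per_min, cfg$duration_s)
    for (g0 in gaps) {
      gl <- stats::runif(1, 1, 3)
      valid[i, bt$time_s >= g0 & bt$time_s < g0 + gl] <- FALSE
    }
  }
  for (v0 in .poisson_events(0.2, cfg$duration_s)) {
    valid[, bt$time_s >= v0 & bt$time_s < v0 + 0.5] <- FALSE
  }

  # spike outliers: present in the data, recorded only in ground truth
  outlier <- matrix(FALSE, n, nt)
  for (i in seq_len(n)) {
    n_out <- stats::rpois(1, cfg$outlier_rate_per_min / 60 * cfg$duration_s)
    if (n_out > 0) {
      idx <- sample(which(valid[i, ]), min(n_out, sum(valid[i, ])))
      outlier[i, idx] <- TRUE
      G[i, idx] <- G[i, idx] + sample(c(-1, 1), length(idx), TRUE) *
        stats::runif(length(idx), 6, 10) * stats::sd(G[i, ])
    }
  }

  epochs <- data.frame(name = "moving", start_s = 0, end_s = cfg$duration_s,
                       stringsAsFactors = FALSE)
  rec <- fluorescence_recording(time_s = bt$time_s, G = G, R = R,
                                valid_mask = valid, epochs = epochs)
  truth <- structure(list(
    behavior = bt, events = behavior$events, tuning_table = cfg$tuning_table,
    signal = signal, gain_eff = gain_eff,
    baseline_G = cfg$baseline, baseline_R = baseline_r,
    bleach_G = bleach_g, bleach_R = bleach_r,
    artifact = artifact, artifact_coupling_G = a_g, artifact_coupling_R = a_r,
    noise_sd = cfg$noise_sd, outlier_mask = outlier,
    event_subsets = subsets,
    immobilization_onset = NA_real_
  ), class = "synthetic_ground_truth")
  list(recording = rec, truth = truth)
}

#' Generate centerline series consistent with a behavior trace
#'
#' Builds 100-point worm centerlines (body length 1 mm) at 50 Hz whose
#' rigid-body displacement follows the true velocity (motion along the
#' centerline-derived head direction) and whose uniform body curvature per
#' frame equals the true mean curvature. Points are emitted in the camera
#' frame together with a smooth stage trajectory; the lab-frame position is
#' points + interpolated stage, mimicking a tracking stage that re-centers
#' the animal.
#'
#' @param behavior a \code{behavior_trace} (volume-rate grid).
#' @param cfg a \code{synth_config}.
#' @param frame_rate_hz centerline sampling rate.
#' @param body_length_mm worm length.
#' @return object of class \code{centerline_series}: \code{points}
#'   (frames x 100 x 2 array, mm, camera frame), \code{frame_time_s},
#'   \code{stage_xy} (frames x 2, mm), \code{stage_time_s}.
#' @export
generate_centerline_series <- function(behavior, cfg, frame_rate_hz = 50,
                                       body_length_mm = 1) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (any(!is.finite(behavior$velocity)) || any(!is.finite(behavior$curvature)))
    stop("behavior must be finite")
  set.seed(cfg$seed + 1L)
  dt <- 1 / frame_rate_hz
  ft <- seq(min(behavior$time_s), max(behavior$time_s), by = dt)
  v <- stats::approx(behavior$time_s, behavior$velocity, ft, rule = 2)$y
  kap <- stats::approx(behavior$time_s, behavior$curvature, ft, rule = 2)$y

  ns <- 100
  s <- seq(0, body_length_mm, length.out = ns)   # arc length from head tip
  nf <- length(ft)
  pts <- array(NA_real_, c(nf, ns, 2))
  head_xy <- c(0, 0)
  phi <- 0    # worm-frame heading of the head-direction chord (lab frame)
  for (f in seq_len(nf)) {
    # body-frame tangent angle: pointing tailward, uniform curvature kap[f]
    psi <- pi + kap[f] * s
    dxs <- diff(s)
    bx <- c(0, cumsum(cos(psi[-ns] + kap[f] * dxs / 2) * dxs))
    by <- c(0, cumsum(sin(psi[-ns] + kap[f] * dxs / 2) * dxs))
    # rotate so that the 10%->20% chord points along phi (the head direction
    # used for the velocity projection), then translate to the head position
    i10 <- which.min(abs(s - 0.10 * body_length_mm))
    i20 <- which.min(abs(s - 0.20 * body_length_mm))
    chord <- c(bx[i10] - bx[i20], by[i10] - by[i20])
    rot <- phi - atan2(chord[2], chord[1])
    cr <- cos(rot); sr <- sin(rot)
    px <- head_xy[1] + cr * bx - sr * by
    py <- head_xy[2] + sr * bx + cr * by
    pts[f, , 1] <- px
    pts[f, , 2] <- py
    head_xy <- head_xy + v[f] * dt * c(cos(phi), sin(phi))
  }
  # stage re-centers the animal: camera frame = lab frame - stage
  stage <- cbind(.gauss_smooth(pts[, 50, 1], 0.5, dt),
                 .gauss_smooth(pts[, 50, 2], 0.5, dt))
  cam <- pts
  cam[, , 1] <- pts[, , 1] - stage[, 1]
  cam[, , 2] <- pts[, , 2] - stage[, 2]
  centerline_series(points = cam, frame_time_s = ft,
                    stage_xy = stage, stage_time_s = ft)
}

#' Centerline series container
#'
#' @param points frames x 100 x 2 array of (x, y) in mm; head is index 1.
#'   Camera-frame coordinates (add interpolated stage position for the lab
#'   frame) unless \code{frame = "lab"}.
#' @param frame_time_s frame times, seconds.
#' @param stage_xy stage positions (mm), one row per stage query.
#' @param stage_time_s stage query times.
#' @param frame "camera" or "lab".
#' @return object of class \code{centerline_series}.
#' @export
centerline_series <- function(points, frame_time_s, stage_xy = NULL,
                              stage_time_s = NULL, frame = "camera") {
  stopifnot(length(dim(points)) == 3, dim(points)[2] == 100, dim(points)[3] == 2)
  if (dim(points)[1] != length(frame_time_s)) stop("frame count mismatch")
  if (any(diff(frame_time_s) <= 0)) stop("frame times must be increasing")
  if (is.null(stage_xy)) {
    stage_xy <- matrix(0, length(frame_time_s), 2)
    stage_time_s <- frame_time_s
    frame <- "lab"
  }
  structure(list(points = points, frame_time_s = frame_time_s,
                 stage_xy = stage_xy, stage_time_s = stage_time_s,
                 frame = frame),
            class = "centerline_series")
}

#' Generate a moving-then-immobilized recording
#'
#' Before \code{cfg$immobilization_onset_s} neurons are driven by
#' behavior-coupled latents (velocity, curvature and one behavior-independent
#' slow latent); after onset the behavior freezes (velocity ~ 0) and the
#' population is driven by a slow low-dimensional oscillator with new
#' loadings, in which a configurable fraction of neurons flip the sign of
#' their loading on the dominant latent relative to an AVA-like reference
#' pair (neurons 1 and 2, labeled AVAL/AVAR, which share their latent with
#' only a small independent component in both epochs). Epochs "moving",
#' "transition" and "immobile" are annotated; the transition is excluded
#' from epoch analyses downstream.
#'
#' @param cfg a \code{synth_config} with finite \code{immobilization_onset_s}.
#' @return list with \code{recording}, \code{truth} and \code{behavior}.
#'   \code{truth} additionally carries per-epoch loadings, the flipped
#'   neuron set, and the latent-model correlation matrices expected in each
#'   epoch (noise-free).
#' @export
generate_immobilization_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  onset <- cfg$immobilization_onset_s
  if (is.na(onset)) stop("immobilization onset outside recording")
  beh <- generate_behavior(cfg)
  bt <- beh$behavior
  dt <- 1 / cfg$volume_rate_hz
  nt <- length(bt$time_s)
  n <- cfg$n_neurons
  set.seed(cfg$seed + 3L)

  # freeze behavior after onset (5 s ramp)
  ramp <- pmin(pmax((onset + 5 - bt$time_s) / 5, 0), 1)
  bt$velocity <- bt$velocity * ramp
  bt$curvature <- bt$curvature * ramp
  moving_idx <- bt$time_s < onset
  immob_idx <- bt$time_s >= onset + cfg$transition_s

  # latents: moving = behavior-coupled; immobile = slow oscillator.
  # Behavior latents are centered and scaled within the moving epoch so
  # that neither epoch carries a mean offset (a step at onset would
  # masquerade as a photobleaching trend downstream); the crossfade takes
  # them smoothly to zero across the annotated transition.
  f_osc <- stats::runif(1, 0.015, 0.03)
  ph <- stats::runif(1, 0, 2 * pi)
  slow_noise <- .zscore(.gauss_smooth(stats::rnorm(nt), 8, dt))
  epoch_z <- function(x) (x - mean(x[moving_idx])) / stats::sd(x[moving_idx])
  lat_mov <- cbind(epoch_z(bt$velocity),
                   epoch_z(bt$curvature),
                   slow_noise)
  lat_imm <- cbind(sin(2 * pi * f_osc * bt$time_s + ph),
                   cos(2 * pi * f_osc * bt$time_s + ph),
                   slow_noise)

  # loadings; AVA-like pair dominated by latent 1
  L_mov <- matrix(stats::rnorm(n * 3, sd = 0.5), n, 3)
  L_mov[, 1] <- L_mov[, 1] + sample(c(-1, 1), n, TRUE) * 0.9
  L_mov[1, ] <- c(1, 0.05, 0.05)
  L_mov[2, ] <- c(1, -0.05, 0.05)
  flip_pool <- 3:n
  flipped <- sort(sample(flip_pool, round(cfg$flip_fraction * length(flip_pool))))
  L_imm <- L_mov
  L_imm[flipped, 1] <- -L_imm[flipped, 1]

  w <- pmin(pmax((bt$time_s - onset) / cfg$transition_s, 0), 1) # crossfade
  indep <- matrix(stats::rnorm(n * nt, sd = 0.15), n, nt)
  sig_mov <- L_mov %*% t(lat_mov)
  sig_imm <- L_imm %*% t(lat_imm)
  drive <- sweep(sig_mov, 2, 1 - w, `*`) + sweep(sig_imm, 2, w, `*`) + indep

  signal <- matrix(0, n, nt)
  for (i in seq_len(n)) signal[i, ] <-
    .zscore(.calcium_filter(drive[i, ], cfg$calcium_tau_s, dt))
  gain_eff <- rep(cfg$signal_gain_global * cfg$signal_scale, n)
  gain_eff[1:2] <- 2 * gain_eff[1:2]   # AVA transients dominate recordings

  artifact <- .artifact_matrix(bt, dt, n)
  suscept <- stats::runif(n, 0.5, 1.5)
  baseline_r <- stats::runif(n, 0.8, 1.2) * cfg$baseline
  a_g <- cfg$artifact_amplitude * suscept
  a_r <- cfg$artifact_amplitude * suscept * (baseline_r / cfg$baseline) *
    (1 + cfg$artifact_ratio_jitter * stats::runif(n, -1, 1))
  if (is.null(cfg$bleach_tau_range)) {
    tau_g <- tau_r <- rep(Inf, n)
  } else {
    tau_g <- stats::runif(n, cfg$bleach_tau_range[1], cfg$bleach_tau_range[2])
    tau_r <- stats::runif(n, cfg$bleach_tau_range[1], cfg$bleach_tau_range[2])
  }
  bleach_g <- exp(-outer(1 / tau_g, bt$time_s))
  bleach_r <- exp(-outer(1 / tau_r, bt$time_s))

  G <- bleach_g * (cfg$baseline + gain_eff * signal + a_g * artifact) +
    matrix(stats::rnorm(n * nt, sd = cfg$noise_sd), n, nt)
  R <- bleach_r * (baseline_r + a_r * artifact) +
    matrix(stats::rnorm(n * nt, sd = cfg$noise_sd), n, nt)
  valid <- matrix(TRUE, n, nt)

  epochs <- data.frame(
    name = c("moving", "transition", "immobile"),
    start_s = c(0, onset, onset + cfg$transition_s),
    end_s = c(onset, onset + cfg$transition_s, cfg$duration_s),
    stringsAsFactors = FALSE)
  labels <- c("AVAL", "AVAR", sprintf("N%03d", 3:n))
  rec <- fluorescence_recording(time_s = bt$time_s, G = G, R = R,
                                valid_mask = valid, epochs = epochs,
                                neuron_labels = labels)

  # expected (latent-model) correlation matrices per epoch
  exp_cor <- function(L, lat_var = c(1, 1, 1), noise_var = 0.15^2) {
    S <- L %*% diag(lat_var) %*% t(L) + diag(noise_var, nrow(L))
    stats::cov2cor(S)
  }
  truth <- structure(list(
    behavior = bt, events = beh$events, tuning_table = NULL,
    signal = signal, gain_eff = gain_eff,
    baseline_G = cfg$baseline, baseline_R = baseline_r,
    bleach_G = bleach_g, bleach_R = bleach_r,
    artifact = artifact, artifact_coupling_G = a_g, artifact_coupling_R = a_r,
    noise_sd = cfg$noise_sd,
    outlier_mask = matrix(FALSE, n, nt), event_subsets = NULL,
    immobilization_onset = onset,
    loadings_moving = L_mov, loadings_immobile = L_imm,
    flipped_neurons = flipped,
    rho_expected_moving = exp_cor(L_mov),
    rho_expected_immobile = exp_cor(L_imm)
  ), class = "synthetic_ground_truth")
  list(recording = rec, truth = truth, behavior = bt)
}
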