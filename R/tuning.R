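#' Pearson tuning of one neuron to one behavior
#'
#' Standard Pearson correlation over paired valid (non-interpolated)
#' points. Errors on constant input, where the coefficient is undefined.
#'
#' @param activity neuron activity series (F_mc or dF/dt).
#' @param behavior behavior series on the same grid.
#' @param valid logical mask of points to use.
#' @return Pearson rho.
#' @export
pearson_tuning <- function(activity, behavior, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(activity))
  valid <- valid & is.finite(activity) & is.finite(behavior)
  if (sum(valid) < 10) stop("need >= 10 paired valid points")
  a <- activity[valid]; b <- behavior[valid]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant series")
  stats::cor(a, b)
}

#' Shuffle null distribution for tuning significance
#'
#' For each neuron the activity is time-reversed and circularly shifted
#' against behavior by a uniform random lag, and the Pearson correlation
#' recomputed; M replicates per neuron are pooled into one M x N sample.
#' This preserves each neuron's autocorrelation while destroying its
#' alignment to behavior. Lags are drawn uniformly over [0, T); the exact
#' all-lag correlation function is evaluated once per neuron by FFT and
#' sampled, so the null is exact for the circular-shift family.
#'
#' @param activity_matrix neurons x time matrix (series as used for the
#'   observed correlations, i.e. already interpolated/restricted).
#' @param behavior behavior series.
#' @param M replicates per neuron (>= 100).
#' @param seed RNG seed.
#' @return matrix M x N of null correlations (class \code{shuffle_null}).
#' @export
shuffle_null <- function(activity_matrix, behavior, M = 500, seed = 0) {
  activity_matrix <- as.matrix(activity_matrix)
  nt <- ncol(activity_matrix)
  if (nt < 2) stop("recording shorter than 2 samples")
  if (M < 100) stop("M must be >= 100")
  set.seed(as.integer(seed))
  n <- nrow(activity_matrix)
  b0 <- behavior - mean(behavior)
  sb <- sqrt(sum(b0^2))
  if (sb == 0) stop("undefined correlation: constant series")
  fb <- stats::fft(b0)
  null <- matrix(NA_real_, M, n)
  for (i in seq_len(n)) {
    x <- rev(activity_matrix[i, ])
    x0 <- x - mean(x)
    sx <- sqrt(sum(x0^2))
    if (sx == 0) stop("undefined correlation: constant series")
    # rho(lag) for all circular lags of x against b
    cc <- Re(stats::fft(fb * Conj(stats::fft(x0)), inverse = TRUE)) / nt
    rho_all <- cc / (sx * sb)
    lags <- sample.int(nt, M, replace = TRUE)   # uniform over [0, T)
    null[, i] <- rho_all[lags]
  }
  structure(null, class = c("shuffle_null", "matrix"))
}

#' Classify tuning significance with pooled shuffle null and Bonferroni
#'
#' One-sided empirical p-values against the pooled M x N null (upper tail
#' for positive rho, lower for negative), compared with the Bonferroni
#' threshold \code{family_alpha / (2 * N_neurons)} (the 2N accounts for
#' testing both F and dF/dt per neuron). A neuron-feature pair is called
#' significant only when additionally |rho| >= \code{rho_min}. Zero tail
#' counts are reported as p = 0 with \code{p_floor = 1/(M*N)} giving the
#' shuffle resolution.
#'
#' @param rhos named numeric vector (or data.frame with columns neuron,
#'   feature, behavior, rho) of observed correlations.
#' @param null a \code{shuffle_null} matrix (pooled).
#' @param N_neurons N used in the Bonferroni factor 2N.
#' @param family_alpha family-wise error level.
#' @param rho_min minimum absolute correlation for a significant call.
#' @return data.frame of class \code{tuning_result}: rho, p_empirical,
#'   significant, threshold_used, p_floor (plus any id columns passed in).
#' @export
classify_significance <- function(rhos, null, N_neurons,
                                  family_alpha = 0.05, rho_min = 0.4) {
  if (length(null) == 0) stop("null is empty")
  pool <- as.numeric(null)
  threshold <- family_alpha / (2 * N_neurons)
  if (length(pool) < 1 / threshold)
    warning("shuffle resolution insufficient to reach threshold")
  df <- if (is.data.frame(rhos)) rhos else data.frame(rho = as.numeric(rhos))
  p <- vapply(df$rho, function(r) {
    if (r >= 0) mean(pool >= r) else mean(pool <= r)
  }, numeric(1))
  df$p_empirical <- p
  df$significant <- (p < threshold) & (abs(df$rho) >= rho_min)
  df$threshold_used <- threshold
  df$p_floor <- 1 / length(pool)
  class(df) <- c("tuning_result", "data.frame")
  df
}

#' Tuning analysis of a preprocessed recording
#'
#' Computes Pearson tuning of every neuron's activity and temporal
#' derivative to velocity and curvature, builds a circular-shift shuffle
#' null per feature, and classifies significance with the Bonferroni
#' threshold 0.05/(2N) and the |rho| >= 0.4 floor. Observed correlations
#' use valid, non-interpolated points only; the shuffle operates on the
#' interpolated series so the circular shift is well defined.
#'
#' @param act a \code{neuron_activity}.
#' @param behavior a \code{behavior_trace} on the same volume grid.
#' @param M shuffle replicates per neuron.
#' @param family_alpha family-wise error level.
#' @param rho_min absolute correlation floor.
#' @param seed RNG seed for the shuffle.
#' @return \code{tuning_result} data.frame, one row per
#'   (neuron, feature, behavior).
#' @export
tuning_analysis <- function(act, behavior, M = 500, family_alpha = 0.05,
                            rho_min = 0.4, seed = 0) {
  stopifnot(inherits(act, "neuron_activity"),
            inherits(behavior, "behavior_trace"))
  n <- nrow(act$F_mc)
  combos <- expand.grid(neuron = seq_len(n),
                        feature = c("activity", "derivative"),
                        behavior = c("velocity", "curvature"),
                        stringsAsFactors = FALSE)
  combos$rho <- NA_real_
  for (k in seq_len(nrow(combos))) {
    i <- combos$neuron[k]
    x <- if (combos$feature[k] == "activity") act$F_mc[i, ] else act$dFdt[i, ]
    b <- if (combos$behavior[k] == "velocity") behavior$velocity
         else behavior$curvature
    combos$rho[k] <- pearson_tuning(x, b, act$valid_mask[i, ])
  }
  out <- NULL
  for (beh in c("velocity", "curvature")) {
    b <- if (beh == "velocity") behavior$velocity else behavior$curvature
    for (feat in c("activity", "derivative")) {
      mat <- if (feat == "activity") act$F_mc else act$dFdt
      null <- shuffle_null(mat, b, M = M,
                           seed = seed + match(feat, c("activity", "derivative")) +
                             2L * match(beh, c("velocity", "curvature")))
      sub <- combos[combos$feature == feat & combos$behavior == beh, ]
      res <- classify_significance(sub, null, N_neurons = n,
                                   family_alpha = family_alpha,
                                   rho_min = rho_min)
      out <- rbind(out, res)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("tuning_result", "data.frame")
  out
}
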