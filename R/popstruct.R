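#' Pairwise correlation structure of a window
#'
#' Pearson correlations of every neuron pair over the valid points of a
#' time window. Neurons constant (or insufficiently sampled) in the window
#' get missing rows/columns with a warning.
#'
#' @param act a \code{neuron_activity} (or list with a neurons x time
#'   matrix in \code{F_mc}, \code{time_s}, \code{valid_mask}).
#' @param window c(start_s, end_s).
#' @param source "activity" (F_mc, default) or "derivative" (dF/dt).
#' @param epoch_name label stored with the result.
#' @param min_window_s minimum window length.
#' @return object of class \code{correlation_structure}: \code{rho}
#'   (N x N), \code{epoch}, \code{window}, \code{cluster_order} (NULL
#'   until \code{\link{cluster_order}} is applied).
#' @export
correlation_matrix <- function(act, window, source = c("activity", "derivative"),
                               epoch_name = "", min_window_s = 60) {
  source <- match.arg(source)
  if (diff(window) < min_window_s)
    stop(sprintf("window must span >= %g s", min_window_s))
  M <- if (source == "activity") act$F_mc else act$dFdt
  if (nrow(M) < 2) stop("need >= 2 neurons")
  idx <- act$time_s >= window[1] & act$time_s < window[2]
  X <- t(M[, idx, drop = FALSE])
  if (!is.null(act$valid_mask)) {
    V <- t(act$valid_mask[, idx, drop = FALSE])
    X[!V] <- NA
  }
  ok <- apply(X, 2, function(x) sum(is.finite(x)) >= 3 &&
                stats::sd(x, na.rm = TRUE) > 0)
  if (any(!ok)) warning(sprintf("%d constant/undersampled neuron(s) in window",
                                sum(!ok)))
  rho <- matrix(NA_real_, ncol(X), ncol(X))
  rho[ok, ok] <- suppressWarnings(
    stats::cor(X[, ok, drop = FALSE], use = "pairwise.complete.obs"))
  diag(rho)[ok] <- 1
  structure(list(rho = rho, epoch = epoch_name, window = window,
                 source = source, cluster_order = NULL),
            class = "correlation_structure")
}

#' Agglomerative clustering order of a correlation matrix
#'
#' Average-linkage hierarchical clustering on the distance 1 - rho; the
#' returned permutation is the dendrogram leaf order (deterministic for a
#' given matrix).
#'
#' @param rho N x N correlation matrix (or a
#'   \code{correlation_structure}).
#' @return integer permutation of 1..N.
#' @export
cluster_order <- function(rho) {
  if (inherits(rho, "correlation_structure")) rho <- rho$rho
  if (nrow(rho) < 2) stop("need >= 2 neurons")
  if (any(!is.finite(rho))) stop("missing rows in correlation matrix")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  hc$order
}

#' Dissimilarity between two correlation structures
#'
#' Root mean square of the change in pairwise correlations over unordered
#' off-diagonal pairs (i < j); pairs missing in either matrix are excluded.
#' A pseudometric on correlation matrices. \code{squared = TRUE} returns
#' the mean squared change without the root.
#'
#' @param rho,rho_prime N x N matrices (or \code{correlation_structure}s)
#'   in the same neuron order.
#' @param squared skip the square root.
#' @return scalar dissimilarity.
#' @export
dissimilarity <- function(rho, rho_prime, squared = FALSE) {
  if (inherits(rho, "correlation_structure")) rho <- rho$rho
  if (inherits(rho_prime, "correlation_structure")) rho_prime <- rho_prime$rho
  if (!all(dim(rho) == dim(rho_prime))) stop("shape mismatch")
  ut <- upper.tri(rho)
  d2 <- (rho_prime[ut] - rho[ut])^2
  m <- mean(d2, na.rm = TRUE)
  if (squared) m else sqrt(m)
}

#' Compare correlation-structure change across recording groups
#'
#' For each moving-to-immobile recording, the dissimilarity between the
#' moving-epoch and immobile-epoch correlation matrices is computed, with
#' the annotated transition window excluded. For each moving-only control
#' recording, the correlation structure of the first 30% of the recording
#' is compared to that of the latter 60%, mimicking the relative timing of
#' the treated group. Groups are compared by Welch's unequal-variance
#' t-test.
#'
#' @param treated list of \code{neuron_activity} objects whose epochs
#'   annotate "moving" and "immobile" (transition excluded by annotation).
#' @param controls list of moving-only \code{neuron_activity} objects.
#' @param source "activity" or "derivative".
#' @return list: \code{treated} and \code{control} dissimilarity vectors,
#'   group medians, and \code{p_value} (Welch test, one-sided greater).
#' @export
epoch_compare <- function(treated, controls, source = "activity") {
  if (length(treated) < 2 || length(controls) < 2)
    stop("need >= 2 recordings per group")
  d_treat <- vapply(treated, function(act) {
    ep <- act$epochs
    if (is.null(ep) || !all(c("moving", "immobile") %in% ep$name))
      stop("missing epoch annotation (moving/immobile)")
    mw <- unlist(ep[ep$name == "moving", c("start_s", "end_s")])
    iw <- unlist(ep[ep$name == "immobile", c("start_s", "end_s")])
    dissimilarity(correlation_matrix(act, mw, source, "moving"),
                  correlation_matrix(act, iw, source, "immobile"))
  }, numeric(1))
  d_ctrl <- vapply(controls, function(act) {
    t0 <- min(act$time_s); t1 <- max(act$time_s)
    dur <- t1 - t0
    w1 <- c(t0, t0 + 0.3 * dur)
    w2 <- c(t1 - 0.6 * dur, t1)
    dissimilarity(correlation_matrix(act, w1, source, "early"),
                  correlation_matrix(act, w2, source, "late"))
  }, numeric(1))
  test <- stats::t.test(d_treat, d_ctrl, alternative = "greater",
                        var.equal = FALSE)
  list(treated = d_treat, control = d_ctrl,
       median_treated = stats::median(d_treat),
       median_control = stats::median(d_ctrl),
       p_value = test$p.value, statistic = unname(test$statistic))
}

#' Epoch-fit PCA state-space projection
#'
#' Principal components are determined from one fit window only (e.g. the
#' immobilized portion of a recording): centering (and optional variance
#' scaling) and the component loadings come from that window, and the
#' entire recording is then projected with those parameters. Component
#' signs are fixed by making each component's largest-magnitude loading
#' positive.
#'
#' @param act a \code{neuron_activity}.
#' @param fit_window c(start_s, end_s) used to fit the components.
#' @param n_components number of components to keep.
#' @param source "activity" or "derivative".
#' @param scale. also scale neurons to unit variance on the fit window.
#' @return object of class \code{state_space_projection}: \code{loadings}
#'   (neurons x k, orthonormal), \code{explained_var} (fractions,
#'   non-increasing), \code{projection} (time x k, whole recording),
#'   \code{time_s}, \code{fit_window}, \code{source}.
#' @export
pca_state_space <- function(act, fit_window, n_components = 3,
                            source = c("activity", "derivative"),
                            scale. = FALSE) {
  source <- match.arg(source)
  M <- if (source == "activity") act$F_mc else act$dFdt
  idx <- act$time_s >= fit_window[1] & act$time_s < fit_window[2]
  if (sum(idx) < n_components) stop("fit window shorter than n_components")
  Xfit <- t(M[, idx, drop = FALSE])
  ctr <- colMeans(Xfit)
  scl <- if (scale.) apply(Xfit, 2, stats::sd) else rep(1, ncol(Xfit))
  pc <- stats::prcomp(Xfit, center = ctr, scale. = if (scale.) scl else FALSE)
  k <- min(n_components, sum(pc$sdev > 1e-12))
  if (k < n_components)
    warning(sprintf("rank %d < %d requested components", k, n_components))
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  Xall <- sweep(sweep(t(M), 2, ctr), 2, scl, `/`)
  proj <- Xall %*% L
  structure(list(loadings = L, explained_var = ev[seq_len(k)],
                 projection = proj, time_s = act$time_s,
                 fit_window = fit_window, source = source),
            class = "state_space_projection")
}

#' Correlation shift of every neuron relative to reference neurons
#'
#' Computes each non-reference neuron's Pearson correlation to each
#' reference neuron (e.g. AVAL/AVAR) separately within two epochs, and
#' tests whether correlations shift between epochs with a paired Wilcoxon
#' signed-rank test on (rho_b - rho_a) over all (neuron, reference) pairs.
#'
#' @param act a \code{neuron_activity} with \code{neuron_labels}.
#' @param reference_ids labels or indices of the reference neurons.
#' @param epoch_a,epoch_b c(start_s, end_s) windows.
#' @return list: data.frame \code{shifts} (neuron, reference, rho_a,
#'   rho_b, sorted by rho_a), \code{p_value} (Wilcoxon),
#'   \code{median_shift}, \code{reference_correlation} (rho between the
#'   references themselves per epoch, when two or more references given).
#' @export
reference_correlation_shift <- function(act, reference_ids, epoch_a, epoch_b) {
  n <- nrow(act$F_mc)
  if (is.character(reference_ids)) {
    if (is.null(act$neuron_labels)) stop("recording has no neuron labels")
    ref <- match(reference_ids, act$neuron_labels)
    if (any(is.na(ref))) stop("reference neurons not found")
  } else ref <- as.integer(reference_ids)
  win_idx <- function(w) act$time_s >= w[1] & act$time_s < w[2]
  ia <- win_idx(epoch_a); ib <- win_idx(epoch_b)
  for (r in ref) {
    if (stats::sd(act$F_mc[r, ia]) == 0 || stats::sd(act$F_mc[r, ib]) == 0)
      stop("reference neuron constant in an epoch")
  }
  others <- setdiff(seq_len(n), ref)
  shifts <- do.call(rbind, lapply(ref, function(r) {
    data.frame(
      neuron = others, reference = r,
      rho_a = apply(act$F_mc[others, ia, drop = FALSE], 1,
                    stats::cor, y = act$F_mc[r, ia]),
      rho_b = apply(act$F_mc[others, ib, drop = FALSE], 1,
                    stats::cor, y = act$F_mc[r, ib]))
  }))
  shifts <- shifts[order(shifts$rho_a), ]
  rownames(shifts) <- NULL
  diffs <- shifts$rho_b - shifts$rho_a
  wt <- stats::wilcox.test(shifts$rho_b, shifts$rho_a, paired = TRUE,
                           exact = FALSE)
  ref_cor <- if (length(ref) >= 2) {
    c(epoch_a = stats::cor(act$F_mc[ref[1], ia], act$F_mc[ref[2], ia]),
      epoch_b = stats::cor(act$F_mc[ref[1], ib], act$F_mc[ref[2], ib]))
  } else NULL
  list(shifts = shifts, p_value = wt$p.value,
       median_shift = stats::median(diffs),
       reference_correlation = ref_cor)
}
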