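#' Hold out the middle 40% of a recording as a test set
#'
#' Test indices are rows floor(0.3 T) .. floor(0.7 T) - 1 (0-based), i.e.
#' the middle 40% of the recording; the two flanks form the training set.
#'
#' @param T_len number of timepoints.
#' @return list with integer vectors \code{train} and \code{test}
#'   (1-based), disjoint and exhaustive.
#' @export
split_train_test <- function(T_len) {
  if (T_len < 10) stop("need at least 10 timepoints")
  test <- (floor(0.3 * T_len) + 1L):floor(0.7 * T_len)
  list(train = setdiff(seq_len(T_len), test), test = test)
}

#' Build the z-scored feature matrix F | dF/dt
#'
#' Columns are each neuron's motion-corrected activity followed by each
#' neuron's temporal derivative (2n columns). Scaling to zero mean and
#' unit variance is computed on training rows only and applied everywhere,
#' so weight magnitudes are comparable and no test-set statistics leak
#' into the fit. Columns constant on the training rows are dropped with a
#' warning.
#'
#' @param act a \code{neuron_activity} (or a list with \code{F_mc} and
#'   \code{dFdt} matrices).
#' @param split output of \code{\link{split_train_test}}.
#' @return list: \code{X} (T x 2n), \code{means}, \code{sds} (training
#'   scaling), \code{kept} (logical per column), \code{neuron} (column ->
#'   neuron index), \code{feature} (column -> "F" or "dFdt").
#' @export
build_features <- function(act, split) {
  n <- nrow(act$F_mc)
  if (is.null(n) || n == 0) stop("no neurons")
  X <- cbind(t(act$F_mc), t(act$dFdt))
  colnames(X) <- c(sprintf("F_%d", seq_len(n)), sprintf("dFdt_%d", seq_len(n)))
  mu <- colMeans(X[split$train, , drop = FALSE])
  sdv <- apply(X[split$train, , drop = FALSE], 2, stats::sd)
  kept <- is.finite(sdv) & sdv > 0
  if (any(!kept))
    warning(sprintf("dropping %d constant feature column(s): %s",
                    sum(!kept), paste(colnames(X)[!kept], collapse = ", ")))
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, mu[kept]), 2, sdv[kept], `/`)
  list(X = Xs, means = mu, sds = sdv, kept = kept,
       neuron = rep(seq_len(n), 2)[kept],
       feature = rep(c("F", "dFdt"), each = n)[kept])
}

#' Mean-subtracted coefficient of determination (RMS-squared)
#'
#' Both series are mean-subtracted over the evaluation window, then the
#' conventional R-squared is computed there:
#' \code{1 - sum((z - zhat)^2) / sum(z^2)} with \code{z = y - mean(y)} and
#' \code{zhat = yhat - mean(yhat)}. Ranges over (-Inf, 1]; a constant
#' prediction scores exactly 0.
#'
#' @param y observed behavior.
#' @param y_hat model prediction.
#' @param window indices of the evaluation window (default: all).
#' @return scalar RMS-squared.
#' @export
rms_r2 <- function(y, y_hat, window = seq_along(y)) {
  if (length(window) == 0) stop("empty evaluation window")
  z <- y[window] - mean(y[window])
  zh <- y_hat[window] - mean(y_hat[window])
  sst <- sum(z^2)
  if (sst == 0) stop("undefined RMS-squared: constant y on window")
  1 - sum((z - zh)^2) / sst
}

# closed-form ridge on centered target: w = (X'X + lambda I)^{-1} X'(y - ybar)
.ridge_solve <- function(X, y, lambda) {
  p <- ncol(X)
  ybar <- mean(y)
  A <- crossprod(X) + diag(lambda, p)
  b <- crossprod(X, y - ybar)
  w <- tryCatch(solve(A, b), error = function(e) {
    warning("singular ridge system; falling back to pseudo-inverse")
    MASS::ginv(A) %*% b
  })
  list(w = as.numeric(w), beta = ybar)
}

# last contiguous third of the training rows is the inner validation chunk
.inner_split <- function(train) {
  nv <- max(1L, floor(length(train) / 3))
  list(fit = train[seq_len(length(train) - nv)],
       val = train[(length(train) - nv + 1L):length(train)])
}

#' Fit the ridge population decoder
#'
#' Minimizes the penalized squared training error
#' \code{sum((y - yhat)^2) + lambda * ||W||^2} over weights on the z-scored
#' features, with an unpenalized intercept (equal to the training mean of
#' the target, since features are training-centered). The ridge strength is
#' chosen on an inner split of the training rows: the model is fit on the
#' first two thirds for each lambda in the grid and the value with the best
#' RMS-squared on the held-back last third wins; the final model is refit
#' on the full training set at that lambda.
#'
#' @param feats output of \code{\link{build_features}}.
#' @param target behavior series (velocity or curvature), length T.
#' @param split output of \code{\link{split_train_test}}.
#' @param lambda_grid candidate ridge strengths (default 30 log-spaced
#'   values in [1e-3, 1e6]).
#' @param target_name "velocity" or "curvature" (metadata).
#' @return object of class \code{population_decoder}: weights \code{W}
#'   (per kept column), \code{W_F}/\code{W_dFdt} (per neuron, zeros for
#'   dropped columns), intercept \code{beta}, \code{lambda}, scaling,
#'   split, predictions and train/test RMS-squared.
#' @export
fit_ridge <- function(feats, target, split,
                      lambda_grid = 10^seq(-3, 6, length.out = 30),
                      target_name = "behavior") {
  X <- feats$X
  if (any(!is.finite(target[split$train]))) stop("target not finite on train")
  inner <- .inner_split(split$train)
  val_score <- vapply(lambda_grid, function(lam) {
    f <- .ridge_solve(X[inner$fit, , drop = FALSE], target[inner$fit], lam)
    pred <- X[inner$val, , drop = FALSE] %*% f$w + f$beta
    rms_r2(target[inner$val], as.numeric(pred))
  }, numeric(1))
  lambda <- lambda_grid[which.max(val_score)]
  fit <- .ridge_solve(X[split$train, , drop = FALSE], target[split$train], lambda)
  .decoder_from_fit(fit$w, fit$beta, lambda, feats, target, split,
                    variant = "ridge", target_name = target_name)
}

# package a weight vector into a population_decoder with scores
.decoder_from_fit <- function(w, beta, lambda, feats, target, split,
                              variant, target_name, mu = NA_real_,
                              l1_ratio = NA_real_) {
  n <- length(feats$kept) / 2
  W_F <- rep(0, n); W_d <- rep(0, n)
  W_F[feats$neuron[feats$feature == "F"]] <- w[feats$feature == "F"]
  W_d[feats$neuron[feats$feature == "dFdt"]] <- w[feats$feature == "dFdt"]
  pred <- as.numeric(feats$X %*% w + beta)
  structure(list(
    W = w, W_F = W_F, W_dFdt = W_d, beta = beta, lambda = lambda,
    feature_means = feats$means, feature_sds = feats$sds, kept = feats$kept,
    target = target_name, split = split, variant = variant,
    mu = mu, l1_ratio = l1_ratio,
    prediction = pred,
    rms_r2_train = rms_r2(target, pred, split$train),
    rms_r2_test = rms_r2(target, pred, split$test),
    rms_r2_all = rms_r2(target, pred)
  ), class = "population_decoder")
}

#' @export
print.population_decoder <- function(x, ...) {
  cat(sprintf("<population_decoder %s/%s> lambda %.3g, RMS^2 train %.3f test %.3f\n",
              x$variant, x$target, x$lambda, x$rms_r2_train, x$rms_r2_test))
  invisible(x)
}

#' Best-single-neuron (BSN) baseline decoder
#'
#' For every single feature column (one neuron's activity or derivative) a
#' slope and intercept are fit by least squares on the training rows; the
#' feature with the best training RMS-squared is selected (training-based
#' selection; test rows never inform the choice), and its test performance
#' reported.
#'
#' @inheritParams fit_ridge
#' @return a \code{population_decoder} with exactly one nonzero weight and
#'   a \code{selected} element (column index, neuron, feature).
#' @export
fit_best_single_neuron <- function(feats, target, split,
                                   target_name = "behavior") {
  X <- feats$X
  tr <- split$train
  ytr <- target[tr]
  scores <- numeric(ncol(X))
  slopes <- numeric(ncol(X)); inters <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    xj <- X[tr, j]
    b1 <- stats::cov(xj, ytr) / stats::var(xj)
    b0 <- mean(ytr) - b1 * mean(xj)
    slopes[j] <- b1; inters[j] <- b0
    scores[j] <- rms_r2(ytr, b1 * xj + b0)
  }
  jbest <- which.max(scores)
  w <- rep(0, ncol(X)); w[jbest] <- slopes[jbest]
  dec <- .decoder_from_fit(w, inters[jbest], 0, feats, target, split,
                           variant = "bsn", target_name = target_name)
  dec$selected <- list(column = jbest, neuron = feats$neuron[jbest],
                       feature = feats$feature[jbest])
  dec
}

#' Truncated-model performance curve and N90
#'
#' Neurons are sorted in descending order of \code{max(|W_F|, |W_dFdt|)}
#' (ties broken by neuron index). For each N the weights of all but the
#' top-N neurons are zeroed, keeping relative weights fixed, and only a
#' scalar gain and offset are refit on the training rows; performance is
#' RMS-squared over the entire recording (train and test), since the
#' relative weights are frozen and overfitting is not a concern. N90 is
#' the smallest N reaching 90% of the full model's whole-recording
#' performance (the N = n entry of this same curve).
#'
#' @param decoder a fitted \code{population_decoder}.
#' @param feats the feature set it was fit on.
#' @param target behavior series.
#' @param refit_gain refit scalar gain/offset per truncation (default) or
#'   freeze the prediction as-is.
#' @param frac performance fraction defining N90.
#' @return object of class \code{restricted_model_curve}: \code{order}
#'   (neuron indices by descending weight), \code{performance} (RMS^2_all
#'   per N), \code{gain}, \code{offset}, \code{N90} (NA when unreached),
#'   \code{full_performance}.
#' @export
restricted_curve <- function(decoder, feats, target, refit_gain = TRUE,
                             frac = 0.9) {
  n <- length(decoder$W_F)
  amp <- pmax(abs(decoder$W_F), abs(decoder$W_dFdt))
  ord <- order(-amp, seq_len(n))
  split <- decoder$split
  perf <- numeric(n); gain <- numeric(n); offset <- numeric(n)
  for (N in seq_len(n)) {
    keep_neurons <- ord[seq_len(N)]
    keep_cols <- feats$neuron %in% keep_neurons
    p <- as.numeric(feats$X[, keep_cols, drop = FALSE] %*%
                      decoder$W[keep_cols]) + decoder$beta
    if (refit_gain) {
      tr <- split$train
      if (stats::var(p[tr]) > 0) {
        g <- stats::cov(p[tr], target[tr]) / stats::var(p[tr])
      } else g <- 0
      o <- mean(target[tr]) - g * mean(p[tr])
    } else { g <- 1; o <- 0 }
    gain[N] <- g; offset[N] <- o
    perf[N] <- rms_r2(target, g * p + o)
  }
  full <- perf[n]
  if (full <= 0) {
    warning("full-model performance <= 0; N90 undefined")
    n90 <- NA_integer_
  } else {
    hit <- which(perf >= frac * full)
    n90 <- if (length(hit)) hit[1] else NA_integer_
  }
  structure(list(order = ord, performance = perf, gain = gain,
                 offset = offset, N90 = n90, full_performance = full,
                 frac = frac),
            class = "restricted_model_curve")
}

#' Neurons shared by two N90 sets
#'
#' Intersection of the top-N90 neuron sets of two restricted-model curves
#' (e.g. velocity and curvature decoders of one recording).
#'
#' @param curve_a,curve_b \code{restricted_model_curve} objects with
#'   defined N90.
#' @return integer vector of shared neuron indices.
#' @export
intersect_n90 <- function(curve_a, curve_b) {
  if (is.na(curve_a$N90) || is.na(curve_b$N90)) stop("N90 undefined")
  intersect(curve_a$order[seq_len(curve_a$N90)],
            curve_b$order[seq_len(curve_b$N90)])
}

#' Fit a penalty-variant population decoder
#'
#' \describe{
#'   \item{ridge}{the standard model (\code{\link{fit_ridge}}).}
#'   \item{accel}{adds \code{mu * (dy/dt - dyhat/dt)^2} to the training
#'     error, with derivatives taken by the Gaussian derivative filter;
#'     solved in closed form via the augmented normal equations.}
#'   \item{elasticnet}{replaces the ridge penalty by
#'     \code{lambda * (r ||W||_1 + (1 - r) ||W||_2^2)}; solved by
#'     coordinate descent (glmnet) with the penalty mapped exactly onto
#'     glmnet's parameterization.}
#' }
#' Lambda is selected on the same inner training/validation split as
#' \code{fit_ridge}.
#'
#' @inheritParams fit_ridge
#' @param variant "ridge", "accel" or "elasticnet".
#' @param mu acceleration-penalty weight (accel variant).
#' @param l1_ratio L1 ratio r (elasticnet variant).
#' @param deriv_width_s width of the Gaussian derivative filter used for
#'   the acceleration penalty.
#' @param time_s time axis (required for the accel variant).
#' @return a \code{population_decoder}.
#' @export
fit_variant <- function(feats, target, split, variant = c("ridge", "accel",
                                                          "elasticnet"),
                        lambda_grid = 10^seq(-3, 6, length.out = 30),
                        mu = 10, l1_ratio = 0.01, deriv_width_s = 2.3,
                        time_s = NULL, target_name = "behavior") {
  variant <- match.arg(variant)
  if (variant == "ridge")
    return(fit_ridge(feats, target, split, lambda_grid, target_name))
  if (variant == "accel") {
    if (is.null(time_s)) stop("accel variant needs time_s")
    dec <- .fit_accel(feats, target, split, lambda_grid, mu, deriv_width_s,
                      time_s, target_name)
    return(dec)
  }
  .fit_elasticnet(feats, target, split, lambda_grid, l1_ratio, target_name)
}

# ridge + acceleration penalty: augmented least squares.
# C = |y_c - Xc w|^2 + mu |D y - D X w|^2 + lambda |w|^2 over train rows,
# beta = mean(y_train) (features are training-centered).
.fit_accel <- function(feats, target, split, lambda_grid, mu, deriv_width_s,
                       time_s, target_name) {
  dt <- .check_time_uniform(time_s)
  k <- .dog_kernel(deriv_width_s, dt)
  dmat <- function(M) apply(M, 2, .conv_edge_replicate, kernel = k)
  solve_rows <- function(rows, lam) {
    X <- feats$X[rows, , drop = FALSE]
    y <- target[rows]
    DX <- dmat(X)
    Dy <- .conv_edge_replicate(y, k)
    ybar <- mean(y)
    A <- crossprod(X) + mu * crossprod(DX) + diag(lam, ncol(X))
    b <- crossprod(X, y - ybar) + mu * crossprod(DX, Dy)
    w <- tryCatch(solve(A, b), error = function(e) MASS::ginv(A) %*% b)
    list(w = as.numeric(w), beta = ybar)
  }
  inner <- .inner_split(split$train)
  val_score <- vapply(lambda_grid, function(lam) {
    f <- solve_rows(inner$fit, lam)
    pred <- feats$X[inner$val, , drop = FALSE] %*% f$w + f$beta
    rms_r2(target[inner$val], as.numeric(pred))
  }, numeric(1))
  lambda <- lambda_grid[which.max(val_score)]
  fit <- solve_rows(split$train, lambda)
  .decoder_from_fit(fit$w, fit$beta, lambda, feats, target, split,
                    variant = "accel", target_name = target_name, mu = mu)
}

# elasticnet via glmnet: our cost  RSS + lambda (r|W|_1 + (1-r)|W|_2^2).
# glmnet minimizes (1/2n)RSS + lg (a|W|_1 + (1-a)/2 |W|_2^2) after
# standardizing the response; supplying y pre-standardized (population SD s)
# and back-scaling w by s makes the effective original-scale penalties
# lg*a*s on |W|_1 and lg*(1-a)/2 on |W|_2^2, so
#   a = r / (r + 2 s (1 - r)),  lg = lambda (1 - r) / (n (1 - a))
# (pure lasso r = 1: a = 1, lg = lambda / (2 n s)). Verified against the
# orthogonal-design soft-threshold closed form in the tests.
.fit_elasticnet <- function(feats, target, split, lambda_grid, l1_ratio,
                            target_name) {
  r <- l1_ratio
  fit_rows <- function(rows, lam) {
    n_obs <- length(rows)
    y <- target[rows]
    s <- sqrt(mean((y - mean(y))^2))
    if (s == 0) stop("constant target on fit rows")
    if (r >= 1) {
      a <- 1
      lg <- lam / (2 * n_obs * s)
    } else {
      a <- r / (r + 2 * s * (1 - r))
      lg <- lam * (1 - r) / (n_obs * (1 - a))
    }
    m <- glmnet::glmnet(feats$X[rows, , drop = FALSE], y / s,
                        alpha = a, lambda = lg, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e7)
    if (m$jerr != 0) stop(sprintf("elasticnet did not converge (jerr=%d)", m$jerr))
    list(w = as.numeric(m$beta) * s, beta = as.numeric(m$a0) * s)
  }
  inner <- .inner_split(split$train)
  val_score <- vapply(lambda_grid, function(lam) {
    f <- fit_rows(inner$fit, lam)
    pred <- feats$X[inner$val, , drop = FALSE] %*% f$w + f$beta
    rms_r2(target[inner$val], as.numeric(pred))
  }, numeric(1))
  lambda <- lambda_grid[which.max(val_score)]
  fit <- fit_rows(split$train, lambda)
  .decoder_from_fit(fit$w, fit$beta, lambda, feats, target, split,
                    variant = "elasticnet", target_name = target_name,
                    l1_ratio = r)
}

#' Decode one behavior from a preprocessed recording
#'
#' Convenience wrapper: middle-40% split, feature building, ridge decoder,
#' BSN baseline and the truncated-model curve with N90.
#'
#' @param act a \code{neuron_activity}.
#' @param behavior a \code{behavior_trace} on the same grid.
#' @param target "velocity" or "curvature".
#' @param lambda_grid ridge strength grid.
#' @return list: \code{decoder}, \code{bsn}, \code{curve}, \code{feats},
#'   \code{split}.
#' @export
decode_behavior <- function(act, behavior, target = c("velocity", "curvature"),
                            lambda_grid = 10^seq(-3, 6, length.out = 30)) {
  target <- match.arg(target)
  y <- if (target == "velocity") behavior$velocity else behavior$curvature
  split <- split_train_test(length(y))
  feats <- build_features(act, split)
  dec <- fit_ridge(feats, y, split, lambda_grid, target_name = target)
  bsn <- fit_best_single_neuron(feats, y, split, target_name = target)
  curve <- restricted_curve(dec, feats, y)
  list(decoder = dec, bsn = bsn, curve = curve, feats = feats, split = split)
}
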