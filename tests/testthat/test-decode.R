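# small feature fixture: planted linear target with redundancy and noise
decode_fixture <- function(seed = 1, nt = 600, n = 6) {
  set.seed(seed)
  F_mc <- matrix(rnorm(n * nt), n, nt)
  dFdt <- matrix(rnorm(n * nt), n, nt)
  act <- list(F_mc = F_mc, dFdt = dFdt)
  y <- 2 * F_mc[1, ] - 1.5 * dFdt[2, ] + rnorm(nt, sd = 0.3)
  split <- split_train_test(nt)
  feats <- build_features(act, split)
  list(act = act, y = y, split = split, feats = feats)
}

test_that("train/test split is the middle 40 percent", {
  s100 <- split_train_test(100)
  expect_equal(s100$test, 31:70)
  expect_equal(length(s100$test), 40)
  s10 <- split_train_test(10)
  expect_equal(s10$test, 4:7)
  expect_setequal(c(s10$train, s10$test), 1:10)
  expect_length(intersect(s10$train, s10$test), 0)
  expect_error(split_train_test(9), "10")
})

test_that("feature matrix is train-scaled with constant columns dropped", {
  fx <- decode_fixture()
  expect_equal(ncol(fx$feats$X), 12)
  mu <- colMeans(fx$feats$X[fx$split$train, ])
  sdv <- apply(fx$feats$X[fx$split$train, ], 2, sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(sdv - 1)), 1e-10)

  act2 <- fx$act
  act2$F_mc[3, ] <- 5
  expect_warning(f2 <- build_features(act2, fx$split), "constant")
  expect_equal(ncol(f2$X), 11)
})

test_that("RMS-squared follows its algebra", {
  y <- sin(seq(0, 20, by = 0.05))
  expect_equal(rms_r2(y, y), 1)
  expect_equal(rms_r2(y, rep(3, length(y))), 0)
  # frozen hand computation: z = y - 2.5, zhat = yhat - 2.75,
  # SSres = 0.75, SStot = 5 -> 0.85
  expect_equal(rms_r2(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.85)
  expect_error(rms_r2(rep(1, 10), rnorm(10)), "constant")
  # offset windows evaluate only inside the window
  expect_equal(rms_r2(c(1, 2, 3, 4, 99), c(1, 2, 3, 5, 0), window = 1:4), 0.85)
})

test_that("ridge decoder fits, selects lambda, and respects limits", {
  fx <- decode_fixture()
  dec <- fit_ridge(fx$feats, fx$y, fx$split)
  expect_gt(dec$rms_r2_test, 0.9)
  expect_lte(dec$rms_r2_test, 1)
  # dominant planted features carry the largest weights with right signs
  expect_gt(dec$W_F[1], 0)
  expect_lt(dec$W_dFdt[2], 0)

  # enormous lambda shrinks everything to the constant-intercept model
  dec_inf <- fit_ridge(fx$feats, fx$y, fx$split, lambda_grid = 1e12)
  expect_lt(max(abs(dec_inf$W)), 1e-3)
  expect_equal(dec_inf$beta, mean(fx$y[fx$split$train]))
  expect_equal(dec_inf$rms_r2_test, 0, tolerance = 1e-3)

  # perfect single predictor at tiny lambda
  act1 <- list(F_mc = matrix(fx$y, 1), dFdt = matrix(rnorm(600), 1))
  f1 <- build_features(act1, fx$split)
  d1 <- fit_ridge(f1, fx$y, fx$split, lambda_grid = 1e-8)
  expect_equal(d1$rms_r2_test, 1, tolerance = 1e-6)
})

test_that("ridge weights equal an independent augmented-QR solve", {
  for (s in 1:20) {
    set.seed(100 + s)
    nt <- 120; p <- 7
    X <- matrix(rnorm(nt * p), nt, p)
    y <- rnorm(nt)
    lam <- 10^runif(1, -2, 3)
    act <- list(F_mc = t(X[, 1:4]), dFdt = t(cbind(X[, 5:7], X[, 1])))
    split <- split_train_test(nt)
    feats <- build_features(act, split)
    dec <- fit_ridge(feats, y, split, lambda_grid = lam)
    # independent route: least squares on rows augmented with sqrt(lam) I
    Xtr <- feats$X[split$train, ]
    ytr <- y[split$train]
    Xa <- rbind(Xtr, sqrt(lam) * diag(ncol(Xtr)))
    ya <- c(ytr - mean(ytr), rep(0, ncol(Xtr)))
    w_oracle <- qr.solve(Xa, ya)
    expect_lt(max(abs(dec$W - w_oracle)) / max(abs(w_oracle)), 1e-8)
  }
})

test_that("best single neuron selects the informative feature", {
  fx <- decode_fixture()
  bsn <- fit_best_single_neuron(fx$feats, fx$y, fx$split)
  expect_equal(sum(bsn$W != 0), 1)
  expect_equal(bsn$selected$neuron, 1)
  expect_equal(bsn$selected$feature, "F")

  # exact copy of the target wins with perfect score
  act1 <- list(F_mc = rbind(fx$y, matrix(rnorm(1200), 2)),
               dFdt = matrix(rnorm(1800), 3))
  f1 <- build_features(act1, fx$split)
  b1 <- fit_best_single_neuron(f1, fx$y, fx$split)
  expect_equal(b1$selected$neuron, 1)
  expect_equal(b1$rms_r2_test, 1, tolerance = 1e-9)

  # one informative feature among noise: found in nearly all replicates
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    nt <- 400
    sig <- rnorm(nt)
    act <- list(F_mc = rbind(sig + rnorm(nt, sd = 0.5),
                             matrix(rnorm(4 * nt), 4)),
                dFdt = matrix(rnorm(5 * nt), 5))
    sp <- split_train_test(nt)
    fs <- build_features(act, sp)
    fit_best_single_neuron(fs, sig, sp)$selected$neuron == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("restricted curve reaches the full model and orders ties by index", {
  fx <- decode_fixture()
  dec <- fit_ridge(fx$feats, fx$y, fx$split, lambda_grid = 1e-6)
  curve <- restricted_curve(dec, fx$feats, fx$y)
  n <- length(dec$W_F)
  expect_equal(curve$performance[n], dec$rms_r2_all, tolerance = 1e-6)
  expect_equal(curve$gain[n], 1, tolerance = 1e-3)
  expect_true(!is.na(curve$N90))
  expect_true(all(sort(curve$order) == 1:n))

  # tied weights fall back to neuron-index order
  dec2 <- dec
  dec2$W_F[] <- 1; dec2$W_dFdt[] <- 0.5
  expect_equal(restricted_curve(dec2, fx$feats, fx$y)$order, 1:n)
})

test_that("single planted driver yields N90 = 1", {
  set.seed(17)
  nt <- 600
  sig <- as.numeric(stats::filter(rnorm(nt), 0.8, method = "recursive"))
  act <- list(F_mc = rbind(sig, matrix(rnorm(5 * nt, sd = 1), 5)),
              dFdt = matrix(rnorm(6 * nt), 6))
  split <- split_train_test(nt)
  feats <- build_features(act, split)
  dec <- fit_ridge(feats, sig, split)
  curve <- restricted_curve(dec, feats, sig)
  expect_equal(curve$N90, 1)
  expect_equal(curve$order[1], 1)
})

test_that("N90 intersection obeys set algebra", {
  fx <- decode_fixture()
  dec <- fit_ridge(fx$feats, fx$y, fx$split)
  c1 <- restricted_curve(dec, fx$feats, fx$y)
  expect_setequal(intersect_n90(c1, c1), c1$order[seq_len(c1$N90)])
  c2 <- c1
  c2$order <- rev(c1$order)
  expect_lte(length(intersect_n90(c1, c2)), min(c1$N90, c2$N90))
  c3 <- c1; c3$N90 <- NA_integer_
  expect_error(intersect_n90(c1, c3), "undefined")
})

test_that("variant penalties reduce to ridge at their null settings", {
  fx <- decode_fixture(seed = 2, nt = 300, n = 4)
  lam <- 5
  base <- fit_ridge(fx$feats, fx$y, fx$split, lambda_grid = lam)
  acc0 <- fit_variant(fx$feats, fx$y, fx$split, "accel", lambda_grid = lam,
                      mu = 0, time_s = seq(0, by = 1 / 6, length.out = 300))
  expect_lt(max(abs(acc0$W - base$W)), 1e-8)

  en0 <- fit_variant(fx$feats, fx$y, fx$split, "elasticnet",
                     lambda_grid = lam, l1_ratio = 0)
  expect_lt(max(abs(en0$W - base$W)), 1e-4)

  # elasticnet against the orthogonal-design soft-threshold closed form
  set.seed(31)
  nt <- 200; p <- 6
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(nt * p), nt, p))))[, -1] * sqrt(nt)
  y <- as.numeric(Q %*% c(2, -1, 0.5, 0, 0, 0)) + rnorm(nt, sd = 0.5)
  feats_o <- list(X = Q, kept = rep(TRUE, p), neuron = rep(1:(p / 2), 2),
                  feature = rep(c("F", "dFdt"), each = p / 2),
                  means = rep(0, p), sds = rep(1, p))
  split_all <- list(train = 1:nt, test = 1:nt)
  for (r in c(0.01, 0.5, 1)) {
    lamr <- 8
    en <- wormdecode:::.fit_elasticnet(feats_o, y, split_all, lamr, r, "y")
    soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
    w_oracle <- soft(crossprod(Q, y - mean(y)), lamr * r / 2) /
      (nt + lamr * (1 - r))
    expect_lt(max(abs(en$W - w_oracle)), 1e-10)
  }

  accel <- fit_variant(fx$feats, fx$y, fx$split, "accel", mu = 10,
                       time_s = seq(0, by = 1 / 6, length.out = 300))
  expect_gt(accel$rms_r2_test, 0.8)
})

test_that("pure lasso splits weight between exact duplicate features", {
  set.seed(23)
  nt <- 400
  sig <- rnorm(nt)
  act <- list(F_mc = rbind(sig, sig), dFdt = matrix(rnorm(2 * nt), 2))
  split <- split_train_test(nt)
  feats <- build_features(act, split)
  en <- fit_variant(feats, sig + rnorm(nt, sd = 0.1), split, "elasticnet",
                    lambda_grid = c(1, 10), l1_ratio = 1)
  w_dup <- abs(en$W_F[1:2])
  expect_lte(sum(w_dup > 1e-6), 1)
})
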