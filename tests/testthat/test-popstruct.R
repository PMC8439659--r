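test_that("correlation matrix is symmetric with unit diagonal and exact duplicates", {
  set.seed(1)
  nt <- 200
  F_mc <- rbind(a = rnorm(nt), b = rnorm(nt), c = rnorm(nt))
  F_mc <- rbind(F_mc, F_mc[1, ])                    # duplicated neuron
  act <- fake_activity(F_mc, seq(0, nt - 1))
  cs <- correlation_matrix(act, c(0, nt))
  expect_identical(cs$rho, t(cs$rho))
  expect_equal(diag(cs$rho), rep(1, 4))
  expect_equal(cs$rho[1, 4], 1)
  expect_true(all(abs(cs$rho) <= 1))

  # independent white noise stays within the null band
  big <- fake_activity(matrix(rnorm(6 * 2000), 6), seq(0, 1999))
  cb <- correlation_matrix(big, c(0, 2000))
  off <- cb$rho[upper.tri(cb$rho)]
  expect_lt(max(abs(off)), 3 / sqrt(2000))

  const <- fake_activity(rbind(rnorm(nt), rep(1, nt), rnorm(nt)),
                         seq(0, nt - 1))
  expect_warning(cc <- correlation_matrix(const, c(0, nt)), "constant")
  expect_true(all(is.na(cc$rho[2, -2])))
  expect_error(correlation_matrix(act, c(0, 30)), "60")
})

test_that("cluster order groups anti-correlated blocks and is deterministic", {
  rho <- diag(6)
  rho[1:3, 1:3] <- 0.9; rho[4:6, 4:6] <- 0.9
  rho[1:3, 4:6] <- -0.8; rho[4:6, 1:3] <- -0.8
  diag(rho) <- 1
  ord <- cluster_order(rho)
  grp <- (ord <= 3)
  expect_true(all(grp[1:3] == grp[1]) && all(grp[4:6] == grp[4]))
  expect_identical(cluster_order(rho), ord)
  expect_true(all(sort(cluster_order(diag(2) * 0 + c(1, 0.2, 0.2, 1))) == 1:2))
  expect_error(cluster_order(matrix(1)), "neurons")
})

test_that("dissimilarity matches closed forms and is a pseudometric", {
  A <- diag(4)
  expect_equal(dissimilarity(A, A), 0)

  P <- choose(4, 2)
  B <- A
  B[1, 2] <- B[2, 1] <- 0.3                         # one pair changed by 0.3
  expect_equal(dissimilarity(A, B), sqrt(0.3^2 / P))
  expect_equal(dissimilarity(A, B), dissimilarity(B, A))
  expect_equal(dissimilarity(A, B, squared = TRUE), 0.3^2 / P)

  cpos <- matrix(0.4, 4, 4); diag(cpos) <- 1
  cneg <- matrix(-0.4, 4, 4); diag(cneg) <- 1
  expect_equal(dissimilarity(cpos, cneg), 0.8)
  expect_error(dissimilarity(diag(3), diag(4)), "shape")
})

test_that("epoch comparison detects a planted switch and passes identical input through", {
  set.seed(7)
  make_switch <- function(seed) {
    set.seed(seed)
    n <- 20; nt <- 600
    L1 <- matrix(rnorm(n), n, 1)
    L2 <- L1 * sample(c(-1, 1), n, replace = TRUE)
    z <- as.numeric(stats::filter(rnorm(nt), 0.9, method = "recursive"))
    F1 <- L1 %*% t(z[1:300]) + matrix(rnorm(n * 300, sd = 0.4), n)
    F2 <- L2 %*% t(z[301:600]) + matrix(rnorm(n * 300, sd = 0.4), n)
    fake_activity(cbind(F1, F2), seq(0, nt - 1),
                  epochs = data.frame(name = c("moving", "immobile"),
                                      start_s = c(0, 320),
                                      end_s = c(280, 599)))
  }
  treated <- lapply(1:4, make_switch)
  controls <- lapply(5:8, function(s) stationary_population(20, 600, seed = s))
  res <- epoch_compare(treated, controls)
  expect_gt(res$median_treated, res$median_control)
  expect_lt(res$p_value, 0.05)

  # identical dissimilarity samples in both groups: t statistic of zero
  same <- lapply(1:3, function(s) stationary_population(20, 600, seed = s))
  treated_same <- lapply(same, function(a) {
    a$epochs <- data.frame(name = c("moving", "immobile"),
                           start_s = c(0, 599 * 0.4), end_s = c(0.3 * 599, 599))
    a
  })
  res2 <- epoch_compare(treated_same, same)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_error(epoch_compare(treated[1], controls), "recordings")
  expect_error(epoch_compare(lapply(1:2, function(s)
    stationary_population(5, 300, seed = s)), controls), "epoch annotation")
})

test_that("PCA state space is fit on its window and explains planted variance", {
  set.seed(11)
  n <- 15; nt <- 800
  L <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) %*% diag(c(4, 3, 2))
  Z <- matrix(rnorm(3 * nt), 3, nt)
  noise_sd <- 0.5
  F_mc <- L %*% Z + matrix(rnorm(n * nt, sd = noise_sd), n)
  act <- fake_activity(F_mc, seq(0, nt - 1))
  ps <- pca_state_space(act, fit_window = c(200, 700), n_components = 3)

  expect_equal(unname(crossprod(ps$loadings)), diag(3), tolerance = 1e-8)
  expect_true(all(diff(ps$explained_var) <= 1e-12))
  fitted_rows <- act$time_s >= 200 & act$time_s < 700
  expect_lt(max(abs(colMeans(ps$projection[fitted_rows, ]))), 1e-9)

  # analytic share from the generative covariance eigenvalues
  ev <- eigen(L %*% t(L) + diag(noise_sd^2, n), symmetric = TRUE)$values
  share <- sum(ev[1:3]) / sum(ev)
  expect_lt(abs(sum(ps$explained_var) - share), 0.05)

  # rank-1 input: one component carries everything
  r1 <- fake_activity(outer(rnorm(n), rnorm(nt)), seq(0, nt - 1))
  expect_warning(p1 <- pca_state_space(r1, c(0, nt), n_components = 3), "rank")
  expect_equal(p1$explained_var[1], 1, tolerance = 1e-9)
})

test_that("PCA projections are invariant to neuron permutation up to sign", {
  set.seed(12)
  act <- stationary_population(12, 400, seed = 3)
  perm <- sample(12)
  act_p <- fake_activity(act$F_mc[perm, ], act$time_s)
  a <- pca_state_space(act, c(50, 350))
  b <- pca_state_space(act_p, c(50, 350))
  for (k in 1:3) {
    agree <- max(abs(a$projection[, k] - b$projection[, k]),
                 abs(a$projection[, k] + b$projection[, k]))
    expect_lt(min(max(abs(a$projection[, k] - b$projection[, k])),
                  max(abs(a$projection[, k] + b$projection[, k]))), 1e-6)
    expect_true(is.finite(agree))
  }
})

test_that("reference correlation shift finds planted flips and honors identity", {
  set.seed(13)
  n <- 16; half <- 400
  z <- as.numeric(stats::filter(rnorm(2 * half), 0.9, method = "recursive"))
  L_a <- c(1, 1, -abs(rnorm(n - 2)))               # others negative vs refs
  L_b <- c(1, 1, abs(rnorm(n - 2)))                # flips to positive
  F1 <- outer(L_a, z[1:half]) + matrix(rnorm(n * half, sd = 0.3), n)
  F2 <- outer(L_b, z[(half + 1):(2 * half)]) + matrix(rnorm(n * half, sd = 0.3), n)
  act <- fake_activity(cbind(F1, F2), seq(0, 2 * half - 1))
  act$neuron_labels <- c("AVAL", "AVAR", sprintf("N%02d", 3:n))

  res <- reference_correlation_shift(act, c("AVAL", "AVAR"),
                                     c(0, half), c(half, 2 * half))
  expect_gt(res$median_shift, 0.5)
  expect_lt(res$p_value, 0.01)
  expect_gt(min(res$reference_correlation), 0.89)
  expect_equal(nrow(res$shifts), 2 * (n - 2))

  # identical epochs: no shift at all
  act2 <- fake_activity(cbind(F1, F1), seq(0, 2 * half - 1))
  res2 <- reference_correlation_shift(act2, c(1, 2), c(0, half),
                                      c(half, 2 * half))
  expect_equal(res2$median_shift, 0, tolerance = 1e-12)
  expect_error(reference_correlation_shift(act, c("AVAX"), c(0, half),
                                           c(half, 2 * half)), "not found")
})

test_that("epoch comparison controls false positives on stationary data", {
  rejections <- vapply(1:100, function(rep) {
    base <- 9000 + rep * 7
    treated <- lapply(1:3, function(k) {
      a <- stationary_population(15, 400, seed = base + k)
      a$epochs <- data.frame(name = c("moving", "immobile"),
                             start_s = c(0, 160), end_s = c(120, 399))
      a
    })
    controls <- lapply(4:6, function(k)
      stationary_population(15, 400, seed = base + k))
    epoch_compare(treated, controls)$p_value < 0.05
  }, logical(1))
  # binomial(100, 0.05): observing more than 12 rejections has p < 0.002
  expect_lte(sum(rejections), 12)
})
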