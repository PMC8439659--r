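test_that("config validation rejects bad inputs", {
  expect_error(synth_config(duration_s = -1, seed = 1), "duration")
  expect_error(synth_config(n_neurons = 1, seed = 1), "n_neurons")
  expect_error(synth_config(reversal_rate = -2, seed = 1), "rates")
  expect_error(synth_config(seed = 1, immobilization_onset_s = 999,
                            duration_s = 480), "onset")
  expect_error(synth_config(duration_s = 60, seed = 1, n_neurons = 4,
                            tuning_table = default_tuning_table(5)),
               "length")
  bad <- fixed_tuning_table(4, list(list(behavior = "velocity",
                                         feature = "activity", sign = 1,
                                         esf = 2)))
  expect_error(synth_config(duration_s = 60, seed = 1, n_neurons = 4,
                            tuning_table = bad), "event_subset_fraction")
})

test_that("behavior generation is deterministic and event-free runs stay forward", {
  cfg0 <- synth_config(duration_s = 300, n_neurons = 4, reversal_rate = 0,
                       turn_rate = 0, seed = 5)
  b0 <- generate_behavior(cfg0)
  expect_true(all(b0$behavior$velocity > 0))
  expect_equal(nrow(b0$events), 0)

  cfg <- synth_config(duration_s = 300, n_neurons = 4, seed = 5)
  b1 <- generate_behavior(cfg)
  b2 <- generate_behavior(cfg)
  expect_identical(b1$behavior$velocity, b2$behavior$velocity)
  expect_identical(b1$behavior$curvature, b2$behavior$curvature)
  expect_identical(b1$events, b2$events)
})

test_that("reversal counts follow the configured Poisson rate", {
  # rate 2/min over 600 s -> lambda = 20 per recording; mean over 100 seeds
  # should land within 3 SDs of the mean estimate, sqrt(20/100)
  counts <- vapply(1:100, function(s) {
    cfg <- synth_config(duration_s = 600, n_neurons = 2, reversal_rate = 2,
                        turn_rate = 0, seed = s)
    sum(generate_behavior(cfg)$events$type == "reversal")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 100))
})

test_that("recording generation is deterministic and shape-consistent", {
  std <- std_recording()
  gen2 <- generate_recording(list(behavior = std$behavior,
                                  events = std$events), std$cfg)
  expect_identical(std$recording$G, gen2$recording$G)
  expect_identical(std$recording$valid_mask, gen2$recording$valid_mask)
  expect_equal(dim(std$recording$G), dim(std$recording$R))
  expect_equal(ncol(std$recording$G), length(std$recording$time_s))
})

test_that("ground-truth components reconstruct raw channels exactly without noise", {
  cfg <- synth_config(duration_s = 120, n_neurons = 6, noise_sd = 0,
                      outlier_rate_per_min = 0, seed = 3)
  beh <- generate_behavior(cfg)
  gen <- generate_recording(beh, cfg)
  tr <- gen$truth
  G_rebuilt <- tr$bleach_G * (tr$baseline_G + tr$gain_eff * tr$signal +
                                tr$artifact_coupling_G * tr$artifact)
  R_rebuilt <- tr$bleach_R * (tr$baseline_R +
                                tr$artifact_coupling_R * tr$artifact)
  expect_equal(gen$recording$G, G_rebuilt, tolerance = 1e-12)
  expect_equal(gen$recording$R, R_rebuilt, tolerance = 1e-12)
})

test_that("zero signal gain leaves channels affine in artifact only", {
  # GFP mode: after removing bleach and artifact terms nothing behavioral
  # remains but noise, so per-neuron corrected-vs-behavior correlation is
  # centered on zero
  cfg <- synth_config(duration_s = 300, n_neurons = 12,
                      signal_gain_global = 0, artifact_ratio_jitter = 0,
                      seed = 4)
  beh <- generate_behavior(cfg)
  gen <- generate_recording(beh, cfg)
  act <- preprocess_recording(gen$recording)
  rhos <- vapply(1:12, function(i)
    cor(act$F_mc[i, ], beh$behavior$velocity), numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("affine generative equation holds with artifact, noise and bleach off", {
  tt <- fixed_tuning_table(3, list(list(behavior = "velocity",
                                        feature = "activity", sign = 1)))
  cfg <- synth_config(duration_s = 120, n_neurons = 3, noise_sd = 0,
                      artifact_amplitude = 0, bleach_tau_range = NULL,
                      outlier_rate_per_min = 0, tuning_table = tt, seed = 8)
  beh <- generate_behavior(cfg)
  gen <- generate_recording(beh, cfg)
  g <- gen$recording$G[1, ]
  s <- gen$truth$signal[1, ]
  fit <- lm(g ~ s)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("planted velocity neuron survives preprocessing with high correlation", {
  tt <- fixed_tuning_table(4, list(list(behavior = "velocity",
                                        feature = "activity", sign = 1,
                                        gain = 3)))
  cfg <- synth_config(duration_s = 300, n_neurons = 4, noise_sd = 0.3,
                      tuning_table = tt, gap_rate_per_min = 0,
                      outlier_rate_per_min = 0, seed = 12)
  beh <- generate_behavior(cfg)
  gen <- generate_recording(beh, cfg)
  act <- preprocess_recording(gen$recording)
  expect_gt(cor(act$F_mc[1, ], beh$behavior$velocity), 0.8)
})

test_that("partial-event neurons peak only at their stored event subset", {
  tt <- fixed_tuning_table(3, list(list(behavior = "velocity",
                                        feature = "activity", sign = 1,
                                        gain = 2, esf = 0.5)))
  cfg <- synth_config(duration_s = 600, n_neurons = 3, reversal_rate = 3,
                      noise_sd = 0, intrinsic_noise_frac = 0,
                      artifact_amplitude = 0, bleach_tau_range = NULL,
                      outlier_rate_per_min = 0, tuning_table = tt, seed = 21)
  beh <- generate_behavior(cfg)
  gen <- generate_recording(beh, cfg)
  sub <- gen$truth$event_subsets[[1]]
  all_rev <- beh$events$time_s[beh$events$type == "reversal"]
  skipped <- setdiff(all_rev, sub)
  # isolate events with no near neighbor, where responses are unambiguous
  isolated <- function(ts) ts[vapply(ts, function(t0)
    sum(abs(all_rev - t0) < 6) == 1, logical(1))]
  sig <- gen$truth$signal[1, ]
  t <- beh$behavior$time_s
  peak_near <- function(t0) max(sig[t >= t0 & t <= t0 + 4])
  expect_gt(length(sub), 0)
  for (t0 in isolated(sub)) expect_gt(peak_near(t0), 1)
  for (t0 in isolated(skipped)) expect_lt(peak_near(t0), 0.5)
})

test_that("immobilization recording annotates epochs and keeps AVA pair coherent", {
  cfg <- synth_config(duration_s = 600, n_neurons = 30,
                      immobilization_onset_s = 270, seed = 31)
  gi <- generate_immobilization_recording(cfg)
  ep <- gi$recording$epochs
  expect_setequal(ep$name, c("moving", "transition", "immobile"))
  expect_equal(ep$end_s[ep$name == "moving"], 270)
  # behavior freezes after onset
  late <- gi$behavior$time_s > 280
  expect_lt(max(abs(gi$behavior$velocity[late])), 0.02)
  # AVA-like pair highly correlated in both epochs
  act <- preprocess_recording(gi$recording)
  mov <- act$time_s < 270; imm <- act$time_s >= 360
  expect_gt(cor(act$F_mc[1, mov], act$F_mc[2, mov]), 0.89)
  expect_gt(cor(act$F_mc[1, imm], act$F_mc[2, imm]), 0.89)
  expect_error(generate_immobilization_recording(
    synth_config(duration_s = 600, n_neurons = 30, seed = 1)), "onset")
})

test_that("planted correlation flip produces at least half its analytic dissimilarity", {
  cfg <- synth_config(duration_s = 600, n_neurons = 30,
                      immobilization_onset_s = 270, seed = 33)
  gi <- generate_immobilization_recording(cfg)
  planted <- dissimilarity(gi$truth$rho_expected_moving,
                           gi$truth$rho_expected_immobile)
  act <- preprocess_recording(gi$recording)
  measured <- dissimilarity(correlation_matrix(act, c(0, 270)),
                            correlation_matrix(act, c(360, 600)))
  expect_gt(planted, 0.3)        # the planted effect is substantial
  expect_gt(measured, 0.5 * planted)
})
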