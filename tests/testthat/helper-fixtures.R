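# Shared fixtures, built once per test run and cached.

.fix <- new.env()

# small standard moving recording (20 neurons, 4 min) + preprocessed activity
std_recording <- function() {
  if (is.null(.fix$std)) {
    cfg <- synth_config(duration_s = 240, n_neurons = 20, seed = 1)
    beh <- generate_behavior(cfg)
    gen <- generate_recording(beh, cfg)
    act <- preprocess_recording(gen$recording)
    .fix$std <- list(cfg = cfg, behavior = beh$behavior, events = beh$events,
                     recording = gen$recording, truth = gen$truth, act = act)
  }
  .fix$std
}

# a deterministic tuning table: k tuned neurons then untuned fill
fixed_tuning_table <- function(n, specs) {
  tt <- data.frame(behavior = rep("none", n), feature = rep("activity", n),
                   sign = rep(1, n), gain = rep(1, n),
                   event_subset_fraction = rep(1, n),
                   stringsAsFactors = FALSE)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    tt[i, c("behavior", "feature")] <- c(s$behavior, s$feature)
    tt$sign[i] <- s$sign
    tt$gain[i] <- if (is.null(s$gain)) 1 else s$gain
    tt$event_subset_fraction[i] <- if (is.null(s$esf)) 1 else s$esf
  }
  tt
}

# minimal neuron_activity carrier for popstruct tests
fake_activity <- function(F_mc, time_s, epochs = NULL) {
  structure(list(F_mc = F_mc, dFdt = F_mc, alpha = rep(1, nrow(F_mc)),
                 interpolated_mask = NULL, valid_mask = NULL,
                 time_s = time_s, qc = NULL, neuron_labels = NULL,
                 epochs = epochs),
            class = "neuron_activity")
}

# stationary latent-factor population for null studies
stationary_population <- function(n_neurons, n_time, dt = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- 3
  L <- matrix(rnorm(n_neurons * k), n_neurons, k)
  Z <- sapply(1:k, function(j) as.numeric(
    stats::filter(rnorm(n_time), 0.9, method = "recursive")))
  F_mc <- L %*% t(Z) + matrix(rnorm(n_neurons * n_time, sd = 0.5),
                              n_neurons, n_time)
  fake_activity(F_mc, seq(0, by = dt, length.out = n_time))
}
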