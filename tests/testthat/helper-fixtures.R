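# Shared fixtures, built once per test run and cached. All sizes are desk
# scale so the whole suite stays fast; every object is deterministic.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# Small source model shared by most source-space tests.
fx_model <- function() {
  fx_cached("model", function() {
    make_source_model(n_vertices = 40, n_channels = 24, seed = 1)
  })
}

# Default-config simulation on the small model.
fx_sim <- function() {
  fx_cached("sim", function() {
    simulate_meg(fx_model(), meg_sim_config(n_trials_per_task = 15), seed = 2)
  })
}

fx_delta <- function() {
  fx_cached("delta", function() bandpass(fx_sim()$epochs, 0.5, 4, "delta"))
}

fx_fit <- function() {
  fx_cached("fit", function() fit_lcmv(fx_model(), data_covariance(fx_delta())))
}

fx_src <- function() {
  fx_cached("src", function() reconstruct(fx_delta(), fx_fit()))
}

fx_emg <- function() {
  fx_cached("emg", function() {
    simulate_emg(emg_sim_config(n_trials_per_task = 15), seed = 3)
  })
}

# Hand-constructed beamformer fit for the activation-index oracle: two
# channels, one vertex, weights (1, 0).
fx_unit_fit <- function() {
  structure(list(weights = matrix(c(1, 0), 1, 2), orientation = NULL,
                 reg = 0, data_cov = diag(2)),
            class = "beamformer_fit")
}

# Epochs whose channel-1 biased variance is exactly 4 in the task window and
# 1 in the baseline window: values +/-2 and +/-1 around a zero mean.
fx_oracle_epochs <- function() {
  n <- 20 # sfreq 10 Hz, [0, 2) s
  x1 <- rep(c(1, -1), n / 2)        # baseline-level variance 1 everywhere
  x1[11:20] <- rep(c(2, -2), 5)     # task window [1, 2): variance 4
  x2 <- rep(c(1, -1), n / 2)
  arr <- array(0, c(1, 2, n))
  arr[1, 1, ] <- x1
  arr[1, 2, ] <- x2
  sensor_epochs(arr, sfreq = 10, t0 = 0, labels = "thumb")
}

# Binomial 95% half-width around chance for n test trials.
chance_ci <- function(n, chance = 0.25) {
  1.96 * sqrt(chance * (1 - chance) / n)
}
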