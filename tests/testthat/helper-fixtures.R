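# Shared fixtures. Expensive objects are built once per test run and cached
# in this environment (helpers are sourced before the test files).

.fixtures <- new.env(parent = emptyenv())

sinusoid_recording <- function(freqs, fs = 256, duration = 20, amps = NULL,
                               noise_sd = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amps <- amps %||% rep(1, length(freqs))
  data <- do.call(rbind, lapply(seq_along(freqs), function(i) {
    amps[i] * sin(2 * pi * freqs[i] * t) +
      if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0
  }))
  if (nrow(data) == 1) data <- rbind(data, 0 * data)
  recording(data, fs = fs)
}

# two channels sharing a narrowband source with a constant phase lag
lagged_pair_recording <- function(lag = pi / 4, center = 10, bw = 2,
                                  duration = 180, fs = 256, seed = 99) {
  a <- gen_oscillation(center, bw, 5, duration, fs, seed, phase_offset = 0)
  b <- gen_oscillation(center, bw, 5, duration, fs, seed, phase_offset = lag)
  recording(rbind(a, b), fs = fs, labels = c("x", "y"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic cohort (8 subjects, 20 s) for pipeline-level tests
mini_cohort_config <- function() {
  cohort_config(n_per_group = 4, duration = 20, seed = 777)
}

mini_cohort_features <- function() {
  if (is.null(.fixtures$mini_features)) {
    cfg <- mini_cohort_config()
    .fixtures$mini_cfg <- cfg
    .fixtures$mini_features <- run_extract(cfg, seed = 5, n_null = 10)
    .fixtures$mini_clinical <- gen_clinical(cfg)
  }
  list(cfg = .fixtures$mini_cfg, features = .fixtures$mini_features,
       clinical = .fixtures$mini_clinical)
}
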