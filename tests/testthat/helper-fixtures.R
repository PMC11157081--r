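# shared fixtures: small, fast configs and a cached zero-noise trial

quiet_cfg <- function(...) {
  cohort_config(grf_noise_sd = 0, emg_noise_sd = 0, ...)
}

fixture_participant <- function(seed = 42, cfg = quiet_cfg()) {
  participant_params(cfg, "P01", seed)
}

# cache expensive generated trials across tests within one run
.fixture_env <- new.env(parent = emptyenv())

fixture_trial <- function(condition = "PRE", seed = 123, noise = FALSE) {
  key <- paste(condition, seed, noise)
  if (is.null(.fixture_env[[key]])) {
    cfg <- if (noise) cohort_config() else quiet_cfg()
    .fixture_env[[key]] <- generate_trial(fixture_participant(cfg = cfg),
                                          condition, seed, cfg)
  }
  .fixture_env[[key]]
}

fixture_norm_peaks <- function(noise = FALSE) {
  key <- paste("peaks", noise)
  if (is.null(.fixture_env[[key]])) {
    cfg <- if (noise) cohort_config() else quiet_cfg()
    p <- fixture_participant(cfg = cfg)
    maxt <- lapply(1:3, function(j) generate_trial(p, "MAX", 200 + j, cfg))
    .fixture_env[[key]] <- normalization_peaks(maxt)
  }
  .fixture_env[[key]]
}

# independent Riemann-sum oracle (midpoint of trapezoid formula written
# longhand, no shared code with trapz_int)
riemann_oracle <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}
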