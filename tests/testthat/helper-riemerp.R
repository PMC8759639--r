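# shared fixtures, all generated in code

# a small, fast simulation configuration used across test files
small_config <- function(...) {
  sim_config(n_subjects = 3L, trials_per_class = c(12L, 24L),
             sampling_rate = 128, ...)
}

# configuration with no noise and no variability: trials == templates
noisefree_config <- function(...) {
  sim_config(n_subjects = 1L, trials_per_class = c(4L, 4L),
             sampling_rate = 128,
             noise = list(spectral_exponent = 1, background_sd_uv = 0,
                          sensor_sd_uv = 0),
             subject_var = list(gain_sdlog = 0, mixing_sd = 0,
                                amp_sdlog = 0, latency_sd_ms = 0),
             trial_var = list(amp_sdlog = 0, latency_sd_ms = 0),
             ...)
}

# random SPD matrix with eigenvalues bounded away from 0
random_spd <- function(n, scale = 1) {
  a <- matrix(rnorm(n * n), n, n)
  scale * (crossprod(a) / n + diag(n))
}

# hand-built epoch_set from an explicit trial list
epochs_from_trials <- function(trials, labels,
                               subject_ids = rep(1L, length(trials)),
                               channel_names = paste0("ch", seq_len(nrow(trials[[1]]))),
                               sampling_rate = 100, t0_offset = 0) {
  arr <- array(0, c(length(trials), nrow(trials[[1]]), ncol(trials[[1]])))
  for (i in seq_along(trials)) arr[i, , ] <- trials[[i]]
  epoch_set(arr, labels, subject_ids, channel_names, sampling_rate,
            t0_offset)
}
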