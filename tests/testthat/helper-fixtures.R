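# Shared fixtures, built in code.

fs_test <- 1024

# epoch_set from a time x trials matrix (single channel "AC")
epochs_from_matrix <- function(m, fs = fs_test, t0 = 0) {
  L <- nrow(m)
  structure(list(
    data = array(t(m), dim = c(ncol(m), 1, L)),
    fs_hz = fs, t0_offset_s = t0, t = t0 + (0:(L - 1)) / fs,
    channel_names = "AC",
    labels = data.frame(kind = rep("x", ncol(m)),
                        gap_width_ms = NA_real_,
                        onset_s = seq_len(ncol(m)))),
    class = "epoch_set")
}

# n_trials copies of a sinusoid with given per-trial phases
sinusoid_trials <- function(phases, f = 40, fs = fs_test, dur = 1) {
  tt <- (0:(round(dur * fs) - 1)) / fs
  sapply(phases, function(p) sin(2 * pi * f * tt + p))
}

# mean over the edge-trimmed interior of one frequency row of a map object
interior_row_mean <- function(map, f_hz, field = "itpc") {
  j <- which.min(abs(map$freqs_hz - f_hz))
  h <- map$edge_samples[j]
  nt <- length(map$t)
  mean(map[[field]][j, (h + 1):(nt - h)])
}

# low-noise effect configuration for parameter-recovery checks
recovery_config <- function(jitter = 0.7) {
  effect_config(bg_rms_uV = 2, gamma_rms_uV = 0.5,
                erp_amp_uV = c(P1 = 0, N1 = 0, P2 = 0),
                base_jitter_rad = jitter, subject_noise_sd = 0)
}

# short-session schedule used where a full 58-minute session is unnecessary
short_schedule <- function(gap_min = 2, noise_min = 2, rest_min = 0.5) {
  session_schedule(rest_min = rest_min, gapassr_min = gap_min,
                   noise_min = noise_min)
}
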