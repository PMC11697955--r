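# Synthetic EEG generator: determinism, planted structure, analytic oracles.

test_that("simulation is bit-reproducible for a fixed seed", {
  ev <- schedule_session(ss = short_schedule(0.5, 0.5, 0), seed = 1)
  p <- animal_params("KO", "NLX101", "F", "P30", seed = 2)
  r1 <- simulate_recording(p, ev, seed = 3)
  r2 <- simulate_recording(p, ev, seed = 3)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(p, ev, seed = 4)
  expect_false(identical(r1$data, r3$data))
})

test_that("effect rules are applied to the drawn parameters", {
  cfg <- effect_config(subject_noise_sd = 0)
  wt <- animal_params("WT", "saline", "M", "P30", cfg, seed = 1)
  ko <- animal_params("KO", "saline", "M", "P30", cfg, seed = 1)
  expect_equal(abs(ko$erp_amp_uV[["N1"]]),
               abs(wt$erp_amp_uV[["N1"]]) * cfg$ko_n1_factor)
  expect_equal(ko$gamma_bg_scale, cfg$ko_gamma_factor)
  expect_equal(ko$assr_phase_jitter_rad,
               wt$assr_phase_jitter_rad * cfg$ko_jitter_factor)

  ko_nlx30 <- animal_params("KO", "NLX101", "M", "P30", cfg, seed = 1)
  expect_equal(ko_nlx30$gamma_bg_scale, 1) # treatment rescue at P30
  ko_nlx21 <- animal_params("KO", "NLX101", "M", "P21", cfg, seed = 1)
  expect_equal(ko_nlx21$gamma_bg_scale, cfg$ko_gamma_factor) # not at P21
  expect_lt(ko_nlx30$assr_phase_jitter_rad, ko$assr_phase_jitter_rad)
})

test_that("zero-amplitude components leave pure noise with a near-zero ERP", {
  cfg <- effect_config(erp_amp_uV = c(P1 = 0, N1 = 0, P2 = 0),
                       assr_amp_uV = 0, subject_noise_sd = 0)
  ev <- schedule_session(ss = short_schedule(0, 4, 0), seed = 5)
  p <- animal_params("WT", "saline", "M", "P30", cfg, seed = 6)
  rec <- simulate_recording(p, ev, seed = 7)
  ep <- preprocess_trials(extract_epochs(rec, "noise_burst", c(-0.25, 0.5)))
  av <- average_erp(ep)
  # mean ERP is at the noise floor: |mean| << single-trial RMS
  expect_lt(max(abs(av$waveform)), 3 * sd(ep$data) / sqrt(av$n_trials) * 5)
  expect_lt(max(abs(av$waveform)) / sd(ep$data), 0.5)
})

test_that("background spectral slope matches the configured alpha", {
  cfg <- effect_config(gamma_rms_uV = 0, erp_amp_uV = c(P1 = 0, N1 = 0, P2 = 0),
                       assr_amp_uV = 0, bg_alpha = 1.3, subject_noise_sd = 0)
  p <- animal_params("WT", "saline", "M", "P30", cfg, seed = 3)
  ev <- structure(data.frame(onset_s = numeric(0), kind = character(0),
                             gap_width_ms = numeric(0)),
                  class = c("event_table", "data.frame"))
  rec <- simulate_recording(p, ev, seed = 4, duration_s = 120)
  sp <- stats::spec.pgram(stats::ts(rec$data[1, ], frequency = 1024),
                          spans = 21, plot = FALSE, taper = 0)
  sel <- sp$freq > 2 & sp$freq < 200
  slope <- unname(coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  expect_equal(slope, -1.3, tolerance = 0.2 / 1.3)
})

test_that("zero jitter and certain response drive downstream ITPC to ~ 1", {
  cfg <- recovery_config(jitter = 0)
  cfg$gap_slope <- 50 # response probability ~ 1 at every width
  p <- animal_params("WT", "saline", "M", "P30", cfg, seed = 8)
  ev <- schedule_session(ss = short_schedule(1, 0, 0), seed = 9)
  rec <- simulate_recording(p, ev, seed = 10)
  ep <- extract_epochs(rec, "gap_segment", c(0, 0.25), gap_width_ms = 9)
  it <- compute_itpc(morlet_transform(ep, freqs = 40))
  expect_gt(interior_row_mean(it, 40), 0.97)
})

test_that("mean 40 Hz ITPC tracks exp(-sigma^2/2) * P(respond) on a sigma/width grid", {
  # oracle: direct simulation of the phase mechanism (wrapped-normal phases
  # for responders, uniform phases for non-responders)
  oracle <- function(n, sigma, p_resp, reps = 600) {
    r <- replicate(reps, {
      resp <- runif(n) < p_resp
      ph <- ifelse(resp, rnorm(n, 0, sigma), runif(n, 0, 2 * pi))
      Mod(mean(exp(1i * ph)))
    })
    c(mean = mean(r), sd = sd(r))
  }
  set.seed(11)
  ss <- short_schedule(6, 0, 0)
  for (sigma in c(0.4, 1.0)) {
    cfg <- recovery_config(jitter = sigma)
    p <- animal_params("WT", "saline", "M", "P30", cfg, seed = 12)
    ev <- schedule_session(ss = ss, seed = 13)
    rec <- simulate_recording(p, ev, seed = 14)
    for (w in c(3, 9)) {
      ep <- extract_epochs(rec, "gap_segment", c(0, 0.25), gap_width_ms = w)
      it <- compute_itpc(morlet_transform(ep, freqs = 40))
      obs <- interior_row_mean(it, 40)
      p_resp <- plogis(cfg$gap_slope * (w - cfg$gap_thresh_ms))
      o <- oracle(dim(ep$data)[1], sigma, p_resp)
      expect_lt(abs(obs - o["mean"]), 3 * o["sd"] + 0.02)
    }
  }
})

test_that("frontal channel is an attenuated, lagged copy of the neural signal", {
  cfg <- effect_config(bg_rms_uV = 0.01, gamma_rms_uV = 0, base_jitter_rad = 0,
                       subject_noise_sd = 0, amp_jitter_sd = 0,
                       lat_jitter_ms = 0)
  p <- animal_params("WT", "saline", "M", "P30", cfg, seed = 15)
  ev <- schedule_session(ss = short_schedule(0, 0.5, 0.1), seed = 16)
  rec <- simulate_recording(p, ev, seed = 17)
  lag_n <- round(cfg$fc_lag_ms / 1000 * 1024)
  n <- ncol(rec$data)
  ac <- rec$data[1, 1:(n - lag_n)]
  fc <- rec$data[2, (lag_n + 1):n]
  expect_gt(cor(ac, fc), 0.99)
  expect_equal(sd(fc) / sd(ac), cfg$fc_gain, tolerance = 0.05)
})

test_that("cohort simulation counts animals and is seed-deterministic", {
  design <- default_design(2) # one animal per genotype x treatment x sex cell
  ss <- short_schedule(0.25, 0.25, 0.1)
  c1 <- simulate_cohort(design, age = "P30", seed = 20, ss = ss)
  expect_length(c1, sum(design$n))
  expect_equal(sum(design$n), 8)
  c2 <- simulate_cohort(design, age = "P30", seed = 20, ss = ss)
  expect_identical(lapply(c1, `[[`, "data"), lapply(c2, `[[`, "data"))
  expect_error(simulate_cohort(design[0, ], seed = 1), "nrow")
  bad <- design
  bad$n[1] <- 0
  expect_error(simulate_cohort(bad, seed = 1), "group sizes")
})

test_that("events beyond the recording span raise a scheduling error", {
  p <- animal_params(seed = 1)
  ev <- schedule_session(ss = short_schedule(1, 0, 0), seed = 2)
  expect_error(simulate_recording(p, ev, seed = 3, duration_s = 10),
               "scheduling")
  expect_error(simulate_recording(p, ev, fs = 100, seed = 3), "256")
})
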