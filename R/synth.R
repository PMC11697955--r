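# Forward simulation of two-channel (AC, FC) continuous EEG for virtual
# cohorts with the effect structure the downstream analyses are built to
# detect: an elevated-|N1| ERP and elevated gamma background in knockouts,
# and a 40 Hz gap-locked response whose across-trial phase jitter (reduced by
# treatment, increased in knockouts) sets the measurable ITPC.
#
# The phase-jitter mechanism is wrapped-normal by construction: if the 40 Hz
# response phase of trial j is phi_j ~ N(0, sigma^2) wrapped to the circle,
# the population mean resultant length is exp(-sigma^2/2), giving an analytic
# oracle for ITPC recovery. Effect magnitudes are package defaults (the
# source study prints significance, not effect sizes) and are configurable.

#' Cohort effect-structure configuration
#'
#' Baseline signal/noise levels and the multiplicative genotype and treatment
#' effects applied on top of them. All magnitudes are package defaults chosen
#' to give a realistic signal-to-noise regime for epidural mouse EEG; none is
#' an empirical estimate.
#'
#' @param erp_amp_uV named template amplitudes `c(P1, N1, P2)` in uV (N1
#'   negative)
#' @param erp_latency_ms component latencies (ms post-onset)
#' @param erp_width_ms component Gaussian widths (ms, SD)
#' @param bg_rms_uV RMS of the 1/f^alpha background (uV)
#' @param bg_alpha spectral slope of the background
#' @param gamma_rms_uV RMS of the 30-100 Hz gamma background at scale 1 (uV)
#' @param assr_amp_uV peak amplitude of each 40 Hz gap-locked burst (uV)
#' @param assr_delay_ms latency of the burst peak after each gap onset (ms)
#' @param assr_width_ms Gaussian width of each burst (ms, SD)
#' @param base_jitter_rad wrapped-normal SD of the 40 Hz response phase in a
#'   saline wild-type animal (radians)
#' @param gap_thresh_ms,gap_slope response-probability logistic:
#'   `P(respond | width) = plogis(gap_slope * (width - gap_thresh_ms))`
#' @param ko_n1_factor multiplier on |N1| in knockouts
#' @param ko_gamma_factor multiplier on the gamma background in knockouts
#' @param ko_jitter_factor multiplier on phase jitter in knockouts
#' @param nlx_jitter_factor multiplier on phase jitter under treatment (both
#'   genotypes)
#' @param nlx_gamma_rescue if `TRUE`, treatment returns the knockout gamma
#'   background to the wild-type level at age P30 only
#' @param fc_gain,fc_lag_ms frontal channel: gain and lag applied to the
#'   shared neural signal before adding independent frontal background noise
#' @param subject_noise_sd between-animal SD of the multiplicative parameter
#'   draws
#' @param amp_jitter_sd,lat_jitter_ms trial-to-trial ERP amplitude (relative
#'   SD) and latency (ms SD) jitter
#' @return a list of class `effect_config`
#' @export
effect_config <- function(erp_amp_uV = c(P1 = 10, N1 = -20, P2 = 12),
                          erp_latency_ms = c(25, 50, 110),
                          erp_width_ms = c(8, 12, 30),
                          bg_rms_uV = 40, bg_alpha = 1.3,
                          gamma_rms_uV = 15,
                          assr_amp_uV = 40, assr_delay_ms = 15,
                          assr_width_ms = 5,
                          base_jitter_rad = 0.7,
                          gap_thresh_ms = 2, gap_slope = 0.9,
                          ko_n1_factor = 1.5, ko_gamma_factor = 1.6,
                          ko_jitter_factor = 1.4,
                          nlx_jitter_factor = 0.7,
                          nlx_gamma_rescue = TRUE,
                          fc_gain = 0.8, fc_lag_ms = 5,
                          subject_noise_sd = 0.1,
                          amp_jitter_sd = 0.1, lat_jitter_ms = 2) {
  structure(as.list(environment()), class = "effect_config")
}

#' Draw the realized parameters of one virtual animal
#'
#' Applies the genotype/treatment/age effect rules of an [effect_config()] to
#' the baseline values and adds between-animal variability (multiplicative
#' Gaussian draws with SD `subject_noise_sd`).
#'
#' @param genotype `"WT"` or `"KO"`
#' @param treatment `"saline"` or `"NLX101"`
#' @param sex `"M"` or `"F"` (carried as metadata; no effect is planted)
#' @param age `"P21"` or `"P30"`
#' @param cfg an [effect_config()]
#' @param seed integer seed
#' @return a list of class `animal_params`
#' @export
animal_params <- function(genotype = c("WT", "KO"),
                          treatment = c("saline", "NLX101"),
                          sex = c("M", "F"), age = c("P30", "P21"),
                          cfg = effect_config(), seed = 1) {
  genotype <- match.arg(genotype)
  treatment <- match.arg(treatment)
  sex <- match.arg(sex)
  age <- match.arg(age)
  set.seed(seed)
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, cfg$subject_noise_sd))

  erp <- cfg$erp_amp_uV
  if (genotype == "KO") erp["N1"] <- erp["N1"] * cfg$ko_n1_factor
  gamma_scale <- if (genotype == "KO") cfg$ko_gamma_factor else 1
  if (genotype == "KO" && treatment == "NLX101" && age == "P30" &&
      isTRUE(cfg$nlx_gamma_rescue)) {
    gamma_scale <- 1
  }
  jitter <- cfg$base_jitter_rad *
    (if (genotype == "KO") cfg$ko_jitter_factor else 1) *
    (if (treatment == "NLX101") cfg$nlx_jitter_factor else 1)

  structure(list(
    genotype = genotype, treatment = treatment, sex = sex, age = age,
    erp_amp_uV = sign(erp) * jit(abs(erp)),
    erp_latency_ms = cfg$erp_latency_ms, erp_width_ms = cfg$erp_width_ms,
    bg_rms_uV = jit(cfg$bg_rms_uV), bg_alpha = cfg$bg_alpha,
    gamma_bg_scale = jit(gamma_scale), gamma_rms_uV = cfg$gamma_rms_uV,
    assr_amp_uV = jit(cfg$assr_amp_uV), assr_delay_ms = cfg$assr_delay_ms,
    assr_width_ms = cfg$assr_width_ms,
    assr_phase_jitter_rad = jit(jitter),
    gap_thresh_ms = cfg$gap_thresh_ms, gap_response_slope = cfg$gap_slope,
    fc_gain = cfg$fc_gain, fc_lag_ms = cfg$fc_lag_ms,
    subject_noise_sd = cfg$subject_noise_sd,
    amp_jitter_sd = cfg$amp_jitter_sd, lat_jitter_ms = cfg$lat_jitter_ms),
    class = "animal_params")
}

# P1-N1-P2 template sampled at fs; returns a numeric vector starting at onset.
erp_template <- function(params, fs) {
  dur <- max(params$erp_latency_ms + 4 * params$erp_width_ms) / 1000
  tt <- seq(0, dur, by = 1 / fs)
  y <- numeric(length(tt))
  for (k in seq_along(params$erp_amp_uV)) {
    y <- y + params$erp_amp_uV[k] *
      exp(-(tt - params$erp_latency_ms[k] / 1000)^2 /
            (2 * (params$erp_width_ms[k] / 1000)^2))
  }
  y
}

#' Simulate one continuous two-channel recording
#'
#' The auditory-cortex channel is the sum of (a) 1/f^alpha background noise,
#' (b) band-limited (30-100 Hz) gamma background scaled by the animal's
#' `gamma_bg_scale`, (c) the P1-N1-P2 template injected at every noise-burst
#' onset with small trial-to-trial amplitude and latency jitter, and (d) for
#' each gap segment, with probability `plogis(slope * (width - threshold))`, a
#' train of 40 Hz-locked bursts (one per gap onset, phase-coherent within the
#' segment) whose segment phase is drawn wrapped-normal with the animal's
#' jitter SD. The frontal channel shares the neural signal (ERP + ASSR)
#' attenuated by `fc_gain` and lagged by `fc_lag_ms`, with independent
#' background noise. A segment either locks to the gap train or does not; the
#' Bernoulli response draw is made once per segment so that the mean 40 Hz
#' ITPC has the closed form `exp(-sigma^2/2) * P(respond)` at high SNR.
#'
#' @param params an [animal_params()]
#' @param events an `event_table` from [schedule_session()]
#' @param fs sampling rate (Hz), `>= 256`
#' @param seed integer seed
#' @param duration_s recording length; defaults to the schedule's total
#'   duration (or the last event onset + 1 s)
#' @return an `eeg_recording`
#' @export
simulate_recording <- function(params, events, fs = 1024, seed = 1,
                               duration_s = NULL) {
  stopifnot(inherits(params, "animal_params"))
  if (fs < 256) stop("fs must be at least 256 Hz", call. = FALSE)
  duration_s <- duration_s %||% attr(events, "total_duration_s") %||%
    (max(events$onset_s, 0) + 1)
  n <- round(duration_s * fs)
  if (nrow(events) > 0 && any(events$onset_s > duration_s)) {
    stop("scheduling error: event outside the recording span", call. = FALSE)
  }
  set.seed(sub_seed(seed, 1))

  # spectral shape: 1/f^alpha (flattened below 0.5 Hz) plus a flat 30-100 Hz
  # gamma band with 5 Hz cosine shoulders
  bg_psd <- function(rms, alpha) {
    cn <- rms^2 / integrate_psd(function(f) pmax(f, 0.5)^(-alpha), fs)
    function(f) cn * pmax(f, 0.5)^(-alpha)
  }
  gamma_psd <- function(rms) {
    shape <- function(f) {
      ifelse(f >= 35 & f <= 95, 1,
             ifelse(f > 30 & f < 35, 0.5 * (1 - cos(pi * (f - 30) / 5)),
                    ifelse(f > 95 & f < 100, 0.5 * (1 + cos(pi * (f - 95) / 5)), 0)))
    }
    cn <- rms^2 / integrate_psd(shape, fs)
    function(f) cn * shape(f)
  }
  p_bg <- bg_psd(params$bg_rms_uV, params$bg_alpha)
  p_ga <- gamma_psd(params$gamma_rms_uV * params$gamma_bg_scale)
  noise_ac <- colored_noise(n, fs, function(f) p_bg(f) + p_ga(f))
  noise_fc <- colored_noise(n, fs, function(f) p_bg(f) + p_ga(f))

  signal <- numeric(n)

  # ERP injections (in-place adds; a helper function would force a full
  # copy of the signal vector per trial)
  set.seed(sub_seed(seed, 2))
  bursts <- events[events$kind == "noise_burst", , drop = FALSE]
  if (nrow(bursts) > 0) {
    tpl <- erp_template(params, fs)
    ltpl <- length(tpl)
    amp <- pmax(stats::rnorm(nrow(bursts), 1, params$amp_jitter_sd), 0)
    lat <- stats::rnorm(nrow(bursts), 0, params$lat_jitter_ms / 1000)
    for (i in seq_len(nrow(bursts))) {
      i0 <- round((bursts$onset_s[i] + lat[i]) * fs) + 1
      i1 <- min(i0 + ltpl - 1, n)
      if (i0 >= 1 && i1 >= i0) {
        signal[i0:i1] <- signal[i0:i1] + amp[i] * tpl[seq_len(i1 - i0 + 1)]
      }
    }
  }

  # 40 Hz gap-locked responses. Segment onsets are sample-aligned multiples
  # of the segment length, so the burst train inside a segment has a fixed
  # sample layout: precompute its cosine/sine quadrature pair once and form
  # each responding segment's train as cos(phi)*A - sin(phi)*B.
  set.seed(sub_seed(seed, 3))
  gaps <- events[events$kind == "gap_segment", , drop = FALSE]
  if (nrow(gaps) > 0) {
    f0 <- 40
    gap_int_s <- 1 / f0
    n_per_seg <- 10
    respond <- stats::runif(nrow(gaps)) <
      stats::plogis(params$gap_response_slope *
                      (gaps$gap_width_ms - params$gap_thresh_ms))
    phase <- stats::rnorm(nrow(gaps), 0, params$assr_phase_jitter_rad)
    w_sd <- params$assr_width_ms / 1000
    half <- ceiling(3 * w_sd * fs)
    first_off <- round((gap_int_s + params$assr_delay_ms / 1000) * fs) - half
    last_off <- round((n_per_seg * gap_int_s + params$assr_delay_ms / 1000) * fs) + half
    span <- first_off:last_off
    train_a <- numeric(length(span))
    train_b <- numeric(length(span))
    for (g in seq_len(n_per_seg)) {
      center_s <- g * gap_int_s + params$assr_delay_ms / 1000
      c0 <- round(center_s * fs)
      tt <- ((c0 - half):(c0 + half)) / fs
      env <- exp(-(tt - center_s)^2 / (2 * w_sd^2))
      at <- (c0 - half):(c0 + half) - first_off + 1
      train_a[at] <- train_a[at] + env * cos(2 * pi * f0 * tt)
      train_b[at] <- train_b[at] + env * sin(2 * pi * f0 * tt)
    }
    train_a <- params$assr_amp_uV * train_a
    train_b <- params$assr_amp_uV * train_b
    for (i in which(respond)) {
      s0 <- round(gaps$onset_s[i] * fs)
      idx <- s0 + span
      keep <- idx >= 1 & idx <= n
      tr <- cos(phase[i]) * train_a - sin(phase[i]) * train_b
      signal[idx[keep]] <- signal[idx[keep]] + tr[keep]
    }
  }

  lag_n <- round(params$fc_lag_ms / 1000 * fs)
  sig_fc <- c(numeric(lag_n), signal)[seq_len(n)] * params$fc_gain
  dat <- rbind(AC = noise_ac + signal, FC = noise_fc + sig_fc)
  recording(dat, fs_hz = fs, channel_names = c("AC", "FC"), events = events,
            meta = params)
}

# numeric integral of a one-sided PSD over (0, fs/2]
integrate_psd <- function(psd, fs) {
  stats::integrate(psd, 0.01, fs / 2, subdivisions = 2000L,
                   rel.tol = 1e-8)$value
}

#' Default cohort design table
#'
#' One row per genotype x treatment x sex cell with `n` animals each.
#'
#' @param n_per_group animals per genotype x treatment group (split as evenly
#'   as possible across the sexes)
#' @return data frame with columns `genotype`, `treatment`, `sex`, `n`
#' @export
default_design <- function(n_per_group = 8) {
  g <- expand.grid(sex = c("M", "F"), treatment = c("saline", "NLX101"),
                   genotype = c("WT", "KO"), stringsAsFactors = FALSE)
  g$n <- ifelse(g$sex == "M", ceiling(n_per_group / 2), floor(n_per_group / 2))
  g[, c("genotype", "treatment", "sex", "n")]
}

#' Simulate a cohort of recordings
#'
#' Draws per-animal parameters around the group means defined by the effect
#' configuration and simulates each animal's full session. Stimulus block
#' order is counterbalanced across animals. Deterministic for a fixed seed.
#'
#' @param design data frame with columns `genotype`, `treatment`, `sex`, `n`
#'   (see [default_design()])
#' @param age `"P21"` or `"P30"`
#' @param seed integer master seed
#' @param cfg an [effect_config()]
#' @param nb,ga,ss stimulus and schedule specifications
#' @param fs sampling rate (Hz)
#' @return list of `eeg_recording` objects, one per animal; each carries its
#'   `animal_params` in `$meta` and an `animal_id` attribute
#' @export
simulate_cohort <- function(design = default_design(1), age = "P30", seed = 1,
                            cfg = effect_config(), nb = noise_burst_spec(),
                            ga = gap_assr_spec(), ss = session_schedule(),
                            fs = 1024) {
  stopifnot(is.data.frame(design), nrow(design) > 0)
  if (any(design$n < 1)) stop("all group sizes must be >= 1", call. = FALSE)
  idx <- 0
  out <- list()
  for (r in seq_len(nrow(design))) {
    for (k in seq_len(design$n[r])) {
      idx <- idx + 1
      out[[idx]] <- simulate_animal(design$genotype[r], design$treatment[r],
                                    design$sex[r], age, idx, seed, cfg,
                                    nb, ga, ss, fs)
    }
  }
  out
}

# One animal: parameter draw + schedule + recording. Split out so the
# pipeline can stream animals without holding a whole cohort in memory.
simulate_animal <- function(genotype, treatment, sex, age, animal_idx, seed,
                            cfg, nb, ga, ss, fs) {
  order <- if (animal_idx %% 2 == 1) "gapassr-first" else "noise-first"
  ssi <- session_schedule(ss$rest_min, ss$gapassr_min, ss$noise_min, order)
  pars <- animal_params(genotype, treatment, sex, age, cfg,
                        seed = sub_seed(seed, 100 + animal_idx))
  ev <- schedule_session(nb, ga, ssi, seed = sub_seed(seed, 200 + animal_idx))
  rec <- simulate_recording(pars, ev, fs = fs,
                            seed = sub_seed(seed, 300 + animal_idx))
  attr(rec, "animal_id") <- sprintf("%s_%s_%s_%s_%02d", age, genotype,
                                    treatment, sex, animal_idx)
  rec
}
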