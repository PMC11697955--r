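# Acoustic stimulus construction and the session/event schedule.
#
# Two stimuli are used throughout: (1) broadband noise bursts that evoke the
# onset ERP, and (2) the 40 Hz gap-in-noise ASSR stimulus -- alternating 250 ms
# segments of plain noise and gap-interrupted noise, with ten gap onsets spaced
# 25 ms apart inside each gap segment (hence a 40 Hz presentation rate) and a
# per-segment gap width drawn at random from 3-9 ms.

#' Noise-burst stimulus specification
#'
#' Broadband noise bursts used to evoke the auditory ERP: 1-12 kHz band,
#' 75 dB SPL, 100 ms duration with 5 ms cosine-squared rise/fall ramps,
#' presented 120 times at a 0.25 Hz repetition rate.
#'
#' Sound level is symbolic in silico: `level_db_spl` maps to a waveform RMS
#' through a fixed calibration constant (75 dB SPL corresponds to RMS 1).
#'
#' @param band_low_hz,band_high_hz noise passband edges (Hz)
#' @param level_db_spl nominal presentation level (dB SPL)
#' @param duration_ms burst duration (ms)
#' @param ramp_ms rise/fall ramp duration (ms)
#' @param n_repetitions nominal number of presentations
#' @param repetition_rate_hz presentation rate (Hz)
#' @return an object of class `noise_burst_spec`
#' @export
noise_burst_spec <- function(band_low_hz = 1000, band_high_hz = 12000,
                             level_db_spl = 75, duration_ms = 100, ramp_ms = 5,
                             n_repetitions = 120, repetition_rate_hz = 0.25) {
  if (duration_ms <= 2 * ramp_ms) {
    stop("duration_ms must exceed twice ramp_ms", call. = FALSE)
  }
  if (n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  if (repetition_rate_hz <= 0) stop("repetition_rate_hz must be > 0", call. = FALSE)
  if (band_high_hz <= band_low_hz) stop("invalid passband", call. = FALSE)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 level_db_spl = level_db_spl, duration_ms = duration_ms,
                 ramp_ms = ramp_ms, n_repetitions = n_repetitions,
                 repetition_rate_hz = repetition_rate_hz),
            class = "noise_burst_spec")
}

#' Gap-ASSR stimulus specification
#'
#' The gap-in-noise ASSR stimulus alternates 250 ms segments of noise and
#' gap-interrupted noise. Within a gap segment, gap onsets are spaced
#' `gap_interval_ms` = 25 ms apart (a 40 Hz presentation rate); all gaps in a
#' segment share one width, drawn at random from `gap_widths_ms`. At the
#' default 75% modulation depth the noise envelope inside a gap is reduced to
#' 25% of its value outside.
#'
#' @param segment_ms segment duration (ms); must be an integer multiple of
#'   `gap_interval_ms`
#' @param gap_interval_ms spacing between consecutive gap onsets (ms)
#' @param gap_widths_ms candidate gap widths (ms), each `< gap_interval_ms`
#' @param modulation_depth_pct percentage reduction of the envelope inside gaps
#' @param block_duration_min duration of the gap-ASSR block (minutes)
#' @param band_low_hz,band_high_hz carrier noise passband (Hz)
#' @param level_db_spl nominal presentation level (dB SPL)
#' @return an object of class `gap_assr_spec`
#' @export
gap_assr_spec <- function(segment_ms = 250, gap_interval_ms = 25,
                          gap_widths_ms = 3:9, modulation_depth_pct = 75,
                          block_duration_min = 30,
                          band_low_hz = 1000, band_high_hz = 12000,
                          level_db_spl = 75) {
  if (any(gap_widths_ms >= gap_interval_ms)) {
    stop("all gap widths must be smaller than gap_interval_ms", call. = FALSE)
  }
  if (abs(segment_ms / gap_interval_ms - round(segment_ms / gap_interval_ms)) > 1e-9) {
    stop("segment_ms must be an integer multiple of gap_interval_ms", call. = FALSE)
  }
  if (modulation_depth_pct < 0 || modulation_depth_pct > 100) {
    stop("modulation_depth_pct must lie in [0, 100]", call. = FALSE)
  }
  structure(list(segment_ms = segment_ms, gap_interval_ms = gap_interval_ms,
                 gap_widths_ms = sort(gap_widths_ms),
                 modulation_depth_pct = modulation_depth_pct,
                 block_duration_min = block_duration_min,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 level_db_spl = level_db_spl),
            class = "gap_assr_spec")
}

#' Recording session schedule
#'
#' The default 58-minute session: 8 min of resting recording (no stimuli),
#' a 30 min gap-ASSR block and a 20 min noise-burst block, the two stimulus
#' blocks counterbalanced in order across animals.
#'
#' @param rest_min resting-block duration (minutes)
#' @param gapassr_min gap-ASSR block duration (minutes)
#' @param noise_min noise-burst block duration (minutes)
#' @param block_order `"gapassr-first"` or `"noise-first"`
#' @return an object of class `session_schedule`
#' @export
session_schedule <- function(rest_min = 8, gapassr_min = 30, noise_min = 20,
                             block_order = c("gapassr-first", "noise-first")) {
  block_order <- match.arg(block_order)
  stopifnot(rest_min >= 0, gapassr_min >= 0, noise_min >= 0)
  structure(list(rest_min = rest_min, gapassr_min = gapassr_min,
                 noise_min = noise_min, block_order = block_order),
            class = "session_schedule")
}

# dB SPL -> waveform RMS; 75 dB SPL is calibrated to RMS 1 (absolute SPL
# calibration is out of scope in silico).
level_to_rms <- function(level_db_spl) 10^((level_db_spl - 75) / 20)

#' Generate one broadband noise burst
#'
#' Band-limited Gaussian noise with cosine-squared rise/fall ramps, scaled so
#' that the nominal level maps to waveform RMS through the package calibration
#' constant (75 dB SPL = RMS 1, measured before ramping).
#'
#' @param spec a [noise_burst_spec()]
#' @param fs audio sampling rate (Hz); must exceed twice the passband top
#' @param seed integer seed
#' @return a `stimulus_waveform`: list with `wave`, `fs`, `t` (seconds) and
#'   the generating `spec`
#' @export
generate_noise_burst <- function(spec = noise_burst_spec(), fs = 44100, seed = 1) {
  if (fs <= 2 * spec$band_high_hz) {
    stop("sampling rate too low for the requested passband", call. = FALSE)
  }
  n <- round(spec$duration_ms / 1000 * fs)
  if (n < 1) stop("empty waveform: duration rounds to zero samples", call. = FALSE)
  set.seed(seed)
  wave <- bandlimited_noise(n, fs, spec$band_low_hz, spec$band_high_hz) *
    level_to_rms(spec$level_db_spl)
  nr <- round(spec$ramp_ms / 1000 * fs)
  if (nr > 0) {
    ramp <- sin(pi / 2 * seq(0, 1, length.out = nr))^2
    wave[seq_len(nr)] <- wave[seq_len(nr)] * ramp
    wave[n - nr + seq_len(nr)] <- wave[n - nr + seq_len(nr)] * rev(ramp)
  }
  structure(list(wave = wave, fs = fs, t = (seq_len(n) - 1) / fs, spec = spec),
            class = "stimulus_waveform")
}

#' Generate one gap-interrupted noise segment
#'
#' A 250 ms band-limited noise segment whose envelope is stepped down to
#' `1 - depth/100` of its background value inside each gap. Gap onsets start
#' one inter-gap interval (25 ms) into the segment and recur every 25 ms, so a
#' default segment carries `segment_ms / gap_interval_ms = 10` onsets; gap
#' edges are instantaneous amplitude steps (no ramps). The onset falling on
#' the segment boundary belongs to the transition into the following plain
#' noise segment of the continuous stimulus and contributes no attenuated
#' samples to the returned waveform.
#'
#' @param spec a [gap_assr_spec()]
#' @param gap_width_ms gap width (ms); must be one of `spec$gap_widths_ms`
#' @param fs audio sampling rate (Hz)
#' @param seed integer seed
#' @return a `stimulus_waveform` with additional fields `gap_onsets_s`,
#'   `gap_width_ms` and `envelope`
#' @export
generate_gap_segment <- function(spec = gap_assr_spec(), gap_width_ms, fs = 44100,
                                 seed = 1) {
  if (!gap_width_ms %in% spec$gap_widths_ms) {
    stop("gap_width_ms must be one of spec$gap_widths_ms", call. = FALSE)
  }
  if (gap_width_ms >= spec$gap_interval_ms) {
    stop("gap width must be smaller than the gap interval", call. = FALSE)
  }
  n <- round(spec$segment_ms / 1000 * fs)
  set.seed(seed)
  noise <- bandlimited_noise(n, fs, spec$band_low_hz, spec$band_high_hz) *
    level_to_rms(spec$level_db_spl)
  n_gaps <- as.integer(round(spec$segment_ms / spec$gap_interval_ms))
  onsets_s <- (seq_len(n_gaps)) * spec$gap_interval_ms / 1000
  env <- rep(1, n)
  scale <- 1 - spec$modulation_depth_pct / 100
  for (g in onsets_s) {
    i0 <- round(g * fs) + 1
    i1 <- min(round((g + gap_width_ms / 1000) * fs), n)
    if (i0 <= n && i1 >= i0) env[i0:i1] <- scale
  }
  structure(list(wave = noise * env, fs = fs, t = (seq_len(n) - 1) / fs,
                 envelope = env, gap_onsets_s = onsets_s,
                 gap_width_ms = gap_width_ms, spec = spec),
            class = "stimulus_waveform")
}

#' Build the session event table
#'
#' Lays out the recording session as an event table (the in-silico analogue of
#' the TTL pulse channel): a resting block with no events, a gap-ASSR block of
#' alternating plain-noise and gap-interrupted 250 ms segments whose gap widths
#' are drawn uniformly at random, and a noise-burst block with onsets at the
#' burst repetition rate. Block order follows the schedule's counterbalancing.
#'
#' @param nb a [noise_burst_spec()]
#' @param ga a [gap_assr_spec()]
#' @param ss a [session_schedule()]
#' @param seed integer seed controlling the gap-width draws
#' @return an `event_table`: data frame with columns `onset_s`, `kind`
#'   (`noise_burst`, `gap_segment` or `nogap_segment`) and `gap_width_ms`
#'   (`NA` except for gap segments), with attribute `total_duration_s`
#' @export
schedule_session <- function(nb = noise_burst_spec(), ga = gap_assr_spec(),
                             ss = session_schedule(), seed = 1) {
  set.seed(seed)
  seg_s <- ga$segment_ms / 1000
  gap_block_s <- ss$gapassr_min * 60
  noise_block_s <- ss$noise_min * 60
  rest_s <- ss$rest_min * 60

  make_gap_block <- function(t0) {
    n_seg <- floor(gap_block_s / seg_s)
    if (n_seg < 1) return(NULL)
    kind <- rep(c("nogap_segment", "gap_segment"), length.out = n_seg)
    width <- rep(NA_real_, n_seg)
    n_gap <- sum(kind == "gap_segment")
    width[kind == "gap_segment"] <-
      sample(ga$gap_widths_ms, n_gap, replace = TRUE)
    data.frame(onset_s = t0 + (seq_len(n_seg) - 1) * seg_s,
               kind = kind, gap_width_ms = width)
  }
  make_noise_block <- function(t0) {
    period <- 1 / nb$repetition_rate_hz
    n_rep <- floor(noise_block_s * nb$repetition_rate_hz)
    if (n_rep < 1) return(NULL)
    # first onset half a period into the block so a pre-stimulus baseline
    # always exists
    onsets <- t0 + period / 2 + (seq_len(n_rep) - 1) * period
    onsets <- onsets[onsets + nb$duration_ms / 1000 <= t0 + noise_block_s]
    data.frame(onset_s = onsets, kind = "noise_burst",
               gap_width_ms = NA_real_)
  }

  if (ss$block_order == "gapassr-first") {
    ev <- rbind(make_gap_block(rest_s),
                make_noise_block(rest_s + gap_block_s))
  } else {
    ev <- rbind(make_noise_block(rest_s),
                make_gap_block(rest_s + noise_block_s))
  }
  if (is.null(ev)) {
    ev <- data.frame(onset_s = numeric(0), kind = character(0),
                     gap_width_ms = numeric(0))
  }
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, total_duration_s = rest_s + gap_block_s + noise_block_s,
            class = c("event_table", "data.frame"))
}

#' Write / read an event table as tab-separated text
#'
#' @param events an `event_table`
#' @param path file path
#' @return `read_events()` returns the `event_table`; `write_events()` its
#'   path, invisibly
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  total <- attr(events, "total_duration_s")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(total)) {
    writeLines(sprintf("# total_duration_s=%.10g", total), con)
  }
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1)
  total <- NULL
  skip <- 0
  if (startsWith(first, "# total_duration_s=")) {
    total <- as.numeric(sub("# total_duration_s=", "", first))
    skip <- 1
  }
  df <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df$onset_s <- as.numeric(df$onset_s)
  df$gap_width_ms <- as.numeric(df$gap_width_ms)
  structure(df, total_duration_s = total,
            class = c("event_table", "data.frame"))
}
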