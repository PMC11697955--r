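# Dynamic complex Morlet wavelet transform and the derived time-frequency
# summaries: single-trial power (STP) and inter-trial phase clustering (ITPC).
#
# The number of wavelet cycles grows with frequency along an anchored sigmoid
# (3 cycles at 1 Hz, asymptote 29 cycles, inflection 70 Hz, logistic slope
# 0.05 per Hz), trading temporal for spectral resolution as frequency rises.
# Wavelets are amplitude-normalized Gabor atoms: a unit-amplitude sinusoid at
# a grid frequency yields |coefficient| = 1 in steady state, so STP reads
# directly in uV^2.

#' Sigmoidal cycles-per-frequency rule
#'
#' Defines `n(f) = c_min + (c_max - c_min) * S(f)` where `S` is a logistic
#' sigmoid with inflection `f_infl_hz` and slope `k_scale` (1/Hz), affinely
#' rescaled so that `S(f_anchor_hz) = 0` and `S(+Inf) = 1`. With the default
#' constants the rule passes exactly through 3 cycles at 1 Hz and approaches
#' 29 cycles at high frequency, with inflection at 70 Hz. The raw (unanchored)
#' logistic would give about 3.8 cycles at 1 Hz; anchoring honors all four
#' defining constants simultaneously.
#'
#' @param c_min cycles at the anchor frequency
#' @param c_max asymptotic cycle count
#' @param f_infl_hz inflection frequency (Hz)
#' @param k_scale logistic slope (1/Hz)
#' @param f_anchor_hz anchor frequency (Hz)
#' @return an object of class `cycle_function`
#' @export
cycle_function <- function(c_min = 3, c_max = 29, f_infl_hz = 70,
                           k_scale = 0.05, f_anchor_hz = 1) {
  stopifnot(c_max > c_min, k_scale > 0, f_anchor_hz > 0)
  structure(list(c_min = c_min, c_max = c_max, f_infl_hz = f_infl_hz,
                 k_scale = k_scale, f_anchor_hz = f_anchor_hz),
            class = "cycle_function")
}

#' Evaluate the cycles-per-frequency rule
#'
#' @param fn a [cycle_function()]
#' @param f_hz frequency or vector of frequencies (Hz), each `>= f_anchor_hz`
#' @return number of wavelet cycles at each frequency
#' @export
cycles_at <- function(fn, f_hz) {
  if (any(f_hz < fn$f_anchor_hz)) {
    stop("frequency below the anchor frequency of the cycle rule", call. = FALSE)
  }
  s0 <- stats::plogis(fn$k_scale * (fn$f_anchor_hz - fn$f_infl_hz))
  s <- (stats::plogis(fn$k_scale * (f_hz - fn$f_infl_hz)) - s0) / (1 - s0)
  fn$c_min + (fn$c_max - fn$c_min) * s
}

# Amplitude-normalized complex Morlet atom at frequency f: Gaussian envelope
# with SD sigma_t = n_cycles / (2 pi f), truncated at +/- 3 SD, scaled so a
# unit-amplitude sinusoid at f maps to |coefficient| = 1 in steady state.
morlet_atom <- function(f, fs, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3 * sigma_t * fs)
  tt <- (-half:half) / fs
  env <- exp(-tt^2 / (2 * sigma_t^2))
  w <- env * exp(2i * pi * f * tt)
  list(w = 2 * w / sum(env), half = half)
}

#' Dynamic complex Morlet wavelet transform of an epoch set
#'
#' Convolves every trial of one channel with a bank of amplitude-normalized
#' complex Morlet atoms (FFT convolution). Samples within one wavelet
#' half-length of either epoch edge are contaminated by the boundary; the
#' per-frequency half-lengths are stored in `edge_samples` and used by the
#' summary stages to trim statistics windows.
#'
#' @param ep an `epoch_set` (see [extract_epochs()])
#' @param freqs frequency grid (Hz), strictly increasing; default 5-100 Hz in
#'   1 Hz steps (the lowest frequencies whose wavelets fit a standard ERP
#'   epoch)
#' @param fn a [cycle_function()]
#' @param channel channel name or index (default first channel)
#' @return a `tfr_map`: complex array `trials x frequencies x time`, plus
#'   `freqs_hz`, `fs_hz`, `t` and `edge_samples`
#' @export
morlet_transform <- function(ep, freqs = 5:100, fn = cycle_function(),
                             channel = 1) {
  stopifnot(inherits(ep, "epoch_set"))
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("frequency grid must be strictly increasing", call. = FALSE)
  }
  x <- epoch_channel_matrix(ep, channel) # time x trials
  L <- nrow(x)
  n_tr <- ncol(x)
  ncyc <- cycles_at(fn, freqs)
  halves <- ceiling(3 * ncyc / (2 * pi * freqs) * ep$fs_hz)
  if (2 * max(halves) + 1 > L) {
    bad <- freqs[2 * halves + 1 > L]
    stop(sprintf(
      "epoch shorter than the wavelet support at %g Hz (need >= %d samples, have %d)",
      bad[1], 2 * max(halves) + 1, L), call. = FALSE)
  }
  nfft <- stats::nextn(L + 2 * max(halves), c(2L, 3L, 5L))
  xf <- stats::mvfft(rbind(x, matrix(0, nfft - L, n_tr)))
  coeffs <- array(complex(real = 0), dim = c(n_tr, length(freqs), L))
  for (j in seq_along(freqs)) {
    atom <- morlet_atom(freqs[j], ep$fs_hz, ncyc[j])
    wf <- stats::fft(c(atom$w, rep(0, nfft - length(atom$w))))
    conv <- stats::mvfft(xf * wf, inverse = TRUE) / nfft
    # full convolution is delayed by `half` samples; realign to epoch time
    coeffs[, j, ] <- t(conv[atom$half + seq_len(L), , drop = FALSE])
  }
  structure(list(coeffs = coeffs, freqs_hz = freqs, fs_hz = ep$fs_hz,
                 t = ep$t, edge_samples = halves, norm = "amplitude",
                 n_trials = n_tr),
            class = "tfr_map")
}

# Logical matrix (frequencies x time) of samples unaffected by epoch edges.
interior_mask <- function(freqs_edge, n_time) {
  m <- matrix(FALSE, length(freqs_edge), n_time)
  for (j in seq_along(freqs_edge)) {
    h <- freqs_edge[j]
    if (n_time > 2 * h) m[j, (h + 1):(n_time - h)] <- TRUE
  }
  m
}

#' Single-trial power map
#'
#' Mean over trials of squared coefficient magnitude, with no baseline
#' normalization or z-scoring: STP sums stimulus-evoked and ongoing background
#' activity and is reported in uV^2/Hz-scaled units under the amplitude
#' normalization of the transform.
#'
#' @param tfr a `tfr_map`
#' @return an `stp_map`: `power` (frequencies x time), `freqs_hz`, `t`,
#'   `edge_samples`, `n_trials`
#' @export
compute_stp <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_map"))
  p2 <- Mod(tfr$coeffs)^2
  power <- apply(p2, c(2, 3), mean)
  structure(list(power = power, freqs_hz = tfr$freqs_hz, t = tfr$t,
                 edge_samples = tfr$edge_samples, n_trials = tfr$n_trials),
            class = "stp_map")
}

#' Inter-trial phase clustering map
#'
#' At each time-frequency point, the coefficient of every trial is reduced to
#' its unit phase vector; ITPC is the modulus of the across-trial mean of
#' those unit vectors, ranging from 0 (uniform phases) to 1 (identical phase
#' on every trial). Points where any trial has a zero coefficient are set to 0
#' and counted in `n_undefined`.
#'
#' @param tfr a `tfr_map` with at least two trials
#' @return an `itpc_map`: `itpc` (frequencies x time) in `[0, 1]`, plus grid
#'   metadata as in [compute_stp()]
#' @export
compute_itpc <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_map"))
  if (dim(tfr$coeffs)[1] < 2) {
    stop("ITPC requires at least two trials", call. = FALSE)
  }
  mod <- Mod(tfr$coeffs)
  zero <- mod == 0
  mod[zero] <- 1
  unit <- tfr$coeffs / mod
  unit[zero] <- 0
  resultant <- apply(unit, c(2, 3), sum) / dim(tfr$coeffs)[1]
  itpc <- pmin(Mod(resultant), 1) # guard rounding just above 1
  undef <- apply(zero, c(2, 3), any)
  itpc[undef] <- 0
  structure(list(itpc = itpc, freqs_hz = tfr$freqs_hz, t = tfr$t,
                 edge_samples = tfr$edge_samples, n_trials = tfr$n_trials,
                 n_undefined = sum(undef)),
            class = "itpc_map")
}

#' Mean 40 Hz ITPC per gap width
#'
#' Averages the 40 Hz row of each per-gap-width ITPC map over an analysis
#' window, producing the per-animal summary entering the group-level ANOVA.
#' The default window is the edge-trimmed interior of the 40 Hz row (samples
#' at least one wavelet half-length from either epoch edge).
#'
#' @param itpc_by_width named list of `itpc_map` objects, names = gap width
#'   in ms
#' @param window `c(t_min, t_max)` in epoch time (seconds), or `NULL` for the
#'   edge-trimmed interior
#' @param f_hz target frequency row (default 40)
#' @return data frame with columns `gap_width_ms` and `mean_itpc`
#' @export
mean_itpc_40hz <- function(itpc_by_width, window = NULL, f_hz = 40) {
  stopifnot(is.list(itpc_by_width), length(itpc_by_width) > 0)
  rows <- lapply(names(itpc_by_width), function(wname) {
    m <- itpc_by_width[[wname]]
    j <- which.min(abs(m$freqs_hz - f_hz))
    h <- m$edge_samples[j]
    nt <- length(m$t)
    keep <- rep(FALSE, nt)
    if (nt > 2 * h) keep[(h + 1):(nt - h)] <- TRUE
    if (!is.null(window)) {
      if (diff(range(window)) <= 0) stop("zero-length analysis window", call. = FALSE)
      keep <- keep & m$t >= window[1] & m$t < window[2]
    }
    if (!any(keep)) stop("analysis window contains no interior samples", call. = FALSE)
    data.frame(gap_width_ms = as.numeric(wname),
               mean_itpc = mean(m$itpc[j, keep]))
  })
  out <- do.call(rbind, rows)
  out[order(out$gap_width_ms), , drop = FALSE]
}

#' Render a time-frequency map as a heatmap
#'
#' @param map an `stp_map` or `itpc_map`
#' @param main plot title
#' @param ... passed to [graphics::image()]
#' @export
plot_tfr_map <- function(map, main = "", ...) {
  z <- if (inherits(map, "stp_map")) map$power else map$itpc
  graphics::image(map$t, map$freqs_hz, t(z),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "time (s)", ylab = "frequency (Hz)", main = main, ...)
}
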