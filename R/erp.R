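# Trial-averaged event-related potentials and P1/N1/P2 peak measurement.

#' Baseline-correct and detrend single trials
#'
#' Per trial and channel: subtract the mean of the 250 ms pre-onset baseline,
#' then remove the best-fit line over the whole trial (ordinary least
#' squares). The epoch window must include the `[-0.25, 0)` s baseline span.
#'
#' @param ep an `epoch_set`
#' @param baseline_s length of the pre-onset baseline (seconds)
#' @return the corrected `epoch_set`
#' @export
preprocess_trials <- function(ep, baseline_s = 0.25) {
  stopifnot(inherits(ep, "epoch_set"))
  if (ep$t0_offset_s > -baseline_s + 1e-12) {
    stop("epoch window lacks the pre-onset baseline span", call. = FALSE)
  }
  base_idx <- which(ep$t >= -baseline_s & ep$t < 0)
  if (length(base_idx) == 0) stop("empty baseline span", call. = FALSE)
  L <- length(ep$t)
  x <- ep$t - mean(ep$t)
  sxx <- sum(x^2)
  d <- dim(ep$data)
  out <- ep$data
  for (ch in seq_len(d[2])) {
    m <- matrix(out[, ch, ], nrow = d[1], ncol = L) # trials x time
    m <- m - rowMeans(m[, base_idx, drop = FALSE])
    # detrend: subtract the per-trial least-squares line over the whole trial
    beta <- (m %*% x) / sxx
    m <- m - rowMeans(m) - tcrossprod(beta, x)
    out[, ch, ] <- m
  }
  ep$data <- out
  ep$preprocessed <- TRUE
  ep
}

#' Average trials into an ERP
#'
#' @param ep an `epoch_set` with at least two trials
#' @return an `erp_result`: `waveform` (channels x time), `t`, `fs_hz`,
#'   `n_trials`
#' @export
average_erp <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  n_tr <- dim(ep$data)[1]
  if (n_tr < 2) stop("ERP averaging requires at least two trials", call. = FALSE)
  wf <- apply(ep$data, c(2, 3), mean)
  rownames(wf) <- ep$channel_names
  structure(list(waveform = wf, t = ep$t, fs_hz = ep$fs_hz, n_trials = n_tr,
                 channel_names = ep$channel_names),
            class = "erp_result")
}

#' Default peak search windows
#'
#' Post-onset windows bracketing standard mouse cortical ERP latencies:
#' P1 10-40 ms, N1 25-100 ms, P2 60-250 ms.
#'
#' @return named list of `c(t_min, t_max)` windows in seconds
#' @export
peak_windows <- function() {
  list(P1 = c(0.010, 0.040), N1 = c(0.025, 0.100), P2 = c(0.060, 0.250))
}

#' Measure P1/N1/P2 peak amplitudes and latencies
#'
#' P1 and P2 are the maxima, N1 the minimum, of the averaged waveform within
#' their search windows; amplitudes are baseline-to-peak (the corrected
#' baseline is 0 uV) with N1 reported as a signed negative value. Ties are
#' broken by the earliest latency. A channel whose waveform is identically
#' zero is flagged low-SNR.
#'
#' @param erp an `erp_result`
#' @param windows named list of search windows as in [peak_windows()]
#' @return the `erp_result` with a `peaks` data frame: one row per channel,
#'   columns `P1_uV`, `N1_uV`, `P2_uV`, `P1_ms`, `N1_ms`, `P2_ms`, `low_snr`
#' @export
measure_peaks <- function(erp, windows = peak_windows()) {
  stopifnot(inherits(erp, "erp_result"))
  tmax <- erp$t[length(erp$t)]
  for (w in windows) {
    if (w[1] < erp$t[1] || w[2] > tmax + 1e-12) {
      stop("peak search window lies outside the epoch", call. = FALSE)
    }
  }
  find <- function(y, w, fun) {
    idx <- which(erp$t >= w[1] & erp$t <= w[2])
    v <- y[idx]
    i <- if (identical(fun, max)) which.max(v) else which.min(v)
    c(amp = v[i], lat = erp$t[idx[i]])
  }
  rows <- lapply(seq_len(nrow(erp$waveform)), function(ch) {
    y <- erp$waveform[ch, ]
    p1 <- find(y, windows$P1, max)
    n1 <- find(y, windows$N1, min)
    p2 <- find(y, windows$P2, max)
    data.frame(channel = erp$channel_names[ch],
               P1_uV = p1["amp"], N1_uV = n1["amp"], P2_uV = p2["amp"],
               P1_ms = p1["lat"] * 1000, N1_ms = n1["lat"] * 1000,
               P2_ms = p2["lat"] * 1000,
               low_snr = all(y == 0))
  })
  erp$peaks <- do.call(rbind, rows)
  rownames(erp$peaks) <- NULL
  erp
}
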