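# Recording container, plain-text serialization, downsampling to the analysis
# rate, and epoch extraction.

#' Construct a continuous recording object
#'
#' @param data numeric matrix, channels x samples (uV)
#' @param fs_hz sampling rate (Hz)
#' @param channel_names channel labels (default `AC`, `FC`)
#' @param events an `event_table` (may have zero rows)
#' @param meta optional provenance list (e.g. the generating animal parameters)
#' @return an object of class `eeg_recording`
#' @export
recording <- function(data, fs_hz, channel_names = rownames(data),
                      events = NULL, meta = NULL) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (anyNA(data)) stop("recording contains missing samples", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- c("AC", "FC")[seq_len(nrow(data))]
  }
  rownames(data) <- channel_names
  if (is.null(events)) {
    events <- structure(data.frame(onset_s = numeric(0), kind = character(0),
                                   gap_width_ms = numeric(0)),
                        class = c("event_table", "data.frame"))
  }
  structure(list(data = data, fs_hz = fs_hz, channel_names = channel_names,
                 events = events, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), paste(x$channel_names, collapse = ", "),
              ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz, nrow(x$events)))
  invisible(x)
}

#' Write / read a recording in the plain-text fixture container
#'
#' The container is three sibling text files sharing a stem:
#' `<stem>.meta.json` (sampling rate, channel names, sample count),
#' `<stem>.data.tsv` (one column per channel, uV) and `<stem>.events.tsv`
#' (the event table). Round-trips preserve samples to the stored precision
#' (better than 16-bit quantization of the physical range) and events exactly.
#'
#' @param rec an `eeg_recording`
#' @param stem path stem (no extension)
#' @return `read_recording()` returns the `eeg_recording`; `write_recording()`
#'   the stem, invisibly
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  meta <- list(fs_hz = rec$fs_hz, channel_names = rec$channel_names,
               n_samples = ncol(rec$data))
  jsonlite::write_json(meta, paste0(stem, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.table(format(df, digits = 10, scientific = TRUE, trim = TRUE),
                     paste0(stem, ".data.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_events(rec$events, paste0(stem, ".events.tsv"))
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta_path <- paste0(stem, ".meta.json")
  ev_path <- paste0(stem, ".events.tsv")
  dat_path <- paste0(stem, ".data.tsv")
  if (!file.exists(meta_path) || !file.exists(dat_path)) {
    stop("not a recording container: missing meta or data file", call. = FALSE)
  }
  if (!file.exists(ev_path)) {
    stop("format error: recording container lacks an event file", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.delim(dat_path)
  if (nrow(df) != meta$n_samples) {
    stop(sprintf("parse error: truncated data file (%d of %d samples)",
                 nrow(df), meta$n_samples), call. = FALSE)
  }
  recording(t(as.matrix(df)), fs_hz = meta$fs_hz,
            channel_names = meta$channel_names, events = read_events(ev_path))
}

#' Downsample a recording to the analysis sampling rate
#'
#' Frequency-domain anti-alias filtering (flat to `0.4 * target_fs`, cosine
#' roll-off to zero at `0.5 * target_fs`) followed by resampling: exact
#' decimation when the rate ratio is an integer, linear interpolation of the
#' band-limited signal otherwise. Event onsets are stored in seconds and are
#' unchanged.
#'
#' @param rec an `eeg_recording`
#' @param target_fs target sampling rate (Hz), `<=` the current rate
#' @return the downsampled `eeg_recording`
#' @export
downsample <- function(rec, target_fs = 1024) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs_hz) {
    stop("upsampling requested: target_fs exceeds the recording rate", call. = FALSE)
  }
  if (target_fs == rec$fs_hz) return(rec)
  n <- ncol(rec$data)
  f <- (0:(n - 1)) * rec$fs_hz / n
  f <- pmin(f, rec$fs_hz - f) # two-sided frequency axis
  lo <- 0.4 * target_fs
  hi <- 0.5 * target_fs
  gain <- ifelse(f <= lo, 1,
                 ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - lo) / (hi - lo)))))
  filt <- t(apply(rec$data, 1, function(x) Re(stats::fft(stats::fft(x) * gain,
                                                         inverse = TRUE)) / n))
  ratio <- rec$fs_hz / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    out <- filt[, seq(1, n, by = round(ratio)), drop = FALSE]
  } else {
    t_old <- (0:(n - 1)) / rec$fs_hz
    t_new <- seq(0, t_old[n], by = 1 / target_fs)
    out <- t(apply(filt, 1, function(x) stats::approx(t_old, x, t_new)$y))
  }
  recording(out, fs_hz = target_fs, channel_names = rec$channel_names,
            events = rec$events, meta = rec$meta)
}

#' Extract stimulus-locked epochs from a recording
#'
#' Cuts one trial per matching event over the half-open window
#' `[t_min, t_max)` relative to event onset (onset at t = 0). Trials whose
#' window exceeds the recording span are dropped with a message. No artifact
#' rejection is applied by default; pass a predicate to `reject` to install
#' one.
#'
#' @param rec an `eeg_recording`
#' @param kind event kind to select (`noise_burst`, `gap_segment`, ...)
#' @param window `c(t_min, t_max)` in seconds relative to onset
#' @param gap_width_ms optionally restrict gap segments to one width
#' @param reject optional function(trial matrix channels x time) -> TRUE to
#'   drop the trial; default keeps everything
#' @return an `epoch_set`: array `trials x channels x time`, with `t`,
#'   `fs_hz`, `t0_offset_s` and a `labels` data frame
#' @export
extract_epochs <- function(rec, kind, window, gap_width_ms = NULL,
                           reject = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2)
  if (diff(window) <= 0) {
    stop("epoch window must have positive length", call. = FALSE)
  }
  ev <- rec$events
  sel <- ev$kind == kind
  if (!is.null(gap_width_ms)) {
    sel <- sel & !is.na(ev$gap_width_ms) & ev$gap_width_ms == gap_width_ms
  }
  ev <- ev[sel, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events match the requested selection", call. = FALSE)
  fs <- rec$fs_hz
  L <- round(diff(window) * fs)
  off <- round(window[1] * fs)
  s0 <- round(ev$onset_s * fs) + 1 # 1-based sample of onset
  first <- s0 + off
  ok <- first >= 1 & (first + L - 1) <= ncol(rec$data)
  if (sum(!ok) > 0) {
    message(sprintf("extract_epochs: dropped %d trial(s) outside the recording span",
                    sum(!ok)))
  }
  ev <- ev[ok, , drop = FALSE]
  first <- first[ok]
  if (nrow(ev) == 0) stop("no events match the requested selection", call. = FALSE)
  n_ch <- nrow(rec$data)
  dat <- array(0, dim = c(nrow(ev), n_ch, L))
  for (i in seq_len(nrow(ev))) {
    dat[i, , ] <- rec$data[, first[i]:(first[i] + L - 1), drop = FALSE]
  }
  if (!is.null(reject)) {
    keep <- !vapply(seq_len(nrow(ev)),
                    function(i) isTRUE(reject(dat[i, , , drop = TRUE])),
                    logical(1))
    if (sum(!keep) > 0) {
      message(sprintf("extract_epochs: rejected %d trial(s)", sum(!keep)))
    }
    dat <- dat[keep, , , drop = FALSE]
    ev <- ev[keep, , drop = FALSE]
  }
  structure(list(data = dat, fs_hz = fs, t0_offset_s = window[1],
                 t = window[1] + (0:(L - 1)) / fs,
                 channel_names = rec$channel_names,
                 labels = data.frame(kind = ev$kind,
                                     gap_width_ms = ev$gap_width_ms,
                                     onset_s = ev$onset_s)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trial(s) x %d channel(s) x %d samples @ %g Hz, window [%g, %g) s\n",
              d[1], d[2], d[3], x$fs_hz, x$t[1], x$t[length(x$t)] + 1 / x$fs_hz))
  invisible(x)
}

# time x trials matrix for one channel of an epoch set
epoch_channel_matrix <- function(ep, channel = 1) {
  if (is.character(channel)) channel <- match(channel, ep$channel_names)
  if (is.na(channel) || channel < 1 || channel > dim(ep$data)[2]) {
    stop("unknown channel", call. = FALSE)
  }
  d <- dim(ep$data)
  t(matrix(ep$data[, channel, ], nrow = d[1], ncol = d[3]))
}
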