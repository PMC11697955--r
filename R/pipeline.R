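# End-to-end orchestration: simulate a cohort, measure every animal (ERP
# peaks, STP map, 40 Hz ITPC per gap width), then run the group-level
# statistics (Mann-Whitney/Holm-Sidak on peaks, cluster permutation tests on
# STP maps for the four genotype/treatment comparisons, repeated-measures
# ANOVA on ITPC). Animals are simulated and measured one at a time so a full
# cohort never has to be held in memory.

#' Run configuration for the end-to-end experiment
#'
#' @param seed master integer seed; a run is reproducible from its
#'   configuration plus this seed
#' @param age `"P21"` or `"P30"`
#' @param n_per_group animals per genotype x treatment group
#' @param effects an [effect_config()]
#' @param nb,ga,ss stimulus and schedule specifications
#' @param fs analysis sampling rate (Hz)
#' @param erp_window ERP epoch window (s, relative to onset)
#' @param stp_freqs frequency grid for the STP cluster maps (Hz)
#' @param stp_decim STP maps are averaged into non-overlapping time bins of
#'   this many samples before group statistics
#' @param gap_window gap-segment analysis window (s)
#' @param cluster a [cluster_config()]
#' @param gamma_band frequency band summarized as "gamma" (Hz)
#' @param out_dir directory for CSV/JSON outputs, or `NULL` to skip writing
#' @return a list of class `run_config`
#' @export
run_config <- function(seed = 1, age = "P30", n_per_group = 8,
                       effects = effect_config(), nb = noise_burst_spec(),
                       ga = gap_assr_spec(), ss = session_schedule(),
                       fs = 1024, erp_window = c(-0.25, 0.5),
                       stp_freqs = 5:100, stp_decim = 16,
                       gap_window = c(0, 0.25),
                       cluster = cluster_config(), gamma_band = c(30, 100),
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Time-frequency power map of an epoch set, computed frequency-band-wise
#'
#' Convenience wrapper around the Morlet transform and [compute_stp()] that
#' processes the frequency grid in chunks (so large trial counts never
#' materialize a full complex coefficient array) and optionally averages the
#' result into non-overlapping time bins.
#'
#' @param ep an `epoch_set`
#' @param freqs frequency grid (Hz)
#' @param fn a [cycle_function()]
#' @param channel channel name or index
#' @param decim time-bin width in samples (1 = no decimation)
#' @param chunk frequencies per chunk
#' @return an `stp_map`
#' @export
stp_map <- function(ep, freqs = 5:100, fn = cycle_function(), channel = 1,
                    decim = 1, chunk = 8) {
  L <- length(ep$t)
  power <- matrix(0, length(freqs), L)
  edges <- integer(length(freqs))
  for (s in seq(1, length(freqs), by = chunk)) {
    j <- s:min(s + chunk - 1, length(freqs))
    tfr <- morlet_transform(ep, freqs = freqs[j], fn = fn, channel = channel)
    power[j, ] <- compute_stp(tfr)$power
    edges[j] <- tfr$edge_samples
  }
  tt <- ep$t
  if (decim > 1) {
    nb <- floor(L / decim)
    idx <- rep(seq_len(nb), each = decim)
    keep <- seq_len(nb * decim)
    power <- t(apply(power[, keep, drop = FALSE], 1,
                     function(r) tapply(r, idx, mean)))
    tt <- tapply(tt[keep], idx, mean)
    edges <- pmax(1L, as.integer(ceiling(edges / decim)))
  }
  structure(list(power = power, freqs_hz = freqs, t = as.numeric(tt),
                 edge_samples = edges, n_trials = dim(ep$data)[1]),
            class = "stp_map")
}

#' Per-animal measures from one recording
#'
#' For each channel: the trial-averaged ERP with P1/N1/P2 peaks, the STP map
#' over the ERP epochs, and the mean 40 Hz ITPC per gap width.
#'
#' @param rec an `eeg_recording` whose events contain noise bursts and gap
#'   segments
#' @param cfg a [run_config()]
#' @return list with `peaks` (data frame), `itpc` (data frame), `stp`
#'   (named list of `stp_map` per channel) and `n_trials`
#' @export
animal_measures <- function(rec, cfg = run_config()) {
  ep_erp <- preprocess_trials(extract_epochs(rec, "noise_burst", cfg$erp_window))
  widths <- sort(unique(stats::na.omit(rec$events$gap_width_ms)))
  er <- measure_peaks(average_erp(ep_erp))
  peaks <- list()
  itpc <- list()
  stp <- list()
  for (ch in rec$channel_names) {
    peaks[[ch]] <- er$peaks[er$peaks$channel == ch, , drop = FALSE]
    stp[[ch]] <- stp_map(ep_erp, freqs = cfg$stp_freqs, channel = ch,
                         decim = cfg$stp_decim)
    maps <- list()
    for (w in widths) {
      ep_w <- extract_epochs(rec, "gap_segment", cfg$gap_window,
                             gap_width_ms = w)
      tfr <- morlet_transform(ep_w, freqs = 40, channel = ch)
      maps[[as.character(w)]] <- compute_itpc(tfr)
    }
    tab <- mean_itpc_40hz(maps)
    tab$channel <- ch
    itpc[[ch]] <- tab
  }
  list(peaks = do.call(rbind, peaks), itpc = do.call(rbind, itpc),
       stp = stp, n_trials = dim(ep_erp$data)[1])
}

# the four group comparisons reported for STP maps
stp_comparisons <- function() {
  list(KOsal_vs_WTsal = c("KO.saline", "WT.saline"),
       KOnlx_vs_KOsal = c("KO.NLX101", "KO.saline"),
       WTnlx_vs_WTsal = c("WT.NLX101", "WT.saline"),
       KOnlx_vs_WTsal = c("KO.NLX101", "WT.saline"))
}

#' Run the full synthetic-cohort experiment
#'
#' Simulates one cohort at the configured age, measures every animal, and
#' runs the complete group-statistics layer. With `out_dir` set, writes the
#' per-animal cohort tables, ERP test table, cluster tables, ANOVA and post
#' hoc tables as CSV plus a JSON manifest (seed and configuration digest);
#' outputs are byte-identical for identical configuration and seed.
#'
#' @param cfg a [run_config()]
#' @return list with elements `cohort_erp`, `cohort_itpc` (per-animal data
#'   frames), `erp_tests`, `cluster` (nested list comparison -> channel ->
#'   `cluster_result`), `cluster_tables`, `itpc_anova`, `itpc_posthoc`,
#'   `config`
#' @export
run_experiment <- function(cfg = run_config()) {
  design <- default_design(cfg$n_per_group)
  erp_rows <- list()
  itpc_rows <- list()
  stp_maps <- list()
  idx <- 0
  for (r in seq_len(nrow(design))) {
    for (k in seq_len(design$n[r])) {
      idx <- idx + 1
      rec <- simulate_animal(design$genotype[r], design$treatment[r],
                             design$sex[r], cfg$age, idx, cfg$seed,
                             cfg$effects, cfg$nb, cfg$ga, cfg$ss, cfg$fs)
      id <- attr(rec, "animal_id")
      meas <- animal_measures(rec, cfg)
      meta <- data.frame(animal_id = id, genotype = design$genotype[r],
                         treatment = design$treatment[r], sex = design$sex[r],
                         age = cfg$age)
      pk <- merge(meta, meas$peaks)
      names(pk)[names(pk) == "channel"] <- "region"
      erp_rows[[idx]] <- pk
      it <- merge(meta, meas$itpc)
      names(it)[names(it) == "channel"] <- "region"
      itpc_rows[[idx]] <- it
      grp <- paste(design$genotype[r], design$treatment[r], sep = ".")
      for (ch in names(meas$stp)) {
        stp_maps[[ch]][[grp]] <- c(stp_maps[[ch]][[grp]],
                                   list(meas$stp[[ch]]))
      }
      rm(rec)
    }
  }
  cohort_erp <- do.call(rbind, erp_rows)
  cohort_itpc <- do.call(rbind, itpc_rows)
  channels <- names(stp_maps)

  # ERP peak statistics: genotype within treatment and treatment within
  # genotype, per region and peak, Holm-Sidak adjusted per region
  erp_tests <- list()
  comps <- list(c("KO.saline", "WT.saline"), c("KO.NLX101", "WT.NLX101"),
                c("KO.NLX101", "KO.saline"), c("WT.NLX101", "WT.saline"))
  for (ch in channels) {
    sub <- cohort_erp[cohort_erp$region == ch, , drop = FALSE]
    sub$grp <- paste(sub$genotype, sub$treatment, sep = ".")
    rows <- list()
    for (peak in c("P1_uV", "N1_uV", "P2_uV")) {
      for (cmp in comps) {
        a <- sub[[peak]][sub$grp == cmp[1]]
        b <- sub[[peak]][sub$grp == cmp[2]]
        mw <- mann_whitney(a, b)
        rows[[length(rows) + 1]] <- data.frame(
          region = ch, measure = sub("_uV", "", peak),
          comparison = paste(cmp[1], "vs", cmp[2]),
          mean_1 = mean(a), mean_2 = mean(b), U = mw$U, p_raw = mw$p)
      }
    }
    tab <- do.call(rbind, rows)
    tab$p_adj <- holm_sidak_adjust(tab$p_raw)
    erp_tests[[ch]] <- tab
  }
  erp_tests <- do.call(rbind, erp_tests)

  # STP cluster permutation tests
  cluster <- list()
  cluster_tables <- list()
  for (nm in names(stp_comparisons())) {
    cmp <- stp_comparisons()[[nm]]
    for (ch in channels) {
      res <- permutation_test(stp_maps[[ch]][[cmp[1]]],
                              stp_maps[[ch]][[cmp[2]]], cfg$cluster)
      cluster[[nm]][[ch]] <- res
      ref <- stp_maps[[ch]][[cmp[1]]][[1]]
      tab <- cluster_table(res, freqs_hz = ref$freqs_hz, t = ref$t)
      if (nrow(tab) > 0) {
        tab <- cbind(comparison = nm, region = ch, tab)
        cluster_tables[[paste(nm, ch)]] <- tab
      }
    }
  }
  cluster_tables <- if (length(cluster_tables)) {
    do.call(rbind, cluster_tables)
  } else {
    NULL
  }

  # ITPC repeated-measures ANOVA + Sidak post hoc, per region
  itpc_anova <- list()
  itpc_posthoc <- list()
  for (ch in channels) {
    sub <- cohort_itpc[cohort_itpc$region == ch, , drop = FALSE]
    itpc_anova[[ch]] <- rm_anova(sub, between = c("genotype", "treatment"),
                                 within = "gap_width_ms", dv = "mean_itpc")
    itpc_posthoc[[ch]] <- sidak_posthoc(sub, factor = "treatment",
                                        by = "genotype", dv = "mean_itpc")
  }

  out <- list(cohort_erp = cohort_erp, cohort_itpc = cohort_itpc,
              erp_tests = erp_tests, cluster = cluster,
              cluster_tables = cluster_tables, itpc_anova = itpc_anova,
              itpc_posthoc = itpc_posthoc, stp_maps = stp_maps, config = cfg)
  if (!is.null(cfg$out_dir)) write_run_outputs(out, cfg$out_dir)
  out
}

# CSV/JSON output bundle; formatting is fixed so identical runs are
# byte-identical.
write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(format(as.data.frame(df), digits = 12, trim = TRUE,
                            scientific = FALSE),
                     file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(res$cohort_erp, "cohort_erp.csv")
  wr(res$cohort_itpc, "cohort_itpc.csv")
  wr(res$erp_tests, "erp_tests.csv")
  if (!is.null(res$cluster_tables)) wr(res$cluster_tables, "stp_clusters.csv")
  for (ch in names(res$itpc_anova)) {
    wr(res$itpc_anova[[ch]], sprintf("itpc_anova_%s.csv", ch))
    wr(res$itpc_posthoc[[ch]], sprintf("itpc_posthoc_%s.csv", ch))
  }
  cfg <- res$config
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(seed = cfg$seed, age = cfg$age,
                   n_per_group = cfg$n_per_group,
                   config_digest = sum(utf8ToInt(as.character(cfg_json))),
                   config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Does a cluster result contain a significant cluster overlapping a band?
#'
#' @param res a `cluster_result`
#' @param freqs_hz frequency axis of the map rows
#' @param band `c(f_lo, f_hi)` in Hz, or `NULL` for any cluster
#' @param sign restrict to clusters of this t-sign (`1`, `-1`, or `NULL`)
#' @return `TRUE` if any significant cluster has a member row inside the band
#' @export
has_significant_cluster <- function(res, freqs_hz, band = NULL, sign = NULL) {
  nr <- nrow(res$t_map)
  for (cl in res$clusters) {
    if (!cl$significant) next
    if (!is.null(sign) && cl$sign != sign) next
    if (is.null(band)) return(TRUE)
    rows <- ((cl$members - 1) %% nr) + 1
    if (any(freqs_hz[rows] >= band[1] & freqs_hz[rows] <= band[2])) {
      return(TRUE)
    }
  }
  FALSE
}
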