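#!/usr/bin/env Rscript
# Step 1 -- Build the acoustic stimuli and a default session schedule.
#
# Constructs the two stimuli the recording session uses (broadband noise
# bursts; 250 ms gap-interrupted noise segments), verifies their defining
# geometry (40 Hz gap rate, 75% envelope modulation), and writes the event
# table of a default 58-minute session.

suppressPackageStartupMessages(library(gapassr))
out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seg <- generate_gap_segment(gap_assr_spec(), gap_width_ms = 5, fs = 44100,
                            seed = 1)
cat(sprintf("gap segment: %d gap onsets, spacing %.3f s -> %.0f Hz presentation rate\n",
            length(seg$gap_onsets_s), median(diff(seg$gap_onsets_s)),
            1 / median(diff(seg$gap_onsets_s))))
cat(sprintf("envelope inside gaps: %.2f of background (modulation depth %g%%)\n",
            min(seg$envelope), gap_assr_spec()$modulation_depth_pct))

burst <- generate_noise_burst(noise_burst_spec(), fs = 44100, seed = 1)
sp <- stats::spec.pgram(stats::ts(burst$wave, frequency = 44100), plot = FALSE,
                        taper = 0)
inband <- sum(sp$spec[sp$freq >= 1000 & sp$freq <= 12000]) / sum(sp$spec)
cat(sprintf("noise burst: %d ms, %.1f%% of power inside 1-12 kHz\n",
            round(1000 * length(burst$wave) / burst$fs), 100 * inband))

ev <- schedule_session(seed = 1)
write_events(ev, file.path(out, "events_default_session.tsv"))
counts <- table(ev$gap_width_ms)
cat(sprintf("session: %.0f min total, %d gap segments, per-width trial counts %d-%d\n",
            attr(ev, "total_duration_s") / 60, sum(ev$kind == "gap_segment"),
            min(counts), max(counts)))

png(file.path(out, "gap_segment_waveform.png"), 900, 360)
plot(seg$t * 1000, seg$wave, type = "l", col = "grey40",
     xlab = "time (ms)", ylab = "amplitude",
     main = "Gap-interrupted noise segment (width 5 ms, depth 75%)")
lines(seg$t * 1000, seg$envelope * max(abs(seg$wave)), col = "red3", lwd = 2)
dev.off()
cat("wrote", file.path(out, "events_default_session.tsv"), "and waveform figure\n")
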