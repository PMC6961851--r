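#!/usr/bin/env Rscript
# Maneuver detection and characterization: regrips on D, sniffs on the
# ventral L, their amplitudes/FWHMs/rates, and sniff timing relative to
# the holding-to-oromanual transition.
#
# Writes:
#   results/regrip_events.csv / results/sniff_events.csv   per-event tables
#   results/maneuver_summary.csv                           per-animal summary

suppressPackageStartupMessages(library(handkin))

sessions <- list.dirs("results/sessions", recursive = FALSE)
stopifnot(length(sessions) > 0)

ev_rows <- list(); sn_rows <- list(); summary_rows <- list()
for (dir in sessions) {
  mouse <- basename(dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  cal <- truth$calibration
  eth <- read_ethogram(file.path(dir, "ethogram.csv"),
                       truth$video_length_frames)
  f <- compute_features(calibrate(
    read_tracking_table(file.path(dir, "front.csv")), cal))
  fv <- compute_features(calibrate(
    read_tracking_table(file.path(dir, "ventral.csv"), view = "ventral"), cal))
  total_s <- truth$video_length_frames / cal$fps

  ev <- peak_metrics(f, detect_regrips(f, eth = eth), cal$fps)
  sn <- peak_metrics(fv, detect_sniffs(fv), cal$fps)
  timing <- maneuver_rates_and_timing(sn, eth, cal$fps, total_s)
  ev$mouse <- mouse; sn$mouse <- mouse
  sn$latency_next_s <- timing$latency_next
  sn$latency_prev_s <- timing$latency_prev
  ev_rows[[mouse]] <- ev; sn_rows[[mouse]] <- sn

  summary_rows[[mouse]] <- data.frame(
    mouse = mouse,
    regrip_rate_hz = nrow(ev) / total_s,
    regrip_fwhm_ms = median(ev$fwhm, na.rm = TRUE) * 1000,
    regrip_amplitude_mm = median(ev$amplitude, na.rm = TRUE),
    sniff_rate_hz = nrow(sn) / total_s,
    sniff_fwhm_ms = median(sn$fwhm, na.rm = TRUE) * 1000,
    sniff_amplitude_mm = median(sn$amplitude, na.rm = TRUE),
    sniff_latency_next_ms = median(timing$latency_next, na.rm = TRUE) * 1000,
    sniff_latency_prev_ms = median(timing$latency_prev, na.rm = TRUE) * 1000)
}

write.csv(do.call(rbind, ev_rows), "results/regrip_events.csv",
          row.names = FALSE)
write.csv(do.call(rbind, sn_rows), "results/sniff_events.csv",
          row.names = FALSE)
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/maneuver_summary.csv", row.names = FALSE)

med_mad <- function(x) sprintf("%.3g +/- %.2g", median(x),
                               median(abs(x - median(x))))
cat("Per-animal maneuver summary (median +/- m.a.d. across mice):\n")
cat("  regrip rate:      ", med_mad(summary$regrip_rate_hz), "Hz\n")
cat("  regrip FWHM:      ", med_mad(summary$regrip_fwhm_ms), "ms\n")
cat("  regrip amplitude: ", med_mad(summary$regrip_amplitude_mm), "mm\n")
cat("  sniff rate:       ", med_mad(summary$sniff_rate_hz), "Hz\n")
cat("  sniff FWHM:       ", med_mad(summary$sniff_fwhm_ms), "ms\n")
cat("  sniff amplitude:  ", med_mad(summary$sniff_amplitude_mm), "mm\n")
cat("  sniff-to-oromanual latency:",
    med_mad(summary$sniff_latency_next_ms), "ms\n")
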