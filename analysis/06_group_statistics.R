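#!/usr/bin/env Rscript
# Group-level statistics with the pipeline's aggregation conventions:
# median +/- m.a.d. across animal medians, exact signed-rank comparison of
# the paired cluster centroids, and multiple-comparison flags.
#
# Reads the tables written by 02 and 03; writes results/group_statistics.csv.

suppressPackageStartupMessages(library(handkin))

centroids <- read.csv("results/cluster_centroids.csv")
maneuvers <- read.csv("results/maneuver_summary.csv")
phases <- read.csv("results/phase_stats.csv")

hold_L <- centroids$L_mm[centroids$phase == "holding"]
oro_L <- centroids$L_mm[centroids$phase == "oromanual"]

# paired comparison of holding vs oromanual L centroids across mice
sr <- signed_rank_test(hold_L, oro_L)
cat(sprintf("holding vs oromanual L centroid: W = %g, p = %.4g (%s, n = %d)\n",
            sr$W, sr$p, sr$method, sr$n))

summarize <- function(x) {
  g <- aggregate_median_mad(as.list(x))
  c(median = g$median, mad = g$mad)
}
rows <- rbind(
  data.frame(quantity = "switch_rate_hz",
             t(summarize(phases$switch_rate_hz))),
  data.frame(quantity = "duty_cycle", t(summarize(phases$duty_cycle))),
  data.frame(quantity = "holding_L_mm", t(summarize(hold_L))),
  data.frame(quantity = "oromanual_L_mm", t(summarize(oro_L))),
  data.frame(quantity = "regrip_rate_hz",
             t(summarize(maneuvers$regrip_rate_hz))),
  data.frame(quantity = "regrip_fwhm_ms",
             t(summarize(maneuvers$regrip_fwhm_ms))),
  data.frame(quantity = "sniff_fwhm_ms",
             t(summarize(maneuvers$sniff_fwhm_ms))),
  data.frame(quantity = "sniff_latency_next_ms",
             t(summarize(maneuvers$sniff_latency_next_ms))))
write.csv(rows, "results/group_statistics.csv", row.names = FALSE)

# sniff latency to the next oromanual onset vs time since the previous one
lat <- signed_rank_test(maneuvers$sniff_latency_next_ms,
                        maneuvers$sniff_latency_prev_ms)
cat(sprintf("sniff latency-to-next vs time-since-previous: W = %g, p = %.4g\n",
            lat$W, lat$p))

flags <- adjust_pvalues(c(centroid_L = sr$p, sniff_latency = lat$p))
print(flags)

cat("\ngroup summaries (median +/- m.a.d. across mice):\n")
for (i in seq_len(nrow(rows))) {
  cat(sprintf("  %-22s %.3g +/- %.2g\n", rows$quantity[i], rows$median[i],
              rows$mad[i]))
}
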