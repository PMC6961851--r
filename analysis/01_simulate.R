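#!/usr/bin/env Rscript
# Simulate a cohort of food-handling sessions with full ground truth.
#
# Stands in for the videography + tracking + annotation stages: eight
# simulated "mice", one 120 s session each, emitted in the exact input
# dialects the readers consume (DeepLabCut-style tracking CSV, ethogram
# CSV, truth/params JSON). Per-animal seeds derive from a single base seed
# so the whole workflow is reproducible end to end.

suppressPackageStartupMessages(library(handkin))

base_seed <- 20260921L
n_mice <- 8L
out_root <- "results/sessions"

params <- generator_params(duration = 120)
for (m in seq_len(n_mice)) {
  dir <- file.path(out_root, sprintf("mouse%02d", m))
  session <- generate_session(params, seed = base_seed + m)
  paths <- write_fixtures(session, dir)
  truth <- session$truth
  cat(sprintf(
    "mouse%02d: %d frames, %d phases, %d true regrips, %d true sniffs -> %s\n",
    m, nrow(session$front$x), nrow(truth$ethogram),
    length(truth$regrip_times), length(truth$sniff_times), dir))
}
cat(sprintf("\nwrote %d sessions under %s\n", n_mice, out_root))
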