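#!/usr/bin/env Rscript
# Run the full analysis pipeline on each simulated cohort: 1 Hz
# subsampling, kinematics, camera-to-cardinal correction, the
# non-oriented / device-biased / oriented screen, reference directions and
# the hypothesis battery. Writes per-larva tables, group summaries, trend
# curves and a run summary per cohort.

suppressPackageStartupMessages(library(discorient))

for (nm in c("h0", "h1", "h4")) {
  data_dir <- file.path("results/cohorts", nm)
  if (!dir.exists(data_dir)) stop("run analysis/01_simulate_cohorts.R first")
  rep <- run_pipeline(data_dir, out_dir = file.path("results/runs", nm))
  cat(sprintf(
    "%s: %s oriented, %d device-biased, %d non-oriented\n",
    nm, format_oriented_fraction(rep$counts$oriented, rep$counts$total),
    rep$counts$device_biased, rep$counts$non_oriented
  ))
}
cat("per-larva and group-summary tables under results/runs/\n")
cat("\nNote the goalless (h0) cohort: most larvae still pass the individual\n")
cat("Rayleigh screen because 1 Hz positions of a slow confined walk are\n")
cat("autocorrelated - the per-larva test is anti-conservative. The\n")
cat("population-level second-order test (03) is the calibrated guard: h0\n")
cat("shows no common bearing there.\n")
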