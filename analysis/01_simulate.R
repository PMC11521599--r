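#!/usr/bin/env Rscript
# Simulate one synthetic MEA recording per condition preset and store them
# for the downstream analysis steps. The presets emulate decreasing
# activity, burstiness and signal patterning: "patterned" (pure neuronal
# culture profile), "intermediate" (few added astrocytes) and "irregular"
# (astrocyte-rich co-culture profile).
#
# Sizes here are desk-scale: 16 channels x 120 s at 10 kHz per condition.

suppressPackageStartupMessages(library(astromea))

seed <- 20260927L
dir.create("results/recordings", showWarnings = FALSE, recursive = TRUE)

summary_rows <- list()
for (cond in c("patterned", "intermediate", "irregular")) {
  params <- generator_params(cond, n_channels = 16, duration_s = 120,
                             sampling_rate = 10000, seed = seed)
  sim <- render_recording(params)
  write_recording(sim$recording,
                  file.path("results/recordings", paste0(cond, ".rds")))
  saveRDS(sim$ground_truth,
          file.path("results/recordings", paste0(cond, "_ground_truth.rds")))
  nsp <- vapply(sim$ground_truth$channels,
                function(g) length(g$spike_times), numeric(1))
  nbu <- vapply(sim$ground_truth$channels,
                function(g) nrow(g$bursts), numeric(1))
  summary_rows[[cond]] <- data.frame(
    condition = cond, n_channels = params$n_channels,
    duration_s = params$duration_s,
    mean_sr_hz = mean(nsp) / params$duration_s,
    mean_br_hz = mean(nbu) / params$duration_s)
  cat(sprintf("%-12s %d channels, %.0f s: mean ground-truth SR %.2f Hz, BR %.3f Hz\n",
              cond, params$n_channels, params$duration_s,
              mean(nsp) / params$duration_s, mean(nbu) / params$duration_s))
}

write_results(list(simulation_summary = do.call(rbind, summary_rows)),
              "results", seed = seed, overwrite = TRUE)
cat("recordings and ground truth written under results/recordings/\n")
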