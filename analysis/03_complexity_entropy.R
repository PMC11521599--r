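#!/usr/bin/env Rscript
# Complexity-entropy causality plane of each simulated condition: 40 Hz
# lowpass + 1 kHz resampling, then one (Hs, Cjs) point per channel with
# embedding dimension M = 5 and lag tau = 100 samples. Patterned activity
# should sit at low entropy / high complexity; irregular activity near the
# (1, 0) corner.

suppressPackageStartupMessages(library(astromea))

cfg <- analysis_config(analysis_window = c(10, 110))
planes <- list()

for (cond in c("patterned", "intermediate", "irregular")) {
  rec <- read_recording(file.path("results/recordings", paste0(cond, ".rds")))
  win <- slice_window(rec, cfg$analysis_window[1], cfg$analysis_window[2])
  pts <- ce_plane(ce_preprocess(win, cfg), cfg)
  planes[[cond]] <- cbind(condition = cond, pts)
  cat(sprintf("%-12s Hs %.3f +/- %.3f   Cjs %.3f +/- %.3f\n",
              cond, mean(pts$Hs), sd(pts$Hs), mean(pts$Cjs), sd(pts$Cjs)))
}

write_results(list(ce_plane = do.call(rbind, planes)), "results",
              overwrite = TRUE)
cat("complexity-entropy plane written to results/ce_plane.csv\n")
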