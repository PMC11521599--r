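#!/usr/bin/env Rscript
# Waveform analysis: extract 3 ms cutouts around every detected spike,
# cluster them per channel, average each cluster, compute the five shape
# features and classify into RS / FS / TS / CS / PS; report the class
# prevalence per condition.

suppressPackageStartupMessages(library(astromea))

cfg <- analysis_config(analysis_window = c(10, 110))
classes <- list(); prevalence <- list()

for (cond in c("patterned", "intermediate", "irregular")) {
  rec <- read_recording(file.path("results/recordings", paste0(cond, ".rds")))
  win <- slice_window(rec, cfg$analysis_window[1], cfg$analysis_window[2])
  filtered <- bandpass_spike(win, cfg)
  spikes <- detect_spikes(filtered, k = cfg$spike_threshold_k,
                          dead_time_ms = cfg$spike_dead_time_ms)
  cut <- extract_cutouts(filtered, spikes, cfg$cutout_pre_ms,
                         cfg$cutout_post_ms)
  cls <- classify_cutouts(cut, cfg)
  prev <- waveform_prevalence(cls)
  classes[[cond]] <- cbind(condition = cond, cls)
  prevalence[[cond]] <- cbind(condition = cond, prev)
  cat(sprintf("%-12s %d cutouts -> %d averaged waveforms: %s\n",
              cond, nrow(cut$waveforms), nrow(cls),
              paste(sprintf("%s %.0f%%", prev$class, prev$percent),
                    collapse = ", ")))
}

write_results(list(waveform_classes = do.call(rbind, classes),
                   waveform_prevalence = do.call(rbind, prevalence)),
              "results", overwrite = TRUE)
cat("waveform tables written under results/\n")
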