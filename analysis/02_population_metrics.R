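#!/usr/bin/env Rscript
# Population sleep metrics (FPS, BF, MSBD) and their recovery of the
# simulator's programmed sleep fraction.
#
# Part A reads the demonstration cohort written by 01 and reports pooled
# metrics per cohort: the mutant cohort should show a clearly lower FPS.
# Part B regenerates 20 replicates of 30 control animals from seeds and
# checks that the mean pooled FPS over a 10-min mid-lethargus window
# recovers the 30% target within sampling error.

suppressPackageStartupMessages(library(wormsleep))

dir.create("results", showWarnings = FALSE)

## Part A: metrics on the demonstration cohort
traces <- read_traces("results/01_demo_traces.csv")
cohort <- sub("_[0-9]+$", "", names(traces))
rows <- lapply(unique(cohort), function(g) {
  m <- population_metrics(traces[cohort == g])
  cbind(cohort = g, m)
})
metrics <- do.call(rbind, rows)
utils::write.csv(metrics, "results/02_population_metrics.csv",
                 row.names = FALSE)
cat("Pooled metrics per cohort (bf in bouts/sec, msbd in sec):\n")
print(metrics, row.names = FALSE, digits = 3)

## Part B: FPS recovery across seeded replicates
params <- bout_params()
rep_fps <- vapply(1:20, function(r) {
  wins <- lapply(1:30, function(i) {
    s <- r * 10000L + i
    sched <- simulate_bouts(params, duration = 12000, seed = s)
    tr <- bouts_to_velocity(sched, dt = 1, seed = s,
                            animal_id = sprintf("r%02da%02d", r, i))
    sample_window(tr, start = params$lethargus_start + 3600, length = 600)
  })
  population_metrics(wins)$fps
}, 0)
recovery <- data.frame(replicate = 1:20, fps = rep_fps)
utils::write.csv(recovery, "results/02_fps_recovery.csv", row.names = FALSE)

se <- sd(rep_fps) / sqrt(length(rep_fps))
cat(sprintf(
  "\nFPS recovery: mean %.4f (target %.2f), SE %.4f -> |dev| = %.2f SE\n",
  mean(rep_fps), params$sleep_fraction_target, se,
  abs(mean(rep_fps) - params$sleep_fraction_target) / se))
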