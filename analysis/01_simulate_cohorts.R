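#!/usr/bin/env Rscript
# Simulate velocity-trace cohorts for the population sleep assay.
#
# Two cohorts of mid-lethargus animals are generated with the alternating
# sleep/motion bout simulator: a control cohort at the wild-type lethargus
# sleep fraction (30%) and a "sleepless" mutant cohort at a third of that.
# A small demonstration cohort is written as CSV for the downstream driver;
# the full-size populations used for metric recovery are regenerated from
# seeds in 02 so no large files are stored.

suppressPackageStartupMessages(library(wormsleep))

dir.create("results", showWarnings = FALSE)
seed0 <- 20260101L %% 100000L

control <- bout_params()  # target sleep fraction 0.30, lethargus [2, 4.5] hr
mutant <- bout_params(sleep_fraction_target = 0.10, mean_sleep_bout = 20)

make_cohort <- function(params, n, tag) {
  lapply(seq_len(n), function(i) {
    s <- seed0 + i + ifelse(tag == "control", 0L, 500L)
    sched <- simulate_bouts(params, duration = 12000, seed = s)
    bouts_to_velocity(sched, dt = 1, seed = s,
                      animal_id = sprintf("%s_%02d", tag, i))
  })
}

# two animals per cohort are enough to demonstrate the file interface;
# velocities are rounded to 3 decimals (0.001 mm/s, below the motionless
# eps) to keep the demonstration file small
demo <- c(make_cohort(control, 2, "control"), make_cohort(mutant, 2, "mutant"))
demo_windows <- lapply(demo, function(tr) {
  w <- sample_window(tr, start = control$lethargus_start + 3600, length = 600)
  velocity_trace(round(w$velocity, 3), dt = w$dt, t0 = w$t0,
                 animal_id = w$animal_id, tracked = w$tracked)
})
write_traces(demo_windows, "results/01_demo_traces.csv")

cat("Wrote results/01_demo_traces.csv:",
    length(demo_windows), "animals x 600 s at dt = 1 s\n")
cat("Cohort targets: control sleep fraction",
    control$sleep_fraction_target, "| mutant",
    mutant$sleep_fraction_target, "\n")
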