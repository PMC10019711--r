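#!/usr/bin/env Rscript
# Build the stimulus schedules for the three experiments, tabulate the
# stimulus-level statistics (entropy, similarity, spectro-temporal density),
# and materialise a few example trials. Large/binary artefacts (full event
# tables, audio) go to scratch/; compact tables go to results/.

suppressPackageStartupMessages(library(awaredyn))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

seed <- 20230316

# -- condition grids and their statistics ------------------------------------
stats <- do.call(rbind, lapply(c("I", "II", "III"), function(e) {
  g <- experiment_conditions(e)
  cbind(experiment = e, g)
}))
write.csv(stats, "results/condition_statistics.csv", row.names = FALSE)
cat("condition grids: 27 cells per experiment;",
    "entropy range", paste(round(range(stats$entropy), 2), collapse = "-"),
    "nats; spectro-temporal density range",
    paste(round(range(stats$std), 1), collapse = "-"), "s^-1 oct^-1\n")

# unique (fpo, interval range) -> entropy, the uncertainty table
u <- unique(stats[c("fpo", "iti_min", "iti_max")])
u$delta <- u$iti_max - u$iti_min
u$entropy <- masker_entropy(u$fpo, u$iti_min, u$iti_max)
u <- u[order(u$fpo, u$delta), ]
write.csv(u, "results/masker_entropy_table.csv", row.names = FALSE)
cat("masker uncertainty spans", round(min(u$entropy), 2), "to",
    round(max(u$entropy), 2), "nats across the parameter sets\n")

# -- schedules ---------------------------------------------------------------
for (e in c("I", "II", "III")) {
  s <- build_schedule(e, seed)
  write.csv(s, sprintf("scratch/schedule_exp%s.csv", e), row.names = FALSE)
  cat(sprintf("experiment %s: %d trials (%d target / %d catch), blocks %s\n",
              e, nrow(s), sum(s$target_present), sum(!s$target_present),
              paste(table(s$block), collapse = "/")))
}

# -- example trial events and audio ------------------------------------------
s1 <- build_schedule("I", seed)
ex <- materialize_schedule(s1[1:2, ])
ex$onset_s <- round(ex$onset_s, 4)
write.csv(ex, "results/example_trial_events.csv", row.names = FALSE)
cat("example event table:", nrow(ex), "tone events over 2 trials\n")

wav <- render_audio(materialize_schedule(s1[1, ]))
write_wav(wav, "scratch/example_trial.wav")
cat("rendered scratch/example_trial.wav, peak",
    round(max(abs(wav)), 3), "\n")
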