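#!/usr/bin/env Rscript
# Simulate the study cohort: 8 control and 7 LPS-treated mice, each with a
# noisy whole-brain TAC on the 25-frame / 120-min schedule, a shared
# arterial plasma sampling series, and known generating kinetics.
# Writes results/cohort/{tac,plasma,truth}.csv.

library(petkin)

cfg <- generator_config(base_seed = 1)     # study defaults: n = 8 + 7
cohort <- generate_cohort(cfg)
dir <- file.path("results", "cohort")
write_cohort(cohort, dir)

truth <- read.csv(file.path(dir, "truth.csv"))
cat("Simulated", nrow(truth), "subjects ->", dir, "\n")
cat("Generating VT, control:",
    round(mean(truth$VT[truth$group == "control"]), 2), "+/-",
    round(sd(truth$VT[truth$group == "control"]), 2), "\n")
cat("Generating VT, LPS:    ",
    round(mean(truth$VT[truth$group == "lps"]), 2), "+/-",
    round(sd(truth$VT[truth$group == "lps"]), 2), "\n")
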