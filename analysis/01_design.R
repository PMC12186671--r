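#!/usr/bin/env Rscript
# Round-1 and round-2 experimental designs for the biosensor library.
#
# Builds the 32-run D-optimal design over the 320-context factor space
# (promoter x RBS x medium x supplement, one-hot linear design model),
# augments it with 32 more runs, and situates both against random designs.

library(biosensordbtl)

seed <- 20260926
dir.create("results", showWarnings = FALSE)

r1 <- d_optimal(n_runs = 32, seed = seed, n_restarts = 4)
r2 <- augment_design(r1$design, n_additional = 32, seed = seed + 1)

write_design_csv(r1$design, "results/design_round1.csv")
write_design_csv(r2$design, "results/design_combined.csv")

set.seed(seed + 2)
cand <- full_factorial()
rand32 <- replicate(1000, design_log_det(cand[sample.int(320, 32), ]))

cat("Round 1: 32-run D-optimal design, log det(X'X) =",
    round(r1$log_det, 3), "\n")
cat("  best of 1000 random 32-run designs:", round(max(rand32), 3),
    " (margin", round(r1$log_det - max(rand32), 3), ")\n")
cat("Round 2: augmented to 64 runs, log det =", round(r2$log_det, 3),
    " (monotone gain", round(r2$log_det - r1$log_det, 3), ")\n")
cat("Designs written to results/design_round1.csv and",
    "results/design_combined.csv\n")
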