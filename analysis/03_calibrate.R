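#!/usr/bin/env Rscript
# Model calibration: growth-law fits for every experiment (shared k1, k2),
# an OD fit-quality table, and bootstrap-bagged kinetic ensembles for a
# desk-scale subset of contexts (50 iterations each).

library(biosensordbtl)

seed <- 20260926
design <- read_design_csv("results/design_combined.csv")
lib <- long_to_experiments(utils::read.csv("results/experiments_long.csv",
                                           stringsAsFactors = FALSE))

## growth fits ---------------------------------------------------------------
jf <- fit_growth_joint(lib, seed = seed + 20)
names(jf$growth) <- names(lib)

rmse_pct <- vapply(seq_along(lib), function(i) {
  e <- lib[[i]]
  y <- rowMeans(e$od)
  yhat <- double_logistic(e$times, jf$growth[[i]])
  100 * sqrt(mean((y - yhat)^2)) / diff(range(y))
}, numeric(1))

gtab <- do.call(rbind, lapply(names(jf$growth), function(cid)
  data.frame(context_id = cid, as.list(unclass(jf$growth[[cid]])))))
gtab$od_rmse_pct <- rmse_pct
utils::write.csv(gtab, "results/growth_fits.csv", row.names = FALSE)

cat("Fitted", length(lib), "growth curves; shared k1 =", round(jf$k1, 3),
    ", k2 =", round(jf$k2, 3), "\n")
cat("Experimental-vs-simulated OD RMSE: mean", round(mean(rmse_pct), 2),
    "% of range, max", round(max(rmse_pct), 2), "%\n")

## kinetic bagging on a context subset ---------------------------------------
subset_ids <- names(lib)[seq(1, length(lib), length.out = 4)]
ens_rows <- list()
for (j in seq_along(subset_ids)) {
  cid <- subset_ids[j]
  pb <- context_fit_problem(lib[[cid]], jf$growth[[cid]])
  ens <- bagging_ensemble(pb, n_iterations = 50,
                          seed = seed + 30 + j, budget = 400, pop_size = 8)
  spread <- apply(log(ens$matrix), 2, sd)
  cat("Context", cid, ": 50 bagged refits, log-scale parameter sd",
      paste(round(spread, 3), collapse = " / "), "\n")
  mat <- ens$matrix
  colnames(mat) <- sub("\\..*$", "", colnames(mat))   # strip scope suffix
  ens_rows[[cid]] <- data.frame(context_id = cid,
                                iteration = seq_len(nrow(mat)),
                                mat, check.names = FALSE)
}
utils::write.csv(do.call(rbind, ens_rows),
                 "results/ensemble_parameters.csv", row.names = FALSE)
cat("Bagged ensemble matrix written to results/ensemble_parameters.csv\n")
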