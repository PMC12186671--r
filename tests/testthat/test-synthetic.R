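test_that("ground truth respects the scoped variability structure", {
  gt <- test_gt(7)
  # two contexts sharing a medium share every medium-scoped rate exactly
  k_a <- resolve_kinetics(gt, c(medium = "M0", supplement = "S0",
                                promoter = "P1", rbs = "R1"))
  k_b <- resolve_kinetics(gt, c(medium = "M0", supplement = "S1",
                                promoter = "P2", rbs = "R2"))
  for (nm in c("K_mRNAp", "K_mRNAdeg", "K_P", "K_lysis"))
    expect_identical(k_a[[nm]], k_b[[nm]])
  # globals shared, promoter strength differs, references pinned at 1
  expect_identical(k_a$vmax_NAR, k_b$vmax_NAR)
  expect_identical(k_a$K_Pk, 1)
  expect_identical(k_a$K_mRNAdeg, 1)
  # counting over the factorial space: 320 RBS strengths, 4 promoter values
  expect_equal(length(unique(gt$contexts$RBS_strength)), 320)
  expect_equal(length(unique(gt$promoter)), 4)
  expect_equal(nrow(gt$contexts), 320)
  # reproducibility
  expect_identical(test_gt(7), gt)
})

test_that("experiments carry the configured replicate noise", {
  gt <- test_gt(7)
  ctx <- test_context()
  # zero noise: replicates equal the noiseless simulation
  e0 <- generate_experiment(ctx, gt, noise = noise_spec(0, 0, 3), seed = 1)
  expect_equal(e0$gfp[, 1], e0$truth$gfp_per_od)
  expect_equal(e0$gfp[, 1], e0$gfp[, 3])
  expect_equal(ncol(e0$od), 3)
  # default noise: replicate sd at high signal tracks proportional_sd * y
  sds <- vapply(1:100, function(s) {
    e <- generate_experiment(ctx, gt, noise = noise_spec(0.05, 0, 3),
                             seed = s)
    i <- which.max(e$truth$gfp_per_od)
    sd(e$gfp[i, ])
  }, numeric(1))
  target <- 0.05 * max(gt_truth <- generate_experiment(
    ctx, gt, noise = noise_spec(0, 0, 1), seed = 1)$truth$gfp_per_od)
  expect_lt(abs(mean(sds) - target) / target, 0.25)
  # determinism of the noise draws
  e1 <- generate_experiment(ctx, gt, seed = 5)
  e2 <- generate_experiment(ctx, gt, seed = 5)
  expect_identical(e1$gfp, e2$gfp)
})

test_that("library generation is per-run seeded and design-shaped", {
  gt <- test_gt(7)
  des <- d_optimal(n_runs = 32, seed = 3, n_restarts = 1)$design
  lib <- generate_library(des, gt, seed = 9)
  expect_length(lib, 32)
  expect_identical(generate_library(des, gt, seed = 9), lib)
  # a 4x4 media-by-supplement screen of one construct gives 16 experiments
  screen <- expand.grid(medium = paste0("M", 0:3),
                        supplement = paste0("S", 0:3),
                        stringsAsFactors = FALSE)
  screen$promoter <- "P2"; screen$rbs <- "R3"
  lib16 <- generate_library(screen, gt, seed = 4)
  expect_length(lib16, 16)
})

test_that("long-format round trip preserves the data", {
  gt <- test_gt(7)
  des <- data.frame(medium = c("M0", "M2"), supplement = c("S0", "S1"),
                    promoter = c("P1", "P3"), rbs = c("R1", "R4"))
  lib <- generate_library(des, gt, seed = 2)
  long <- experiments_to_long(lib)
  expect_setequal(names(long), c("context_id", "medium", "supplement",
                                 "promoter", "rbs", "replicate", "time_h",
                                 "od", "gfp_per_od"))
  back <- long_to_experiments(long)
  expect_equal(back[[1]]$od, lib[[1]]$od, ignore_attr = TRUE)
  expect_equal(back[[2]]$gfp, lib[[2]]$gfp, ignore_attr = TRUE)
  expect_identical(unname(back[[2]]$context), unname(lib[[2]]$context))
})
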