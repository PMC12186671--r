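make_noisefree_problem <- function(seed = 42, uniform_weights = TRUE,
                                   free = NULL) {
  gt <- test_gt(seed)
  ctx <- test_context()
  gp <- resolve_growth(gt, ctx)
  kp <- resolve_kinetics(gt, ctx)
  e <- generate_experiment(ctx, gt, noise = noise_spec(0, 0, 3), seed = 1)
  if (is.null(free))
    free <- c(paste0("RBS_strength.", context_id(ctx)), "K_P.M0", "K_NFDER")
  w <- if (uniform_weights)
    list(list(od = rep(1, length(e$times)), gfp = rep(1, length(e$times))))
  else NULL
  truth <- setNames(vapply(free, function(nm)
    kp[[strsplit(nm, ".", fixed = TRUE)[[1]][1]]], numeric(1)), free)
  list(problem = fit_problem(e, free = free, lower = 1e-2, upper = 1e2,
                             growth = gp, kinetics = kp, weights = w),
       truth = truth, gt = gt, ctx = ctx, gp = gp, kp = kp, exp = e)
}

test_that("weighted cost is a weighted sum of squared residuals", {
  setup <- make_noisefree_problem()
  # model equals data at the generating parameters: zero cost
  expect_equal(weighted_cost(setup$truth, setup$problem), 0)
  # hand-written residual check: shift the gfp data by known residuals
  r <- c(rep(0, 92), 2, -1, 0.5, 0, 3)
  w <- runif(97, 0.5, 2)
  pb <- setup$problem
  pb$experiments[[1]]$gfp <- pb$experiments[[1]]$gfp + r
  pb$weights <- list(list(od = rep(1, 97), gfp = w))
  expect_equal(weighted_cost(setup$truth, pb), sum(w * r^2),
               tolerance = 1e-10)
  # single-point arithmetic: residual 2, weight 1 contributes 4
  pb2 <- setup$problem
  pb2$experiments[[1]]$gfp <- pb2$experiments[[1]]$gfp +
    c(2, rep(0, 96))
  expect_equal(weighted_cost(setup$truth, pb2), 4, tolerance = 1e-10)
})

test_that("weights invert the replicate variance with a floor", {
  gt <- test_gt(3)
  e <- generate_experiment(test_context(), gt, noise = noise_spec(0, 0, 3),
                           seed = 1)
  # identical replicates: all weights at the floor-determined constant
  w0 <- estimate_weights(e)
  expect_equal(length(unique(round(w0$gfp, 6))), 1)
  # doubling the sd at one point quarters its weight
  e2 <- e
  e2$gfp <- e2$gfp + matrix(rnorm(97 * 3, 0, 0.05), 97, 3)
  e3 <- e2
  e3$gfp[50, ] <- mean(e3$gfp[50, ]) +
    2 * (e3$gfp[50, ] - mean(e3$gfp[50, ]))
  w2 <- estimate_weights(e2); w3 <- estimate_weights(e3)
  expect_equal(w3$gfp[50] / w2$gfp[50], 0.25, tolerance = 1e-8)
  # single replicate falls back to uniform weights with a warning
  e1 <- e; e1$od <- e1$od[, 1, drop = FALSE]; e1$gfp <- e1$gfp[, 1, drop = FALSE]
  expect_warning(w1 <- estimate_weights(e1), "single replicate")
  expect_true(all(w1$od == 1))
})

test_that("replicate variance estimates track the true noise law", {
  # sigma_t = 0.05 y_t; across 200 seeded datasets the pooled per-point
  # variance should sit within 30% of truth for >= 80% of high-signal points
  gt <- test_gt(3)
  truth <- generate_experiment(test_context(), gt,
                               noise = noise_spec(0, 0, 1), seed = 1)$truth
  s2 <- matrix(NA_real_, 97, 200)
  for (s in 1:200) {
    e <- generate_experiment(test_context(), gt,
                             noise = noise_spec(0.05, 0, 3), seed = 1000 + s)
    s2[, s] <- apply(e$gfp, 1, var)
  }
  sigma2 <- (0.05 * truth$gfp_per_od)^2
  hi <- which(truth$gfp_per_od > 0.2 * max(truth$gfp_per_od))
  rel <- abs(rowMeans(s2)[hi] - sigma2[hi]) / sigma2[hi]
  expect_gte(mean(rel <= 0.3), 0.8)
})

test_that("growth fitting recovers known parameters", {
  gt <- test_gt(11)
  ctx <- c(medium = "M1", supplement = "S2", promoter = "P2", rbs = "R3")
  gp <- resolve_growth(gt, ctx)
  # noise-free: (L1, a1, t1) within 1% relative
  e <- generate_experiment(ctx, gt, noise = noise_spec(0, 0, 3), seed = 1)
  fg <- fit_growth(e, seed = 1)
  expect_equal(unname(fg$fit$k_hat[c("L1", "a1", "t1")]),
               c(gp$L1, gp$a1, gp$t1), tolerance = 0.01)
  # single-logistic truth: fitted second-phase gain collapses
  gp1 <- growth_params(1.2, 0.7, 6, k1 = 0, k2 = 1.3)
  e1 <- e
  e1$od <- matrix(double_logistic(e$times, gp1), 97, 3)
  fg1 <- fit_growth(e1, seed = 2)
  expect_lte(fg1$fit$k_hat[["k1"]], 1e-3 * fg1$fit$k_hat[["L1"]])
  # degenerate input is refused
  eflat <- e; eflat$od <- matrix(0.5, 97, 3)
  expect_error(fit_growth(eflat), "degenerate")
})

test_that("calibration meets the known-truth oracle and is deterministic", {
  setup <- make_noisefree_problem()
  fit <- calibrate(setup$problem, seed = 3, budget = 1500)
  expect_lte(fit$cost, weighted_cost(setup$truth, setup$problem) + 1e-6)
  expect_true(all(fit$k_hat >= setup$problem$lower - 1e-12 &
                    fit$k_hat <= setup$problem$upper + 1e-12))
  # same seed -> bitwise identical
  fit2 <- calibrate(setup$problem, seed = 3, budget = 1500)
  expect_identical(fit$k_hat, fit2$k_hat)
  # collapsed bounds return the point itself
  pb <- setup$problem
  pb$lower <- pb$upper <- setup$truth
  fit3 <- calibrate(pb, seed = 1)
  expect_identical(fit3$k_hat, setup$truth)
  expect_equal(fit3$cost, 0)
})

test_that("bootstrap resampling preserves shape and replicate frequencies", {
  gt <- test_gt(3)
  e <- generate_experiment(test_context(), gt, seed = 2)
  # identical replicates resample to themselves
  e0 <- generate_experiment(test_context(), gt, noise = noise_spec(0, 0, 3),
                            seed = 2)
  expect_equal(bootstrap_resample(e0, seed = 1)$gfp, e0$gfp)
  # shape is preserved
  r <- bootstrap_resample(e, seed = 7)
  expect_identical(dim(r$od), dim(e$od))
  expect_identical(r$times, e$times)
  expect_identical(bootstrap_resample(e, seed = 7)$gfp, r$gfp)
  # each replicate drawn with frequency 1/3 +/- 0.02 at a fixed time point
  vals <- e$gfp[50, ]
  draws <- vapply(1:3500, function(s)
    bootstrap_resample(e, seed = s)$gfp[50, ], numeric(3))
  freq <- table(factor(match(as.vector(draws), vals), levels = 1:3)) /
    length(draws)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("bagging aggregates resampled refits deterministically", {
  setup <- make_noisefree_problem(
    free = c(paste0("RBS_strength.", context_id(test_context())), "K_P.M0"))
  # no noise, one iteration: the member refits the original data
  ens <- bagging_ensemble(setup$problem, n_iterations = 1, seed = 5,
                          budget = 400, pop_size = 8)
  expect_equal(nrow(ens$matrix), 1)
  member_traj <- simulate_biosensor(
    setup$gp, update_kp(setup$kp, ens$matrix[1, ]))
  truth_traj <- setup$exp$truth
  rng <- diff(range(truth_traj$gfp_per_od))
  expect_lt(sqrt(mean((member_traj$gfp_per_od -
                         truth_traj$gfp_per_od)^2)) / rng, 0.01)
  # reproducible member matrix, and spread appears once noise is present
  gt <- setup$gt
  e_noisy <- generate_experiment(test_context(), gt,
                                 noise = noise_spec(0.05, 0.01, 3), seed = 3)
  pbn <- fit_problem(e_noisy, free = setup$problem$free, lower = 1e-2,
                     upper = 1e2, growth = setup$gp, kinetics = setup$kp)
  ens2 <- bagging_ensemble(pbn, n_iterations = 6, seed = 8, budget = 250,
                           pop_size = 6)
  ens3 <- bagging_ensemble(pbn, n_iterations = 6, seed = 8, budget = 250,
                           pop_size = 6)
  expect_identical(ens2$matrix, ens3$matrix)
  expect_true(all(apply(ens2$matrix, 2, sd) > 0))
})
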