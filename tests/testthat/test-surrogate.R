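test_that("cross-validation metrics follow their definitions", {
  obs <- cbind(y = c(1, 2, 3, 4))
  expect_equal(cv_report(obs, obs)$q2_mean, 1)
  expect_equal(cv_report(obs, obs)$rmse_relative_mean, 0)
  # predicting the mean gives exactly zero explained variance
  expect_equal(unname(cv_report(matrix(rep(2.5, 4)), obs)$r2_per_target), 0)
  # 4-point example against spreadsheet-style arithmetic
  pred <- cbind(y = c(1.1, 1.9, 3.2, 3.8))
  got <- cv_report(pred, obs)
  press <- sum((obs - pred)^2)          # 0.01 + 0.01 + 0.04 + 0.04
  tss <- sum((obs - 2.5)^2)             # 5
  expect_equal(unname(got$q2), 1 - press / tss)
  expect_equal(unname(got$rmse_relative),
               100 * sqrt(press / 4) / 3)
  expect_error(cv_report(obs, cbind(y = rep(1, 4))), "zero observed range")
})

test_that("the kernel regressor realises linear maps and rejects noise", {
  pe <- default_promoter_encoding()
  set.seed(33)
  des <- full_factorial()[sample.int(320, 28), ]
  X <- encode_contexts(des, pe)
  beta <- rnorm(11)
  targets <- cbind(lin = as.numeric(scale(X) %*% beta))
  fit <- train_growth_surrogate(X, targets, seed = 1)
  expect_gte(fit$report$r2_per_target[["lin"]], 0.99)
  # LOO mechanics: one held-out prediction per training row
  expect_equal(nrow(fit$loo_predictions), 28)
  # pure-noise targets: no apparent skill in >= 90% of seeded trials
  ok <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    noise <- cbind(n = rnorm(28))
    f <- train_growth_surrogate(X, noise, seed = s)
    ok <- ok + (f$report$r2_per_target[["n"]] <= 0.2)
  }
  expect_gte(ok, 9)
  expect_error(train_growth_surrogate(X, cbind(k = rep(1, 28))),
               "degenerate")
  expect_error(train_growth_surrogate(X[1:10, ], targets[1:10, , drop = FALSE]),
               ">= 14")
})

test_that("no leakage: permuted labels yield no predictive skill", {
  pe <- default_promoter_encoding()
  set.seed(5)
  des <- full_factorial()[sample.int(320, 24), ]
  X <- encode_contexts(des, pe)
  gt <- test_gt(5)
  a1 <- log(gt$contexts$a1[match(context_id(des),
                                 gt$contexts$context_id)])
  q2s <- vapply(1:10, function(s) {
    set.seed(500 + s)
    f <- train_growth_surrogate(X, cbind(a1 = sample(a1)), seed = s,
                                costs = c(1, 10))
    f$report$r2_per_target[["a1"]]
  }, numeric(1))
  expect_lte(mean(q2s), 0.1)
})

test_that("the reporter network learns, interpolates and is reproducible", {
  pe <- default_promoter_encoding()
  set.seed(9)
  des <- full_factorial()[sample.int(320, 12), ]
  des$context_id <- context_id(des)
  # noise-free ensembles: every member equals the context's parameter pair
  par_true <- cbind(K_P = exp(runif(12, -0.5, 0.5)),
                    RBS_strength = exp(runif(12, -1, 1)))
  ens <- lapply(seq_len(12), function(i) {
    m <- par_true[rep(i, 20), , drop = FALSE]
    colnames(m) <- colnames(par_true)
    m
  })
  names(ens) <- des$context_id
  ts <- reporter_training_set(ens, des, pe)
  expect_equal(nrow(ts$x), 240)
  mod <- train_reporter_surrogate(ts$x, ts$y, seed = 2,
                                  hidden = c(32, 32, 16, 8), epochs = 300,
                                  dropout = 0, batch = 48)
  # training loss decreases from initialisation
  expect_lt(tail(mod$net$losses, 1), mod$net$losses[1])
  # interpolation sanity: training contexts recovered within 10% relative
  pred <- exp(predict_reporter_surrogate(mod, encode_contexts(des, pe)))
  expect_lt(max(abs(pred - par_true) / par_true), 0.10)
  # determinism: identical refit, identical predictions
  mod2 <- train_reporter_surrogate(ts$x, ts$y, seed = 2,
                                   hidden = c(32, 32, 16, 8), epochs = 300,
                                   dropout = 0, batch = 48)
  expect_identical(mod$net$losses, mod2$net$losses)
  expect_identical(predict_reporter_surrogate(mod2, encode_contexts(des, pe)),
                   predict_reporter_surrogate(mod, encode_contexts(des, pe)))
})

test_that("composed surrogates produce trajectories for any context", {
  pe <- default_promoter_encoding()
  gt <- test_gt(5)
  set.seed(14)
  des <- full_factorial()[sample.int(320, 20), ]
  des$context_id <- context_id(des)
  X <- encode_contexts(des, pe)
  rows <- gt$contexts[match(des$context_id, gt$contexts$context_id), ]
  growth_model <- train_growth_surrogate(
    X, cbind(log_a1 = log(rows$a1), log_t1 = log(rows$t1)), seed = 1,
    costs = c(1, 10))
  ens <- lapply(seq_len(20), function(i) {
    m <- cbind(K_Pk = rep(unname(gt$promoter[rows$promoter[i]]), 10),
               K_mRNAp = 1, K_mRNAdeg = 1, K_P = 1, K_lysis = 1,
               RBS_strength = rows$RBS_strength[i])
    m
  })
  names(ens) <- des$context_id
  ts <- reporter_training_set(ens, des, pe)
  reporter_model <- train_reporter_surrogate(ts$x, ts$y, seed = 1,
                                             hidden = c(16, 16, 8, 8),
                                             epochs = 60)
  aux <- list(L1 = mean(rows$L1), k1 = gt$globals$k1, k2 = gt$globals$k2)
  # a sample of unseen keys across the whole space: always a trajectory
  unseen <- full_factorial()[seq(1, 320, by = 13), ]
  for (i in seq_len(nrow(unseen))) {
    tr <- predict_response(unseen[i, ], growth_model, reporter_model, pe,
                           growth_aux = aux, globals = gt$globals)
    expect_true(all(tr$gfp_per_od >= 0) && all(tr$od > 0))
  }
})
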