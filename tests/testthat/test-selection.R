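test_that("candidates rank by gain descending and half-time ascending", {
  gains <- c(A = 10, B = 8, C = 5)
  top2 <- rank_candidates(gains, "gain", k = 2)
  expect_equal(top2$context_id, c("A", "B"))
  # k beyond the candidate count returns everything
  expect_equal(nrow(rank_candidates(gains, "gain", k = 10)), 3)
  # three-way tie at the minimum half-time shares rank 1
  ht <- c(E1 = 0.48, E2 = 0.48, E3 = 0.48, E4 = 1.2, E5 = 2)
  rt <- rank_candidates(ht, "half_time", k = 5, observed = ht)
  expect_equal(rt$predicted_rank[1:3], c(1, 1, 1))
  expect_equal(rt$predicted_rank[4], 4)
  # zero-response candidates are excluded, not fatal
  trajs <- list(
    good = data.frame(time_h = 0:10, gfp_per_od = 0:10),
    dead = data.frame(time_h = 0:10, gfp_per_od = rep(0, 11)))
  expect_message(rt2 <- rank_candidates(trajs, "half_time", k = 5),
                 "excluded")
  expect_equal(rt2$context_id, "good")
})

test_that("top-k overlap counts predicted hits among observed leaders", {
  # perfect agreement gives k
  obs <- c(a = 9, b = 8, c = 7, d = 6)
  rt <- rank_candidates(obs, "gain", k = 3, observed = obs)
  expect_equal(top_k_overlap(rt, 3), 3)
  # observed leaders entirely outside the predicted top-k give 0
  pred <- c(a = 1, b = 2, c = 10, d = 11)
  rt2 <- rank_candidates(pred, "gain", k = 2,
                         observed = c(a = 10, b = 9, c = 1, d = 2))
  expect_equal(top_k_overlap(rt2, 2), 0)
  rt3 <- rt2; rt3$observed_rank <- NULL
  expect_error(top_k_overlap(rt3, 2), "observed ranks")
})

test_that("kendall tau-b and exact one-tailed p match brute-force enumeration", {
  # exhaustive n = 3 and representative tie patterns at n = 4
  grid3 <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  xs3 <- split(as.matrix(grid3), seq_len(nrow(grid3)))
  for (x in list(c(1, 2, 3), c(1, 1, 2))) {
    for (y in xs3) {
      if (length(unique(y)) == 1) next
      got <- kendall_one_tailed(x, y)
      expect_equal(got$p, brute_kendall_p(x, y))
      expect_equal(got$tau, suppressWarnings(cor(x, y, method = "kendall")),
                   tolerance = 1e-12)
    }
  }
  set.seed(4)
  xs4 <- list(c(1, 2, 3, 4), c(1, 1, 2, 3), c(1, 1, 2, 2), c(1, 1, 1, 2))
  for (x in xs4) {
    for (rep in 1:40) {
      y <- sample(1:4, 4, replace = TRUE)
      if (length(unique(y)) == 1) next
      expect_equal(kendall_one_tailed(x, y)$p, brute_kendall_p(x, y))
    }
  }
  expect_error(kendall_one_tailed(c(1, 1, 1), c(1, 2, 3)), "tau undefined")
  expect_error(kendall_one_tailed(1:2, 1:2), "length >= 3")
})

test_that("kendall boundary cases and the normal approximation behave", {
  # only one of 120 permutations attains perfect concordance
  k <- kendall_one_tailed(1:5, c(10, 20, 30, 40, 50))
  expect_equal(k$tau, 1)
  expect_equal(k$p, 1 / 120)
  expect_equal(kendall_one_tailed(1:5, 5:1)$p, 1)
  # antisymmetry of tau for tie-free inputs
  set.seed(8)
  x <- sample(100, 7); y <- sample(100, 7)
  expect_equal(kendall_one_tailed(x, y)$tau,
               -kendall_one_tailed(x, -y)$tau)
  # normal approximation within 0.02 of exact at n = 8 (tie-free)
  set.seed(12)
  worst <- 0
  for (i in 1:100) {
    x8 <- sample(1000, 8); y8 <- sample(1000, 8)
    pe <- kendall_one_tailed(x8, y8, method = "exact")$p
    pn <- kendall_one_tailed(x8, y8, method = "normal")$p
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.02)
})

test_that("reference ranking fixtures reproduce the published validation", {
  hg <- reference_ranking("high_gain")
  expect_equal(nrow(hg), 10)
  expect_equal(top_k_overlap(hg, 10), 8)
  kt <- kendall_one_tailed(hg$predicted, hg$observed)
  expect_gt(kt$tau, 0)
  fr <- reference_ranking("fast_response")
  expect_equal(sum(fr$observed_rank == 1), 5)
  # tie groups share the minimum rank as printed
  expect_equal(fr$predicted[1:3], rep(0.48, 3))
})
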