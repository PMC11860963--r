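test_that("softmax choice probability matches its analytic cases", {
  expect_equal(choice_prob(0.3, 0.3, 5), 0.5)     # equal values
  expect_equal(choice_prob(0.9, 0.1, 0), 0.5)     # flat at tau = 0
  expect_equal(choice_prob(1, 0, 1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(choice_prob(1, 0, 1), 0.7310586, tolerance = 1e-7)
  # complement
  expect_equal(choice_prob(0.2, 0.8, 3) + choice_prob(0.8, 0.2, 3), 1)
  # numerically safe at extreme value differences: finite, in [0, 1], and
  # strictly interior while the exponential is representable
  expect_true(is.finite(choice_prob(1, 0, 1e4)))
  expect_true(choice_prob(1, 0, 30) < 1)
  expect_true(choice_prob(0, 1, 30) > 0)
  # the log-likelihood path survives an effectively greedy policy
  rec <- tibble::tibble(chosen = c("a", "a"), reward = c(1L, 1L))
  expect_true(is.finite(sequence_nll(rec, params_shared(1, 1e4), model = "M1")))
  expect_error(choice_prob(1, 0, -1), "tau")
})

test_that("delta-rule update moves only the chosen arm", {
  up <- update_values(0.5, 0.5, "a", reward = 1, alpha = 0.2)
  expect_equal(up$v_a, 0.6)
  expect_equal(up$v_b, 0.5)
  # zero and full learning-rate steps
  expect_equal(update_values(0.4, 0.7, "b", 1, alpha = 0)$v_b, 0.7)
  expect_equal(update_values(0.4, 0.7, "b", 0, alpha = 1)$v_b, 0)
  expect_error(update_values(0.5, 0.5, "a", 1, alpha = 1.2), "alpha")
})

test_that("values stay in [0, 1] under arbitrary update sequences", {
  set.seed(99)
  for (rep in 1:20) {
    v_a <- runif(1); v_b <- runif(1)
    alpha <- runif(1)
    for (t in 1:50) {
      up <- update_values(v_a, v_b, sample(c("a", "b"), 1),
                          rbinom(1, 1, 0.5), alpha)
      v_a <- up$v_a; v_b <- up$v_b
      expect_true(v_a >= 0 && v_a <= 1 && v_b >= 0 && v_b <= 1)
    }
  }
})

test_that("sequence NLL equals brute-force recomputation on short instances", {
  # hand-worked 3-trial example, recomputed step by step here
  rec <- tibble::tibble(chosen = c("a", "a", "b"), reward = c(1L, 0L, 1L))
  p1 <- 0.5                                   # V = (0.5, 0.5)
  p2 <- 1 / (1 + exp(-2 * (0.75 - 0.5)))      # after a rewarded: Va = 0.75
  p3 <- 1 - 1 / (1 + exp(-2 * (0.375 - 0.5))) # after a unrewarded: Va = 0.375
  expected <- -(log(p1) + log(p2) + log(p3))
  expect_equal(sequence_nll(rec, params_shared(0.5, 2), model = "M1"),
               expected, tolerance = 1e-12)

  # random instances up to 10 trials against the independent reference
  for (seed in 1:25) {
    n <- sample(1:10, 1)
    rec <- random_records(n, seed)
    alpha <- runif(1); tau <- runif(1, 0, 8)
    expect_equal(sequence_nll(rec, params_shared(alpha, tau), model = "M1"),
                 ref_nll(rec$chosen, rec$reward, alpha, tau),
                 tolerance = 1e-10)
  }
})

test_that("null and flat models give n log 2; missing trials drop out", {
  rec <- random_records(17, seed = 3)
  expect_equal(sequence_nll(rec, model = "M0"), 17 * log(2))
  expect_equal(sequence_nll(rec, params_shared(0.4, 0), model = "M1"),
               17 * log(2))
  # missing responses contribute nothing and trigger no update
  rec_m <- random_records(40, seed = 4, p_missing = 0.3)
  n_obs <- sum(!is.na(rec_m$chosen))
  expect_equal(sequence_nll(rec_m, model = "M0"), n_obs * log(2))
  expect_equal(sequence_nll(rec_m, params_shared(0.3, 2), model = "M1"),
               ref_nll(rec_m$chosen, rec_m$reward, 0.3, 2),
               tolerance = 1e-10)
  expect_error(sequence_nll(rec_m[is.na(rec_m$chosen), ], model = "M0"),
               "non-missing")
})

test_that("M2 likelihood decouples across conditions", {
  set.seed(11)
  rec <- tibble::tibble(
    condition = rep(c("self", "other"), 10),
    chosen = sample(c("a", "b"), 20, replace = TRUE),
    reward = rbinom(20, 1, 0.6))
  p <- params_separate(0.7, 0.2, 4, 1)
  by_hand <- ref_nll(rec$chosen[rec$condition == "self"],
                     rec$reward[rec$condition == "self"], 0.7, 4) +
    ref_nll(rec$chosen[rec$condition == "other"],
            rec$reward[rec$condition == "other"], 0.2, 1)
  expect_equal(sequence_nll(rec, p, model = "M2"), by_hand, tolerance = 1e-10)
})

test_that("simulated agents behave sensibly in the limits", {
  sch <- fx_schedule()
  # alpha = 0: values never move, choices are coin flips
  a0 <- simulate_agent(sch, params_separate(0, 0, 5, 5), seed = 21)
  hrp <- attr(a0, "hrp")
  expect_true(all(abs(hrp - 0.5) < 0.15))  # 90 trials/condition of fair coin
  # determinism given the seed
  a1 <- simulate_agent(sch, params_separate(0.6, 0.3, 4, 2), seed = 77)
  a2 <- simulate_agent(sch, params_separate(0.6, 0.3, 4, 2), seed = 77)
  expect_identical(a1, a2)
  # greedy lock-in: huge tau, alpha = 1, no reversals
  sch_nr <- build_schedule(task_config(n_blocks = 1, trials_per_condition = 10,
                                       reversal_period = 10))
  g <- simulate_agent(sch_nr, params_separate(1, 1, 20, 20), seed = 5)
  gs <- g[g$condition == "self", ]
  first_rewarded <- which(gs$reward == 1)[1]
  expect_false(is.na(first_rewarded))
  expect_lt(first_rewarded, 10)
  # the very next choice repeats the just-rewarded arm (value pinned at 1)
  expect_identical(gs$chosen[first_rewarded + 1], gs$chosen[first_rewarded])
})

test_that("higher learning rates earn higher HRP under reversals", {
  sch <- build_schedule(task_config(n_blocks = 1))
  set.seed(31)
  hi <- replicate(300, mean(attr(
    simulate_agent(sch, params_separate(0.8, 0.8, 5, 5)), "hrp")))
  lo <- replicate(300, mean(attr(
    simulate_agent(sch, params_separate(0.1, 0.1, 5, 5)), "hrp")))
  expect_gt(mean(hi), mean(lo))
})

test_that("generating parameters beat grossly wrong ones in likelihood", {
  sch <- build_schedule(task_config(n_blocks = 1))
  set.seed(41)
  diffs <- replicate(40, {
    ag <- simulate_agent(sch, params_separate(0.7, 0.7, 4, 4))
    good <- sequence_nll(ag, params_separate(0.7, 0.7, 4, 4), model = "M2")
    bad <- sequence_nll(ag, params_separate(0.3, 0.3, 2, 2), model = "M2")
    bad - good
  })
  expect_gt(mean(diffs), 0)
})
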