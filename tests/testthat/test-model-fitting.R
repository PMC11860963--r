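test_that("BIC obeys its defining identity", {
  expect_equal(bic(30 * log(2), 0, 30), 60 * log(2))
  expect_equal(bic(30 * log(2), 0, 30), 41.589, tolerance = 1e-4)
  expect_equal(bic(20, 2, 30), 2 * log(30) + 40)
  expect_equal(bic(20, 2, 30), 46.803, tolerance = 1e-4)
  # penalty difference at equal fit
  expect_equal(bic(20, 4, 30) - bic(20, 2, 30), 2 * log(30))
  expect_error(bic(10, 2, 0), "n")
})

test_that("M0 fits have the closed form and fitted rows satisfy the identity", {
  rec <- random_records(30, seed = 8)
  f0 <- fit_subject_block(rec, model = "M0")
  expect_equal(f0$k, 0L)
  expect_equal(f0$nll, 30 * log(2))
  expect_equal(f0$bic, 2 * 30 * log(2))

  f1 <- fit_subject_block(rec, model = "M1")
  expect_equal(f1$bic, f1$k * log(f1$n_trials) + 2 * f1$nll)
  expect_equal(f1$k, 2L)
  expect_true(f1$nll >= 0)
})

test_that("refitting identical records is bit-identical", {
  set.seed(13)
  ag <- simulate_agent(fx_schedule(), params_separate(0.5, 0.3, 3, 3))
  sub <- ag[ag$block == 1, ]
  sub$condition <- as.character(sub$condition)
  f_a <- fit_subject_block(sub, model = "M2")
  f_b <- fit_subject_block(sub, model = "M2")
  expect_identical(f_a, f_b)
})

test_that("fitted NLL never exceeds the chance bound and models nest", {
  fits <- fx_fits_m2()
  expect_true(all(fits$nll <= fits$n_trials * log(2) + 1e-6))

  # nesting on a small subset with all three models
  trials <- fx_cohort()$trials
  sub <- trials[trials$subject_id %in% unique(trials$subject_id)[1:6] &
                  trials$block == 1, ]
  all_fits <- fit_cohort(sub, models = c("M0", "M1", "M2"))
  wide <- tidyr::pivot_wider(all_fits[, c("subject_id", "model", "nll")],
                             names_from = "model", values_from = "nll")
  expect_true(all(wide$M2 <= wide$M1 + 1e-6))
  expect_true(all(wide$M1 <= wide$M0 + 1e-6))
})

test_that("separate-parameter fits recover the ordering of condition alphas", {
  set.seed(17)
  sch <- build_schedule(task_config(n_blocks = 1))
  fits <- purrr::map_dfr(1:60, function(i) {
    ag <- simulate_agent(sch, params_separate(0.7, 0.2, 5, 5))
    fit_subject_block(ag, model = "M2")
  })
  expect_gt(mean(fits$alpha_self), mean(fits$alpha_other))
})

test_that("degenerate data are flagged, not fatal", {
  rec <- tibble::tibble(condition = "self", chosen = c("a", NA),
                        reward = c(1L, NA))
  f <- fit_subject_block(rec, model = "M2")
  expect_false(f$converged)
  expect_error(fit_subject_block(rec[2, ], model = "M2"), "non-missing")
})

test_that("model comparison sums BIC and reports exact deltas", {
  trials <- fx_cohort()$trials
  sub <- trials[trials$subject_id %in% unique(trials$subject_id)[1:5], ]
  fits <- fit_cohort(sub, models = c("M1", "M2"))
  cmp <- compare_models(fits)
  sums <- fits |>
    dplyr::group_by(block, model) |>
    dplyr::summarise(s = sum(bic), .groups = "drop")
  joined <- dplyr::inner_join(cmp, sums, by = c("block", "model"))
  expect_equal(joined$sum_bic, joined$s)
  per_block <- split(cmp, cmp$block)
  for (pb in per_block) {
    expect_equal(pb$delta_bic[pb$model == pb$winner[1]], 0)
    expect_equal(max(pb$delta_bic), abs(diff(pb$sum_bic)))
  }
  # single subject: delta equals the per-subject difference
  one <- fit_cohort(sub[sub$subject_id == sub$subject_id[1] & sub$block == 1, ],
                    models = c("M1", "M2"))
  cmp1 <- compare_models(one)
  expect_equal(max(cmp1$delta_bic), abs(diff(one$bic)))
  # missing fits are rejected with the offending subject named
  expect_error(compare_models(fits[-1, ]), "missing fits")
})

test_that("exclusion rules fire on missingness and boundary self-learning", {
  trials <- fx_cohort()$trials
  fits <- fx_fits_m2()
  ids <- unique(trials$subject_id)

  # subject with > half the responses of one block missing
  t_mod <- trials
  b2 <- which(t_mod$subject_id == ids[1] & t_mod$block == 2)
  kill <- b2[1:31]
  t_mod$chosen[kill] <- NA
  t_mod$reward[kill] <- NA_integer_
  t_mod$chose_high[kill] <- NA_integer_
  # subject with block-1 self learning rate at the zero boundary
  f_mod <- fits
  f_mod$alpha_self[f_mod$subject_id == ids[2] & f_mod$block == 1] <- 0

  exc <- apply_exclusions(t_mod, f_mod)
  expect_false(exc$included[exc$subject_id == ids[1]])
  expect_match(exc$reasons[exc$subject_id == ids[1]], "missing")
  expect_false(exc$included[exc$subject_id == ids[2]])
  expect_match(exc$reasons[exc$subject_id == ids[2]], "no self-learning")
  # an unremarkable subject stays in
  ok <- exc$subject_id[exc$included]
  expect_true(length(ok) >= 1)
  expect_equal(exc$reasons[exc$included][1], "")
})
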