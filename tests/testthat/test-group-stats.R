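make_summary_fixture <- function() {
  trials <- fx_cohort()$trials
  fits <- fx_fits_m2()
  summarize_subjects(trials, fits)
}

test_that("PLS arithmetic, labeling boundary and partition", {
  s <- make_summary_fixture()
  expect_equal(s$pls, s$alpha_other - s$alpha_self)
  b1 <- s[s$block == 1, ]
  expect_equal(b1$label, ifelse(b1$pls < 0, "Selfish", "Prosocial"))
  # every subject carries exactly one label, fixed by block 1
  per_subj <- tapply(s$label, s$subject_id, function(x) length(unique(x)))
  expect_true(all(per_subj == 1))
  expect_true(all(s$label %in% c("Selfish", "Prosocial")))

  # boundary: PLS exactly 0 is Prosocial
  fits0 <- fx_fits_m2()
  sid <- fits0$subject_id[1]
  fits0$alpha_other[fits0$subject_id == sid & fits0$block == 1] <-
    fits0$alpha_self[fits0$subject_id == sid & fits0$block == 1]
  s0 <- summarize_subjects(trials = fx_cohort()$trials, fits = fits0)
  expect_equal(unique(s0$label[s0$subject_id == sid]), "Prosocial")
})

test_that("z-scored reaction times are standardized within subject and block", {
  trials <- fx_cohort()$trials
  s <- make_summary_fixture()
  # reconstruct one subject-block by hand
  one <- trials[trials$subject_id == trials$subject_id[1] & trials$block == 1, ]
  z <- (one$rt_ms - mean(one$rt_ms, na.rm = TRUE)) / sd(one$rt_ms, na.rm = TRUE)
  by_hand <- tapply(z, one$condition, mean, na.rm = TRUE)
  row <- s[s$subject_id == one$subject_id[1] & s$block == 1, ]
  expect_equal(row$zrt_self, unname(by_hand["self"]), tolerance = 1e-12)
  expect_equal(row$zrt_other, unname(by_hand["other"]), tolerance = 1e-12)
  # self condition is faster on average (negative z difference)
  expect_lt(mean(s$zrt_self - s$zrt_other), 0)

  # constant RTs: z-scores collapse to 0 and the block is flagged
  t2 <- trials
  pick <- t2$subject_id == t2$subject_id[1] & t2$block == 1
  t2$rt_ms[pick] <- 700
  s2 <- summarize_subjects(t2, fx_fits_m2())
  r2 <- s2[s2$subject_id == t2$subject_id[1] & s2$block == 1, ]
  expect_equal(r2$zrt_self, 0)
  expect_true(r2$zrt_degenerate)
})

test_that("mixed ANOVA agrees with a direct aov decomposition on a balanced design", {
  # 2x2 between x 2x2 within, 3 subjects per cell; Type III = Type I here
  set.seed(61)
  des <- tidyr::expand_grid(A = c("a1", "a2"), B = c("b1", "b2"), s = 1:3) |>
    dplyr::mutate(subject_id = sprintf("%s%s%d", A, B, s))
  long <- tidyr::expand_grid(des, C = c("c1", "c2"), D = c("d1", "d2")) |>
    dplyr::mutate(y = rnorm(dplyr::n()) +
                    (A == "a1") * 0.5 + (C == "c1") * (D == "d1") * 0.8)
  fit <- mixed_anova(long, "y", between = c("A", "B"), within = c("C", "D"))

  ref <- summary(aov(y ~ A * B * C * D + Error(subject_id / (C * D)),
                     data = long))
  ref_rows <- do.call(rbind, lapply(ref, function(stratum) {
    tab <- stratum[[1]]
    data.frame(effect = trimws(rownames(tab)), F = tab$`F value`,
               p = tab$`Pr(>F)`)
  }))
  ref_rows <- ref_rows[!is.na(ref_rows$F), ]
  for (i in seq_len(nrow(ref_rows))) {
    got <- fit[fit$effect == ref_rows$effect[i], ]
    expect_equal(got$statistic, ref_rows$F[i], tolerance = 1e-8)
    expect_equal(got$p.value, ref_rows$p[i], tolerance = 1e-8)
  }
  # partial eta squared consistent with F and dfs: F = pes/(1-pes) * df2/df1
  expect_equal(fit$statistic,
               fit$pes / (1 - fit$pes) * fit$df2 / fit$df1,
               tolerance = 1e-8)
})

test_that("mixed ANOVA rejects malformed designs and handles symmetry", {
  set.seed(62)
  long <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:8),
                             C = c("c1", "c2")) |>
    dplyr::mutate(G = rep(c("g1", "g2"), each = 8),
                  y = rnorm(16))
  # duplicated groups: between effect F near 0
  dup <- dplyr::bind_rows(
    dplyr::mutate(long, G = "g1"),
    dplyr::mutate(long, G = "g2", subject_id = paste0(subject_id, "x")))
  fit <- mixed_anova(dup, "y", between = "G", within = "C")
  expect_lt(fit$statistic[fit$effect == "G"], 1e-20)

  # unbalanced within-cells rejected with the offender named
  broken <- long[-1, ]
  expect_error(mixed_anova(broken, "y", between = "G", within = "C"), "s1")
  # too-small between cell rejected
  tiny <- long[long$subject_id %in% c("s1", "s2", "s5"), ]
  expect_error(mixed_anova(tiny, "y", between = "G", within = "C"),
               "at least 2")
})

test_that("Benjamini-Hochberg worked example and post-hoc contracts", {
  # step-up rule on the worked p-set
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.60), method = "BH"),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.60))

  set.seed(63)
  fam <- list(
    up = list(x = rnorm(20, 1), y = rnorm(20)),
    null1 = list(x = rnorm(20), y = rnorm(20)),
    null2 = list(x = rnorm(20), y = rnorm(20)),
    null3 = list(x = rnorm(20), y = rnorm(20)))
  ph <- posthoc_paired(fam)
  expect_equal(ph$p.adjusted, p.adjust(ph$p.value, "BH"))
  expect_true(all(ph$p.adjusted >= ph$p.value))
  expect_true(all(ph$p.adjusted <= 1))
  # cross-check one contrast against t.test directly
  tt <- t.test(fam$up$x, fam$up$y, paired = TRUE)
  expect_equal(ph$statistic[1], unname(tt$statistic))
  expect_equal(ph$p.value[1], tt$p.value)
  # single contrast: adjusted = raw
  one <- posthoc_paired(fam["up"])
  expect_equal(one$p.adjusted, one$p.value)
  # degenerate pairs
  expect_error(posthoc_paired(list(a = list(x = 1, y = 2))), "pairs")
  flat <- posthoc_paired(list(a = list(x = c(1, 2, 3), y = c(0, 1, 2)),
                              b = list(x = rnorm(5), y = rnorm(5))))
  expect_equal(flat$note[1], "zero variance")
  expect_true(is.na(flat$statistic[1]))
})

test_that("manipulation-check battery has the standard behavior", {
  s <- make_summary_fixture()
  res <- basic_tests(s, block = 1)
  expect_true(all(c("test", "measure", "statistic", "p.value") %in% names(res)))
  # learners: HRP above chance, alpha and tau above zero, for both conditions
  above <- res[res$test %in% c("one-sample vs 0.5", "one-sample vs 0"), ]
  expect_true(all(above$statistic > 0))
  # cross-check the self-HRP row against t.test
  b1 <- s[s$block == 1, ]
  tt <- t.test(b1$hrp_self, mu = 0.5)
  row <- res[res$test == "one-sample vs 0.5" & res$measure == "hrp_self", ]
  expect_equal(row$statistic, unname(tt$statistic))
  expect_equal(row$p.value, tt$p.value)
  # degenerate sample flagged, not tested
  s_flat <- s
  s_flat$hrp_self <- 0.5
  res_flat <- basic_tests(s_flat, block = 1)
  row_flat <- res_flat[res_flat$test == "one-sample vs 0.5" &
                         res_flat$measure == "hrp_self", ]
  expect_equal(row_flat$note, "zero variance")
  # PLS correlates with the HRP condition difference in the expected direction
  cor_row <- res[res$test == "correlation with PLS" &
                   res$measure == "hrp_other - hrp_self", ]
  expect_gt(cor_row$estimate, 0)
})

test_that("bootstrap difference is deterministic and calibrated at the extremes", {
  a <- rnorm(30, sd = 0.2)
  # identical samples: p near 1, CI covers 0
  b1 <- bootstrap_diff(a, a, n_boot = 500, seed = 4)
  expect_gt(b1$p.value, 0.5)
  expect_true(b1$ci[1] <= 0 && b1$ci[2] >= 0)
  # huge separation: p near 0
  b2 <- bootstrap_diff(a + 100, a, n_boot = 500, seed = 4)
  expect_lt(b2$p.value, 0.01)
  # determinism
  b3 <- bootstrap_diff(a + 100, a, n_boot = 500, seed = 4)
  expect_identical(b2, b3)
  expect_warning(bootstrap_diff(a, a, n_boot = 50, seed = 1), "n_boot")
  expect_error(bootstrap_diff(numeric(0), a), "non-empty")
})
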