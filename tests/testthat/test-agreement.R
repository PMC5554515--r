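cmp_row <- function(test, ref, metric = "t_mean_over_b", subject = "S01",
                    study = "S01_T1", method = "TEST")
  paired_comparison(subject, study, metric, test, ref, method)

cmp_set <- function(ratios, subjects = paste0("S", seq_along(ratios)),
                    metric = "t_mean_over_b") {
  do.call(rbind, lapply(seq_along(ratios), function(i)
    cmp_row(ratios[i], 1, metric, subjects[i], paste0(subjects[i], "_T1"))))
}

test_that("paired comparisons keep log and percentage scales consistent", {
  cmp <- cmp_row(2.3, 2.0)
  expect_equal(cmp$abs_diff, 0.3)
  expect_equal(cmp$rel_diff_pct, 15)
  expect_equal(cmp$rel_diff_pct, 100 * (exp(cmp$log_ratio) - 1),
               tolerance = 1e-12)
  expect_error(cmp_row(-1, 2), "positive")
  expect_error(cmp_row(2, 0), "positive")
})

test_that("Bland-Altman statistics match hand computation", {
  # all test = ref
  ba0 <- bland_altman(cmp_set(c(1, 1, 1)))
  expect_equal(ba0$d_bar, 0)
  expect_equal(ba0$mean_pct, 0)
  expect_equal(ba0$loa_pct, c(0, 0))

  # hand-computed three-study example
  ba <- bland_altman(cmp_set(c(1.05, 0.95, 1.00)))
  d_hand <- c(0.0487901642, -0.0512932944, 0)
  expect_equal(ba$d_bar, mean(d_hand), tolerance = 1e-6)
  expect_equal(ba$d_bar, -0.000834377, tolerance = 1e-6)
  expect_equal(ba$mean_pct, 100 * (exp(mean(d_hand)) - 1), tolerance = 1e-6)
  expect_equal(ba$sd_d, sd(d_hand), tolerance = 1e-6)
  expect_equal(ba$loa_pct,
               100 * (exp(mean(d_hand) + c(-1, 1) * 1.96 * sd(d_hand)) - 1),
               tolerance = 1e-6)
  expect_equal(ba$ci_mean_pct,
               100 * (exp(mean(d_hand) + c(-1, 1) * 1.96 * sd(d_hand) / sqrt(3)) - 1),
               tolerance = 1e-6)

  # swapping test and reference negates the log-scale statistics
  swapped <- do.call(rbind, lapply(c(1.05, 0.95, 1.00), function(r)
    cmp_row(1, r, subject = paste0("S", r), study = paste0("S", r, "_T1"))))
  ba_sw <- bland_altman(swapped)
  expect_equal(ba_sw$d_bar, -ba$d_bar, tolerance = 1e-12)
  expect_equal(log(1 + ba_sw$loa_pct / 100),
               -rev(log(1 + ba$loa_pct / 100)), tolerance = 1e-12)

  expect_error(bland_altman(cmp_set(c(1, 1))), "at least 3")
  mixed <- rbind(cmp_set(c(1, 1, 1)), cmp_set(1.1, "S9", metric = "btv_ml"))
  expect_error(bland_altman(mixed), "mix")
})

test_that("percentage results invert exactly back to the log scale", {
  set.seed(60)
  ba <- bland_altman(cmp_set(exp(rnorm(12, 0.01, 0.05))))
  d_back <- log(1 + ba$mean_pct / 100)
  sd_back <- (log(1 + ba$loa_pct[2] / 100) - log(1 + ba$loa_pct[1] / 100)) /
    (2 * 1.96)
  expect_equal(d_back, ba$d_bar, tolerance = 1e-10)
  expect_equal(sd_back, ba$sd_d, tolerance = 1e-10)
})

test_that("the literal CI-of-LoA variant applies its stated formula", {
  comps <- cmp_set(exp(c(-0.02, 0.01, 0.04, -0.03, 0.02)))
  ba <- bland_altman(comps, ci_loa_variant = "literal")
  half <- 3 * ba$sd_d / sqrt(2 * ba$n)
  expect_equal(ba$ci_loa_pct$lower, 100 * (exp(ba$d_bar - half) - 1))
  expect_equal(ba$ci_loa_pct$upper, 100 * (exp(ba$d_bar + half) - 1))
  # standard variant brackets each limit symmetrically on the log scale
  ba2 <- bland_altman(comps)
  lo_log <- log(1 + ba2$ci_loa_pct$lower / 100)
  expect_equal(mean(lo_log), log(1 + ba2$loa_pct[1] / 100), tolerance = 1e-12)
})

test_that("repeated-measures SD reduces to the sample SD and matches ANOVA", {
  set.seed(61)
  d <- rnorm(10)
  expect_equal(sd_with_repeated_measures(d, paste0("S", 1:10)), sd(d))

  # hand-worked two-subject example: MS_W = 0, MS_B = 1, m0 = 2
  expect_equal(sd_with_repeated_measures(c(0, 0, 1, 1), c("a", "a", "b", "b")),
               sqrt(0.5))

  # duplicating every study leaves the between-subject component unchanged
  d2 <- c(0, 0, 1, 1); s2 <- c("a", "a", "b", "b")
  expect_equal(sd_with_repeated_measures(c(d2, d2), c(s2, s2)),
               sd_with_repeated_measures(d2, s2))

  # cross-check mean squares against stats::aov on unbalanced data
  dd <- rnorm(9)
  ss <- c("a", "a", "a", "b", "b", "c", "c", "c", "c")
  fit <- summary(aov(dd ~ ss))[[1]]
  ms_b <- fit["ss", "Mean Sq"]; ms_w <- fit["Residuals", "Mean Sq"]
  m_i <- table(ss); N <- 9; k <- 3
  m0 <- (N - sum(m_i^2) / N) / (k - 1)
  want <- sqrt(max(0, (ms_b - ms_w) / m0) + ms_w)
  expect_equal(sd_with_repeated_measures(dd, ss), want, tolerance = 1e-12)

  expect_error(sd_with_repeated_measures(c(1, 2), c("a", "a")), "single subject")
})

test_that("bland_altman engages the repeated-measures correction", {
  comps <- rbind(cmp_set(exp(c(0, 0)), subjects = c("a", "a")),
                 cmp_set(exp(c(1, 1)), subjects = c("b", "b")))
  ba <- bland_altman(comps)
  expect_equal(ba$sd_d, sqrt(0.5))
  expect_equal(ba$n, 4)
  expect_equal(ba$n_subjects, 2)
})

test_that("acceptance criteria apply the absolute-or-relative rule", {
  thr <- acceptance_thresholds()
  mk <- function(metric, test, ref)
    cmp_row(test, ref, metric)
  pass_tm <- mk("t_mean_over_b", 2.0, 2.0)
  pass_btv <- mk("btv_ml", 10, 10)

  # printed failing example: T_MAX/B 2.53 -> 2.39
  fail_tmax <- mk("t_max_over_b", 2.39, 2.53)
  expect_gte(abs(fail_tmax$abs_diff), 0.1)
  expect_gte(abs(fail_tmax$rel_diff_pct), 5)
  v <- acceptance_check(pass_tm, fail_tmax, pass_btv, thr)
  expect_false(v$t_max_over_b); expect_false(v$overall)

  # printed failing example: BTV 40.0 -> 47.9 mL
  fail_btv <- mk("btv_ml", 47.9, 40.0)
  v2 <- acceptance_check(pass_tm, mk("t_max_over_b", 3, 3), fail_btv, thr)
  expect_false(v2$btv_ml); expect_false(v2$overall)

  # OR rule: |0.09| < 0.1 passes although 3% relative bound is irrelevant
  or_case <- mk("t_max_over_b", 3.09, 3.00)
  v3 <- acceptance_check(pass_tm, or_case, pass_btv, thr)
  expect_true(v3$t_max_over_b); expect_true(v3$overall)

  # identical values pass everything
  v4 <- acceptance_check(pass_tm, mk("t_max_over_b", 2.2, 2.2), pass_btv, thr)
  expect_true(v4$overall)

  expect_error(acceptance_check(fail_tmax, fail_tmax, pass_btv, thr),
               "expected a t_mean_over_b")
})

test_that("clinical categories split at 2.0 and 2.4 with closed boundaries", {
  expect_equal(as.character(classify_category(c(1.9, 2.2, 2.6))),
               c("reactive", "equivocal", "active"))
  expect_equal(as.character(classify_category(c(2.0, 2.4))),
               c("equivocal", "equivocal"))
  expect_error(classify_category(0), "positive")
})

test_that("category shift tables tally off-diagonal moves", {
  same <- classify_category(c(1.5, 2.2, 3.0))
  expect_equal(category_shift_table(same, same)$n_shifted, 0)

  ref <- classify_category(c(1.9, 2.2))
  test <- classify_category(c(2.1, 2.5))
  st <- category_shift_table(ref, test)
  expect_equal(st$n_shifted, 2)
  expect_equal(st$table["reactive", "equivocal"], 1L,
               ignore_attr = TRUE)

  set.seed(62)
  rr <- sample(c("reactive", "equivocal", "active"), 40, replace = TRUE)
  tt <- sample(c("reactive", "equivocal", "active"), 40, replace = TRUE)
  st2 <- category_shift_table(rr, tt)
  expect_equal(st2$n_shifted, sum(rr != tt))
  for (a in c("reactive", "equivocal", "active"))
    for (b in c("reactive", "equivocal", "active"))
      expect_equal(st2$table[a, b], sum(rr == a & tt == b),
                   ignore_attr = TRUE)
})

test_that("agreement_table summarizes per method and metric", {
  set.seed(63)
  comps <- do.call(rbind, lapply(c("A", "B"), function(m)
    do.call(rbind, lapply(1:6, function(i)
      paired_comparison(paste0("S", i), paste0("S", i, "_T1"),
                        "t_max_over_b", exp(rnorm(1, 0, 0.05)) * 2.5, 2.5,
                        method = m)))))
  tab <- agreement_table(comps)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$method, c("A", "B"))
  ba_a <- bland_altman(comps[comps$method == "A", ])
  expect_equal(tab$mean_pct[tab$method == "A"], ba_a$mean_pct)
})
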