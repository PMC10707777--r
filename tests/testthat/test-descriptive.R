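test_that("clinical derivations follow their defining formulas", {
  expect_equal(compute_bmi(100, 1.60), 39.0625)
  expect_equal(compute_bmi(84.22, 1.60), 32.9, tolerance = 1e-3)
  expect_equal(compute_bmi(2 * 70, 1.7), 2 * compute_bmi(70, 1.7))
  expect_error(compute_bmi(-1, 1.6), "positive")

  expect_equal(compute_homa(22.5, 1.0), 1.0)
  expect_equal(compute_homa(10, 5.6), 10 * 5.6 / 22.5)
  expect_true(is.na(compute_homa(10, 5.6, insulin_treated = 1)))

  expect_equal(friedewald_ldl(5, 1, 2.2), 3.0)
  expect_equal(friedewald_ldl(5, 1, 0), 4.0)
  # validity bound: 400 mg/dL of TG is 400/88.57 = 4.516 mmol/L
  expect_warning(ldl_hi <- friedewald_ldl(5, 1, 5.0), "bound")
  expect_true(is.na(ldl_hi))
})

test_that("BMI tertiles cut at empirical terciles or fixed points", {
  res <- bmi_tertiles(1:9)
  expect_equal(unname(res$cuts), c(3, 6))
  expect_equal(as.vector(table(res$tertile)), c(3L, 3L, 3L))
  # brute-force quantile oracle (inverse ECDF: order statistics 3 and 6)
  expect_equal(res$cuts, unname(quantile(1:9, c(1 / 3, 2 / 3), type = 1)))

  fixed <- bmi_tertiles(c(35, 43, 50), cuts = c(40.2, 46.2))
  expect_equal(fixed$tertile, c(1L, 2L, 3L))
  # right-closed intervals: a value at the cut stays in the lower category
  expect_equal(bmi_tertiles(c(40.2, 46.2), cuts = c(40.2, 46.2))$tertile,
               c(1L, 2L))
  # monotone in BMI
  t1 <- bmi_tertiles(c(39, 41, 47), cuts = c(40.2, 46.2))$tertile
  t2 <- bmi_tertiles(c(41, 47, 60), cuts = c(40.2, 46.2))$tertile
  expect_true(all(t2 >= t1))
  expect_warning(bmi_tertiles(rep(5, 10)), "identical")
})

test_that("chi-squared test matches the hand-evaluated formula", {
  tab <- matrix(c(10, 30, 20, 40), nrow = 2)
  res <- chi_square_test(tab)
  # X2 = sum (O-E)^2/E computed by hand
  E <- outer(rowSums(tab), colSums(tab)) / 100
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_equal(res$statistic, 0.79365, tolerance = 1e-4)
  expect_equal(res$df, 1)

  prop <- matrix(c(10, 20, 20, 40), nrow = 2)
  res2 <- chi_square_test(prop)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Monte-Carlo exact test agrees with complete enumeration", {
  tab <- matrix(c(2, 0, 0, 2), nrow = 2)
  res <- fisher_exact_mc(tab, reps = 20000, seed = 3)
  # enumeration: margins (2,2)/(2,2); cell x ~ hypergeometric {0,1,2} with
  # probs (1,4,1)/6; X2 >= observed for x in {0,2} -> p = 2/6
  expect_equal(res$p_value, 1 / 3, tolerance = 0.02)
  expect_equal(res$method, "fisher_mc")
  # determinism under seed
  expect_equal(res$p_value, fisher_exact_mc(tab, reps = 20000, seed = 3)$p_value)
})

test_that("the expected-count rule switches between chi-squared and MC Fisher", {
  flag_big <- rep(c(0, 1), each = 100)
  grp_big <- rep(c("a", "b"), times = 100)
  r1 <- chronoprof:::group_contact_test(flag_big, grp_big, mc_reps = 500)
  expect_equal(r1$method, "chi2")
  flag_small <- c(rep(1, 4), rep(0, 36))
  grp_small <- rep(c("a", "b"), times = 20)
  r2 <- chronoprof:::group_contact_test(flag_small, grp_small, mc_reps = 500)
  expect_equal(r2$method, "fisher_mc")
})

test_that("rank tests match brute-force ranks and each other", {
  # groups {1,2,3} vs {4,5,6}: H computed from first principles
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  H <- chronoprof::kruskal_wallis_test(x, g)$statistic
  R <- rank(x)
  H_hand <- 12 / (6 * 7) * sum(tapply(R, g, function(r) length(r) *
                                        (mean(r) - 3.5)^2))
  expect_equal(H, H_hand, tolerance = 1e-10)

  # identical distributions: zero statistic
  expect_equal(kruskal_wallis_test(rep(c(1, 2), 4), rep(c("a", "b"), each = 4))$statistic,
               0, tolerance = 1e-12)

  # two-group Kruskal-Wallis agrees with the rank-sum test
  withr::with_seed(51, {
    a <- rnorm(30)
    b <- rnorm(30, 0.8)
    p_kw <- kruskal_wallis_test(c(a, b), rep(c("a", "b"), each = 30))$p_value
    p_w <- wilcoxon_rank_sum(a, b)$p_value
    expect_equal(p_kw, p_w, tolerance = 0.02)
  })
})

test_that("summary tables honour grouping, tests and degenerate columns", {
  g <- generate_cohort(120, seed = 52, missingness = FALSE)
  cohort <- prepare_model_data(g$cohort)
  # single group: overall column only, no tests
  s0 <- summary_table(cohort, variables = c("age", "gender"))
  expect_false("p_value" %in% names(s0))

  cohort$all_missing <- NA_real_
  s1 <- summary_table(cohort, group_by = "bmi_tertile",
                      variables = c("age", "gender", "all_missing"),
                      mc_reps = 500)
  expect_true("p_value" %in% names(s1))
  expect_true(is.na(s1$overall[s1$variable == "all_missing"]))
  expect_true(all(c("group_1", "group_2", "group_3") %in% names(s1)))

  # grouped by true profile at moderate n, contact rates echo the generator
  big <- generate_cohort(4000, seed = 53, missingness = FALSE)
  big$cohort$true_profile <- big$truth$true_profile
  s2 <- summary_table(big$cohort, group_by = "true_profile",
                      variables = "evening_snack", mc_reps = 500)
  row1 <- s2[s2$level == "1", ]
  # profile 2 always snacks in the evening; profile 1 never does
  expect_match(row1$group_2, "100%")
  expect_match(row1$group_1, "\\(0%\\)")
})
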