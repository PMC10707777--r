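test_that("profile sampling follows the mixture weights", {
  withr::with_seed(1, {
    expect_true(all(sample_profiles(200, c(1, 0, 0, 0)) == 1L))
    expect_error(sample_profiles(10, c(0.5, 0.4)), "sum to 1")

    lab <- sample_profiles(1e5)
    p3 <- 55 / 173
    se <- sqrt(p3 * (1 - p3) / 1e5)
    expect_lt(abs(mean(lab == 3) - p3), 3 * se)
  })

  # chi-square goodness of fit is calibrated: non-significant at alpha = 0.01
  # in at least 18 of 20 seeded replicates
  w <- generator_defaults()$mixture_weights
  ok <- sum(vapply(1:20, function(s) {
    lab <- withr::with_seed(s, sample_profiles(2000))
    obs <- tabulate(lab, 4)
    suppressWarnings(chisq.test(obs, p = w)$p.value) > 0.01
  }, logical(1)))
  expect_gte(ok, 18)
})

test_that("degenerate contact probabilities are deterministic, moderate ones converge", {
  withr::with_seed(2, {
    lab <- rep(1:4, each = 500)
    flags <- sample_contacts(lab)
    # profile 2: every snack certain; profile 1: no nibbling at all
    expect_true(all(flags$morning_snack[lab == 2] == 1))
    expect_true(all(flags$evening_snack[lab == 2] == 1))
    nib <- c("morning_nibbling", "afternoon_nibbling", "evening_nibbling",
             "night_nibbling")
    expect_true(all(as.matrix(flags[lab == 1, nib]) == 0))
    expect_true(all(flags$dinner == 1))
  })
  withr::with_seed(3, {
    lab3 <- rep(3L, 2e4)
    f3 <- sample_contacts(lab3)
    p <- 22 / 55
    se <- sqrt(p * (1 - p) / 2e4)
    expect_lt(abs(mean(f3$afternoon_nibbling) - p), 3 * se)
  })
})

test_that("covariate marginals hit the calibration targets", {
  cov <- withr::with_seed(4, sample_covariates(5e4))
  expect_lt(abs(median(cov$age) - 46), 1)
  expect_gte(min(cov$age), 17)
  expect_lte(max(cov$age), 71)
  expect_lt(abs(median(cov$BMI) - 43), 0.5)
  expect_gte(min(cov$BMI), 32.9)
  expect_lte(max(cov$BMI), 80.3)
  se <- sqrt(0.68 * 0.32 / 5e4)
  expect_lt(abs(mean(cov$gender == "F") - 0.68), 3 * se)
  expect_equal(cov$BMI, cov$weight / cov$height^2, tolerance = 1e-12)
})

test_that("outcome models are centred as declared", {
  # zero-coefficient logistic model: prevalence one half
  params <- generator_defaults()$outcome_params
  params$logistic$hypertension <- c(`(Intercept)` = 0)
  withr::with_seed(5, {
    cov <- sample_covariates(2e4)
    lab <- sample_profiles(2e4)
    out <- sample_outcomes(cov, lab, params)$outcomes
    expect_lt(abs(mean(out$hypertension) - 0.5), 3 * sqrt(0.25 / 2e4))
  })
  # median-zero noise contract
  noise <- withr::with_seed(6, chronoprof:::median_zero_noise(1e6, scale = 3))
  expect_lt(abs(median(noise)), 0.01 * 3)
  expect_gt(mean(noise), 0) # right-skewed: mean above the median
})

test_that("logistic generator is recoverable by refitting", {
  # male hypertension odds ratio 2.21 recovered within 15% at large n
  withr::with_seed(7, {
    cov <- sample_covariates(2e4)
    lab <- sample_profiles(2e4)
    out <- sample_outcomes(cov, lab)$outcomes
    d <- dplyr::mutate(cov, hypertension = out$hypertension)
    fit <- logistic_reg(hypertension ~ age + I(gender == "M") + alcohol, d)
    or_male <- exp(coef(fit)[["I(gender == \"M\")TRUE"]])
    expect_lt(abs(or_male - 2.21) / 2.21, 0.15)
  })
})

test_that("missingness is injected at the target rates and is MAR", {
  g0 <- generate_cohort(200, seed = 8, missingness = FALSE)
  expect_false(anyNA(g0$cohort$HDL))
  withr::with_seed(9, {
    g <- generate_cohort(5e4, seed = 9, missingness = FALSE)
    masked <- inject_missingness(g$cohort)
    r <- mean(is.na(masked$HDL))
    se <- sqrt(0.15 * 0.85 / 5e4)
    expect_lt(abs(r - 0.15), 3 * se)
    # MAR: given age and gender, the mask is independent of the hidden value
    mfit <- glm(is.na(masked$HDL) ~ g$cohort$HDL + g$cohort$age +
                  I(g$cohort$gender == "M"), family = binomial())
    z <- summary(mfit)$coefficients["g$cohort$HDL", "z value"]
    expect_lt(abs(z), 4)
  })
  expect_error(inject_missingness(g0$cohort, c(nope = 0.5)), "absent")
})

test_that("generate_cohort is deterministic and schema-complete", {
  g1 <- generate_cohort(173, seed = 10)
  g2 <- generate_cohort(173, seed = 10)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$cohort), 173)
  expect_true(all(slot_names() %in% names(g1$cohort)))
  expect_true(all(c("age", "BMI", "hypertension", "diabetes", "HOMA",
                    "SCL90_GSI", "BES") %in% names(g1$cohort)))
  expect_true(all(g1$truth$true_profile %in% 1:4))

  # overall breakfast prevalence: mixture arithmetic gives 154/173
  pd <- generator_defaults()
  target <- sum(pd$mixture_weights * pd$contact_prob["breakfast", ])
  expect_equal(target, 154 / 173, tolerance = 1e-12)
  big <- generate_cohort(5e4, seed = 11, missingness = FALSE)
  se <- sqrt(target * (1 - target) / 5e4)
  expect_lt(abs(mean(big$cohort$breakfast) - target), 3 * se)
})
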