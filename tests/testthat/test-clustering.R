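test_that("metric embedding preserves L2 distances between curves", {
  bs <- fourier_basis()
  withr::with_seed(21, {
    G <- matrix(rnorm(10 * 5, sd = 0.5), ncol = 5,
                dimnames = list(paste0("p", 1:10),
                                c("alpha", "a1", "b1", "a2", "b2")))
    Z <- embed_curves(G, bs)
    for (i in 1:4) {
      j <- i + 5
      fi <- function(t) {
        vals <- sapply(1:5, function(k) basis_fun(k)(t))
        as.vector(vals %*% G[i, ])
      }
      fj <- function(t) {
        vals <- sapply(1:5, function(k) basis_fun(k)(t))
        as.vector(vals %*% G[j, ])
      }
      l2 <- simpson(function(t) (fi(t) - fj(t))^2, 0, 24)
      expect_equal(sum((Z[i, ] - Z[j, ])^2), l2, tolerance = 1e-8)
    }
  })
  # identical curves embed identically; constant-only curves: sqrt(24)|dalpha|
  G2 <- rbind(c(0.3, 0, 0, 0, 0), c(0.3, 0, 0, 0, 0), c(0.8, 0, 0, 0, 0))
  colnames(G2) <- c("alpha", "a1", "b1", "a2", "b2")
  Z2 <- embed_curves(G2, bs)
  expect_equal(Z2[1, ], Z2[2, ])
  expect_equal(sqrt(sum((Z2[1, ] - Z2[3, ])^2)), sqrt(24) * 0.5,
               tolerance = 1e-12)
})

test_that("single-component fit is the closed-form global Gaussian", {
  withr::with_seed(22, {
    Z <- matrix(rnorm(200), ncol = 5)
    f <- fit_profile_mixture(Z, K = 1, em_settings(n_init = 1), seed = 1)
    expect_equal(f$pi, 1)
    expect_equal(as.vector(f$mu), colMeans(Z), tolerance = 1e-9)
    expect_true(all(f$assignments == 1))
  })
})

test_that("well-separated clusters are recovered exactly and EM is monotone", {
  withr::with_seed(23, {
    Z <- rbind(matrix(rnorm(40 * 5, mean = 0, sd = 0.1), ncol = 5),
               matrix(rnorm(40 * 5, mean = 10, sd = 0.1), ncol = 5))
    truth <- rep(1:2, each = 40)
    f <- fit_profile_mixture(Z, K = 2, em_settings(n_init = 5), seed = 2)
    expect_equal(adjusted_rand_index(f$assignments, truth), 1)
  })
  # log-likelihood never decreases along any seeded run
  for (s in 1:50) {
    Z <- withr::with_seed(s, matrix(rnorm(60 * 5), ncol = 5))
    f <- fit_profile_mixture(Z, K = 3, em_settings(n_init = 1), seed = s)
    expect_true(all(diff(f$trace) >= -1e-8), info = paste("seed", s))
  }
})

test_that("BIC selects the constructed K and guards against overfitting", {
  withr::with_seed(24, {
    Z <- rbind(matrix(rnorm(50 * 5, 0, 0.3), ncol = 5),
               matrix(rnorm(50 * 5, 6, 0.3), ncol = 5),
               matrix(rnorm(50 * 5, -6, 0.3), ncol = 5))
    sel <- select_k_by_bic(Z, 2:5, em_settings(n_init = 5), seed = 3)
    expect_equal(sel$model$K, 3L)
    expect_equal(nrow(sel$bic_table), 4L)
  })
  # single blob: selected K at or near the range minimum in most seeds
  ks <- vapply(1:10, function(s) {
    Z <- withr::with_seed(100 + s, matrix(rnorm(80 * 5), ncol = 5))
    select_k_by_bic(Z, 2:4, em_settings(n_init = 3), seed = s)$model$K
  }, integer(1))
  expect_gte(mean(ks <= 3), 0.8)
})

test_that("assignments are equivariant under row permutation", {
  g <- generate_cohort(80, seed = 25, missingness = FALSE)
  curves <- smooth_cohort(g$cohort, lambda = 1)
  Z <- embed_curves(curves)
  f1 <- fit_profile_mixture(Z, 3, em_settings(n_init = 4), seed = 9)
  perm <- withr::with_seed(1, sample(nrow(Z)))
  f2 <- fit_profile_mixture(Z[perm, ], 3, em_settings(n_init = 4), seed = 9)
  expect_equal(f2$assignments, f1$assignments[perm])
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
  a <- rep(1:2, each = 50)
  b <- withr::with_seed(26, sample(a))
  expect_lt(abs(adjusted_rand_index(a, b)), 0.15)
})

test_that("profile contact table reduces to the overall column for one cluster", {
  g <- generate_cohort(60, seed = 27, missingness = FALSE)
  tab <- profile_contact_table(g$cohort, rep(1L, 60))
  expect_equal(tab$cluster1_n, tab$overall_n)
  expect_equal(tab$cluster1_pct, tab$overall_pct)
  # with true labels at large n, cell percentages approach generator rates
  big <- generate_cohort(8000, seed = 28, missingness = FALSE)
  tb <- profile_contact_table(big$cohort, big$truth$true_profile, mc_reps = 500)
  pd <- generator_defaults()
  # cluster columns are in decreasing size order: 1, 3, 4, 2
  expect_equal(tb$cluster1_pct[tb$slot == "morning_snack"],
               100 * pd$contact_prob["morning_snack", 1], tolerance = 3)
  expect_equal(tb$cluster3_pct[tb$slot == "afternoon_nibbling"],
               100 * pd$contact_prob["afternoon_nibbling", 3], tolerance = 3)
  expect_true(all(tb$p_value[tb$slot == "evening_snack"] < 0.001))
})
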