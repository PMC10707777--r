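test_that("median regression reference points are exact", {
  withr::with_seed(41, {
    d <- data.frame(y = rnorm(31), x = rnorm(31))
    f <- median_reg(y ~ 1, d)
    expect_equal(unname(coef(f)), median(d$y))
    expect_equal(pseudo_r1(f), 0)

    # exactly affine response: zero loss, exact coefficients, R1 = 1
    d2 <- data.frame(x = 1:20)
    d2$y <- 3 - 2 * d2$x
    f2 <- median_reg(y ~ x, d2)
    expect_equal(unname(coef(f2)), c(3, -2), tolerance = 1e-10)
    expect_lt(f2$V, 1e-10)
    expect_equal(pseudo_r1(f2), 1)
  })
})

test_that("median regression objective matches the enumeration oracle", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(12:20, 1)
      p <- sample(2:3, 1)
      X <- cbind(1, matrix(rnorm(n * (p - 1)), ncol = p - 1))
      beta <- rnorm(p)
      y <- as.vector(X %*% beta) + rexp(n) - log(2) # skewed noise
      d <- as.data.frame(X[, -1, drop = FALSE])
      names(d) <- paste0("x", seq_len(p - 1))
      d$y <- y
      f <- median_reg(y ~ ., d)
      expect_equal(f$V, median_reg_oracle(X, y), tolerance = 1e-8)
    }
  })
})

test_that("median regression rejects rank-deficient designs and names columns", {
  d <- data.frame(y = rnorm(20), a = 1:20)
  d$b <- 2 * d$a
  expect_error(median_reg(y ~ a + b, d), "collinear.*b")
})

test_that("nested median fits have non-decreasing pseudo-R1", {
  withr::with_seed(43, {
    d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
    d$y <- 1 + d$x1 + 0.5 * d$x2 + rexp(100)
    r0 <- pseudo_r1(median_reg(y ~ 1, d))
    r1 <- pseudo_r1(median_reg(y ~ x1, d))
    r2 <- pseudo_r1(median_reg(y ~ x1 + x2, d))
    expect_lte(r0, r1 + 1e-12)
    expect_lte(r1, r2 + 1e-12)
  })
})

test_that("logistic regression reproduces the 2x2 cross-product odds ratio", {
  tab <- data.frame(
    y = rep(c(1, 0, 1, 0), times = c(10, 20, 30, 40)),
    x = rep(c(1, 1, 0, 0), times = c(10, 20, 30, 40))
  )
  f <- logistic_reg(y ~ x, tab)
  expect_equal(tidy(f)$odds.ratio[2], (10 * 40) / (20 * 30), tolerance = 1e-6)

  balanced <- data.frame(y = rep(c(1, 0, 1, 0), each = 25),
                         x = rep(c(1, 1, 0, 0), each = 25))
  fb <- logistic_reg(y ~ x, balanced)
  expect_equal(tidy(fb)$odds.ratio[2], 1, tolerance = 1e-8)
  expect_error(logistic_reg(y ~ x, data.frame(y = c(0, 1, 2, 1), x = 1:4)),
               "binary")
})

test_that("AIC definitions match independent evaluations", {
  withr::with_seed(44, {
    d <- data.frame(x = rnorm(120))
    d$y <- rbinom(120, 1, plogis(0.5 + d$x))
    f <- logistic_reg(y ~ x, d)
    # independent likelihood evaluation
    pr <- plogis(as.vector(cbind(1, d$x) %*% coef(f)))
    ll <- sum(d$y * log(pr) + (1 - d$y) * log(1 - pr))
    expect_equal(model_aic(f), -2 * ll + 2 * 2, tolerance = 1e-8)
    expect_equal(model_aic(f), model_aic(logistic_reg(y ~ x, d)))

    # median AIC: asymmetric-Laplace working likelihood
    dm <- data.frame(x = rnorm(60))
    dm$y <- 1 + dm$x + rexp(60)
    fm <- median_reg(y ~ x, dm)
    expect_equal(model_aic(fm), 2 * 2 + 2 * 60 * log(fm$V / 60))
  })
})

test_that("a pure-noise predictor usually raises the AIC", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(400 + s, {
      d <- data.frame(x = rnorm(300), z = rnorm(300))
      d$y <- rbinom(300, 1, plogis(d$x))
      model_aic(logistic_reg(y ~ x + z, d)) >
        model_aic(logistic_reg(y ~ x, d))
    })
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("backward selection keeps signal, drops noise, and traces AIC", {
  withr::with_seed(45, {
    d <- data.frame(a = rnorm(250), g = factor(sample(letters[1:3], 250, TRUE)),
                    z = rnorm(250))
    d$y <- 2 + 3 * d$a + rexp(250) - log(2)
    sel <- backward_select(y ~ a + g + z, d, family = "median")
    expect_true("a" %in% attr(terms(sel$formula), "term.labels"))
    expect_true(all(diff(sel$trace$aic) < 0))
  })
  # outcome independent of all predictors: intercept-only in most replicates
  null_hits <- vapply(1:20, function(s) {
    withr::with_seed(500 + s, {
      d <- data.frame(x1 = rnorm(150), x2 = factor(sample(c("u", "v"), 150, TRUE)))
      d$y <- rbinom(150, 1, 0.4)
      sel <- backward_select(y ~ x1 + x2, d, family = "logistic")
      length(attr(terms(sel$formula), "term.labels")) == 0
    })
  }, logical(1))
  expect_gte(mean(null_hits), 0.6)
})

test_that("factor blocks enter and leave selection atomically", {
  withr::with_seed(46, {
    d <- data.frame(g = factor(sample(letters[1:4], 300, TRUE)),
                    x = rnorm(300))
    shift <- c(a = 0, b = 4, c = -3, d = 2)
    d$y <- shift[as.character(d$g)] + rexp(300) - log(2)
    sel <- backward_select(y ~ g + x, d, family = "median")
    tl <- attr(terms(sel$formula), "term.labels")
    expect_true("g" %in% tl)   # whole factor retained
    cf <- names(coef(sel$fit))
    expect_true(all(c("gb", "gc", "gd") %in% cf))
  })
})

test_that("fits are invariant to row order and equivariant to rescaling", {
  withr::with_seed(47, {
    d <- data.frame(x = rnorm(80))
    d$y <- 1 + 2 * d$x + rexp(80)
    f1 <- median_reg(y ~ x, d)
    f2 <- median_reg(y ~ x, d[sample(80), ])
    expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
    d$x10 <- d$x / 10
    f3 <- median_reg(y ~ x10, d)
    expect_equal(coef(f3)[["x10"]], 10 * coef(f1)[["x"]], tolerance = 1e-6)
  })
})
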