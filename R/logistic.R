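#' Binary logistic regression with odds-ratio reporting
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`), Wald 95% confidence intervals, odds ratios by
#' exponentiation. Quasi-separation (any |coefficient| > 15) is recorded as
#' a warning on the returned object.
#'
#' @param formula Model formula; the response must be 0/1.
#' @param data Data frame.
#' @return Object of class `logistic_fit` wrapping the `glm` fit.
#' @export
logistic_reg <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")
  fit <- suppressWarnings(
    glm(formula, data = data, family = binomial(),
        control = list(maxit = 100))
  )
  if (!fit$converged) abort("logistic fit did not converge in 100 iterations")
  warn_sep <- NULL
  if (max(abs(coef(fit))) > 15) {
    warn_sep <- "possible quasi-separation: |coefficient| > 15"
    warn(warn_sep)
  }
  structure(list(glm = fit, formula = formula, n = length(fit$y),
                 warning = warn_sep),
            class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) coef(object$glm)

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression, n =", x$n, " AIC =",
      format(model_aic(x), digits = 6), "\n")
  print(tidy.logistic_fit(x))
  invisible(x)
}

#' @export
#' @rdname logistic_reg
#' @param x,object A fitted `logistic_fit`.
#' @param ... Unused.
tidy.logistic_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  est <- s[, "Estimate"]
  se <- s[, "Std. Error"]
  tibble::tibble(
    term = rownames(s),
    estimate = unname(est),
    std.error = unname(se),
    p.value = unname(s[, "Pr(>|z|)"]),
    conf.low = unname(est - 1.96 * se),
    conf.high = unname(est + 1.96 * se),
    odds.ratio = exp(unname(est)),
    or.low = exp(unname(est - 1.96 * se)),
    or.high = exp(unname(est + 1.96 * se))
  )
}

#' @export
#' @rdname logistic_reg
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = as.numeric(logLik(x$glm)),
                 aic = model_aic(x), deviance = x$glm$deviance)
}

#' AIC of a fitted association model
#'
#' Logistic fits use the ordinary AIC = 2p - 2 logLik. Median fits use the
#' asymmetric-Laplace working likelihood, giving
#' AIC = 2p + 2n log( (1/n) sum rho_tau(residuals) ).
#'
#' @param fit A `median_fit` or `logistic_fit`.
#' @return Numeric AIC.
#' @export
model_aic <- function(fit) {
  if (inherits(fit, "logistic_fit")) {
    return(2 * length(coef(fit$glm)) - 2 * as.numeric(logLik(fit$glm)))
  }
  if (inherits(fit, "median_fit")) {
    return(2 * fit$p + 2 * fit$n * log(fit$V / fit$n))
  }
  abort("model_aic() expects a median_fit or logistic_fit")
}

#' Backward AIC selection over whole factor blocks
#'
#' Starting from the full model, repeatedly removes the predictor (a factor
#' enters and leaves as a whole treatment-coded block) whose removal most
#' reduces the AIC, until no removal reduces it. Ties are broken by dropping
#' the block earliest in the declared predictor order.
#'
#' @param formula Full model formula.
#' @param data Data frame.
#' @param family `"median"` (quantile 0.5) or `"logistic"`.
#' @param ci Confidence-interval method for the final median fit
#'   (`"none"` or `"boot"`, see [median_reg()]).
#' @param B,seed Bootstrap settings for the final median fit.
#' @return List with `fit` (the selected model), `trace` (tibble of steps:
#'   `step`, `dropped`, `aic`) and `formula` (the selected formula).
#' @export
backward_select <- function(formula, data, family = c("median", "logistic"),
                            ci = "none", B = 999L, seed = 1L) {
  family <- match.arg(family)
  fit_fun <- function(f) {
    if (family == "median") median_reg(f, data) else logistic_reg(f, data)
  }
  # complete cases over the full model so all candidate fits share the data
  data <- data[stats::complete.cases(data[, all.vars(formula), drop = FALSE]), ,
               drop = FALSE]
  response <- all.vars(formula)[1]
  terms_now <- attr(terms(formula, data = data), "term.labels")
  current <- formula
  fit <- fit_fun(current)
  aic_now <- model_aic(fit)
  trace <- tibble::tibble(step = 0L, dropped = "<full>", aic = aic_now)
  step <- 0L
  while (length(terms_now) > 0) {
    cand_aic <- vapply(terms_now, function(tm) {
      remaining <- setdiff(terms_now, tm)
      f <- if (length(remaining)) {
        reformulate(remaining, response = response)
      } else as.formula(paste(response, "~ 1"))
      model_aic(fit_fun(f))
    }, numeric(1))
    if (min(cand_aic) >= aic_now - 1e-10) break
    drop_i <- which(cand_aic <= min(cand_aic) + 1e-10)[1] # earliest declared
    dropped <- terms_now[drop_i]
    terms_now <- setdiff(terms_now, dropped)
    current <- if (length(terms_now)) {
      reformulate(terms_now, response = response)
    } else as.formula(paste(response, "~ 1"))
    fit <- fit_fun(current)
    aic_now <- model_aic(fit)
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(step = step,
                                                    dropped = dropped,
                                                    aic = aic_now))
  }
  if (family == "median" && ci == "boot") {
    fit <- median_reg(current, data, ci = "boot", B = B, seed = seed)
  }
  list(fit = fit, trace = trace, formula = current)
}
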