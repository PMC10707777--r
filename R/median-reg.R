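#' Pinball (check) loss
#'
#' rho_tau(u) = u * (tau - 1\{u < 0\}); its minimizer over a location is the
#' tau-quantile, the median for tau = 0.5.
#'
#' @param u Residuals.
#' @param tau Quantile level in (0, 1).
#' @return Numeric vector of losses.
#' @export
pinball_loss <- function(u, tau = 0.5) u * (tau - (u < 0))

# MM (majorize-minimize) iterations for the pinball objective, followed by a
# vertex polish: an optimal basic solution interpolates p observations, so we
# search exact-fit solutions through subsets of the lowest-|residual| points.
quantile_fit_engine <- function(X, y, tau = 0.5, polish = TRUE,
                                max_iter = 500L, tol = 1e-12, eps = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  obj <- function(b) sum(pinball_loss(y - X %*% b, tau))
  # start from least squares
  b <- qr.coef(qr(X), y)
  b[is.na(b)] <- 0
  last <- obj(b)
  for (it in seq_len(max_iter)) {
    r <- as.vector(y - X %*% b)
    w <- 1 / (2 * (abs(r) + eps))
    XtW <- t(X * w)
    rhs <- XtW %*% y + (tau - 0.5) * colSums(X)
    bn <- tryCatch(solve(XtW %*% X, rhs), error = function(e) NULL)
    if (is.null(bn)) break
    newv <- obj(bn)
    if (newv <= last) {
      b <- as.vector(bn)
      if (last - newv < tol * (1 + abs(last))) { last <- newv; break }
      last <- newv
    } else break
  }
  if (polish && n > p) {
    r <- abs(as.vector(y - X %*% b))
    m <- if (p <= 8L) min(n, p + 6L) else min(n, p + 4L)
    cand <- order(r)[seq_len(m)]
    subs <- utils::combn(cand, p)
    for (j in seq_len(ncol(subs))) {
      idx <- subs[, j]
      bs <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                     error = function(e) NULL)
      if (is.null(bs)) next
      v <- obj(bs)
      if (v < last - 1e-14) { b <- as.vector(bs); last <- v }
    }
  }
  list(coefficients = as.vector(b), objective = last)
}

#' Median (quantile) regression
#'
#' Fits coefficients minimizing the summed pinball loss
#' sum_i rho_tau(y_i - x_i' beta) at tau = 0.5 (the median). The
#' non-smooth objective is minimized by majorize-minimize iterations
#' followed by an exact vertex search (an optimal solution interpolates p
#' observations). 95% confidence intervals come from a pairs (case
#' resampling) percentile bootstrap.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param tau Quantile level, fixed at 0.5 for the median analysis.
#' @param ci `"boot"` for pairs-bootstrap percentile intervals, `"none"`.
#' @param B Bootstrap replicates (999 by default).
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `median_fit` with coefficients, fitted values,
#'   residuals, the attained objective `V`, `aic`, and (if requested)
#'   bootstrap confidence limits.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 10), x = c(0, 1, 2, 3))
#' coef(median_reg(y ~ 1, d))  # the sample median
#' @export
median_reg <- function(formula, data, tau = 0.5, ci = c("none", "boot"),
                       B = 999L, seed = 1L) {
  ci <- match.arg(ci)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort("need more observations than coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(drop_cols, collapse = ", ")))
  }
  if (p == 1L && all(X[, 1] == 1)) {
    # intercept-only: the minimizer set is the median interval; report the
    # conventional sample median (its midpoint for even n)
    b <- median(y)
    fitres <- list(coefficients = b, objective = sum(pinball_loss(y - b, tau)))
  } else {
    fitres <- quantile_fit_engine(X, y, tau)
  }
  coefs <- setNames(fitres$coefficients, colnames(X))
  fitted <- as.vector(X %*% coefs)
  out <- structure(list(
    coefficients = coefs, fitted = fitted, residuals = y - fitted,
    V = fitres$objective, n = n, p = p, tau = tau,
    formula = formula, terms = attr(mf, "terms"), X = X, y = y,
    conf = NULL
  ), class = "median_fit")
  out$aic <- model_aic(out)
  if (ci == "boot") {
    bs <- withr::with_seed(as.integer(seed), {
      replicate(B, {
        idx <- sample.int(n, n, replace = TRUE)
        quantile_fit_engine(X[idx, , drop = FALSE], y[idx], tau,
                            polish = FALSE)$coefficients
      })
    })
    qs <- apply(bs, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    out$conf <- tibble::tibble(term = names(coefs),
                               conf.low = qs[1, ], conf.high = qs[2, ])
  }
  out
}

#' @export
coef.median_fit <- function(object, ...) object$coefficients

#' @export
print.median_fit <- function(x, ...) {
  cat("Median regression (tau =", x$tau, "), n =", x$n, "\n")
  print(round(x$coefficients, 4))
  cat("pinball objective:", format(x$V, digits = 6),
      " AIC:", format(x$aic, digits = 6), "\n")
  invisible(x)
}

#' Goodness of fit of a median regression
#'
#' R1 = 1 - V_full / V_null, where V is the summed pinball loss and V_null
#' comes from the intercept-only fit of the same response: the quantile
#' analogue of R-squared, in `[0, 1]`.
#'
#' @param fit A `median_fit`.
#' @return Numeric scalar.
#' @export
pseudo_r1 <- function(fit) {
  stopifnot(inherits(fit, "median_fit"))
  v0 <- sum(pinball_loss(fit$y - median(fit$y), fit$tau))
  if (v0 <= 0) return(if (fit$V <= 0) 1 else 0)
  max(0, min(1, 1 - fit$V / v0))
}

#' @export
#' @rdname median_reg
#' @param object,x A fitted `median_fit`.
#' @param ... Unused.
tidy.median_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients))
  if (!is.null(x$conf)) out <- dplyr::left_join(out, x$conf, by = "term")
  out
}

#' @export
#' @rdname median_reg
glance.median_fit <- function(x, ...) {
  tibble::tibble(n = x$n, tau = x$tau, objective = x$V, aic = x$aic,
                 pseudo_r1 = pseudo_r1(x))
}
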