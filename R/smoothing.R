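#' Order-2 Fourier basis on the 24-hour grid
#'
#' The hourly step function of each patient is approximated by
#' f(t) = alpha + sum_{n=1,2} a_n cos(2 pi n t / 24) + b_n sin(2 pi n t / 24),
#' i.e. a Fourier basis of order 2 with period 24 h and p = 5 coefficients
#' ordered (alpha, a1, b1, a2, b2).
#'
#' The Gram matrix `W` (L2 inner products of the basis functions) and the
#' curvature penalty matrix `R` (inner products of second derivatives) are
#' computed in closed form over the full period `[0, 24]`, where the basis
#' is orthogonal: `W = diag(24, 12, 12, 12, 12)` and
#' `R = diag(0, c1, c1, c2, c2)` with `c_n = (2 pi n / 24)^4 * 12`.
#'
#' @param order Harmonic order (2 in the reference analysis).
#' @param period Period in hours (24).
#' @return List of class `fourier_basis` with elements `order`, `period`,
#'   `grid`, `B` (24 x p basis matrix), `W` (Gram matrix) and `R` (penalty).
#' @export
fourier_basis <- function(order = 2L, period = 24L) {
  stopifnot(order >= 1, period >= 2)
  grid <- seq_len(period)
  p <- 2L * order + 1L
  B <- matrix(1, nrow = period, ncol = p)
  cn <- numeric(p) # fourth-power curvature weights
  nm <- "const"
  for (n in seq_len(order)) {
    w <- 2 * pi * n / period
    B[, 2 * n] <- cos(w * grid)
    B[, 2 * n + 1] <- sin(w * grid)
    cn[c(2 * n, 2 * n + 1)] <- w^4 * period / 2
    nm <- c(nm, paste0("cos", n), paste0("sin", n))
  }
  colnames(B) <- nm
  W <- diag(c(period, rep(period / 2, p - 1L)))
  R <- diag(cn)
  dimnames(W) <- dimnames(R) <- list(nm, nm)
  structure(list(order = order, period = period, grid = grid,
                 B = B, W = W, R = R),
            class = "fourier_basis")
}

#' Curvature penalty matrix of a Fourier basis
#'
#' `R(j,k)` = integral of D2 phi_j(t) * D2 phi_k(t) dt over one full period.
#' The constant basis function has zero curvature, so its row and column
#' are identically zero.
#'
#' @param basis A [fourier_basis()] object.
#' @return The p x p positive-semidefinite penalty matrix.
#' @export
roughness_penalty <- function(basis) basis$R

#' Penalized least-squares fit of one hourly series
#'
#' Minimizes sum_t (f(t) - y(t))^2 + lambda * integral (D2 f)^2 dt over the
#' basis coefficients; the solution is (B'B + lambda R)^{-1} B'y, computed
#' via a Cholesky solve. The fitted curve is a probability-like smooth of a
#' binary series and is deliberately NOT clipped to the unit interval.
#'
#' @param y Numeric vector of length `period` (the binary hourly series).
#' @param basis A [fourier_basis()] object.
#' @param lambda Roughness penalty weight, >= 0.
#' @return List of class `smoothed_curve` with `coefficients`, `fitted`,
#'   `residuals`, `sse`, `edf` and `lambda`.
#' @export
fit_penalized <- function(y, basis = fourier_basis(), lambda = 0) {
  stopifnot(length(y) == basis$period, lambda >= 0)
  B <- basis$B
  M <- crossprod(B) + lambda * basis$R
  U <- chol(M)
  coefs <- backsolve(U, forwardsolve(t(U), crossprod(B, y)))
  coefs <- as.vector(coefs)
  names(coefs) <- colnames(B)
  fitted <- as.vector(B %*% coefs)
  res <- y - fitted
  # smoother trace: tr(B M^-1 B') = tr(M^-1 B'B)
  edf <- sum(diag(backsolve(U, forwardsolve(t(U), crossprod(B)))))
  structure(list(coefficients = coefs, fitted = fitted, residuals = res,
                 sse = sum(res^2), edf = edf, lambda = lambda),
            class = "smoothed_curve")
}

# effective degrees of freedom of the common smoother at lambda
smoother_edf <- function(basis, lambda) {
  M <- crossprod(basis$B) + lambda * basis$R
  sum(diag(solve(M, crossprod(basis$B))))
}

#' Pooled GCV selection of the smoothing parameter
#'
#' One roughness penalty lambda is shared by all subjects; it is chosen by
#' minimizing the pooled generalized cross-validation score
#' GCV(lambda) = (sum_i SSE_i / (T N)) / (1 - edf(lambda)/T)^2
#' over a grid, where T = 24 and edf is the trace of the common smoother
#' matrix. Ties go to the smaller lambda.
#'
#' @param series_df Long series tibble from [contacts_to_series()], or a
#'   cohort tibble with flag columns (expanded automatically).
#' @param basis A [fourier_basis()] object.
#' @param lambda_grid Non-empty grid of candidate lambdas (>= 0).
#' @return List with `lambda` (selected value) and `diagnostics`, a tibble
#'   with one row per candidate (`lambda`, `edf`, `sse`, `gcv`).
#' @export
gcv_select_lambda <- function(series_df, basis = fourier_basis(),
                              lambda_grid = default_lambda_grid()) {
  if (!length(lambda_grid)) abort("lambda_grid must be non-empty")
  if (any(lambda_grid < 0)) abort("lambda_grid values must be >= 0")
  Y <- as_series_matrix(series_df, basis)
  N <- nrow(Y)
  Tt <- basis$period
  diag_tbl <- purrr::map_dfr(lambda_grid, function(lam) {
    M <- crossprod(basis$B) + lam * basis$R
    H <- solve(M, t(basis$B))   # p x T mapping y -> coefficients
    coefs <- H %*% t(Y)         # p x N
    fitted <- basis$B %*% coefs # T x N
    res <- t(Y) - fitted
    sse <- sum(res^2)
    edf <- sum(diag(basis$B %*% H))
    gcv <- (sse / (Tt * N)) / (1 - edf / Tt)^2
    tibble::tibble(lambda = lam, edf = edf, sse = sse, gcv = gcv)
  })
  best <- which(diag_tbl$gcv <= min(diag_tbl$gcv) + 1e-15)
  sel <- diag_tbl$lambda[best[which.min(diag_tbl$lambda[best])]]
  list(lambda = sel, diagnostics = diag_tbl)
}

# accept either the long tibble or a cohort with flag columns; N x 24 matrix
as_series_matrix <- function(x, basis = fourier_basis()) {
  if (is.matrix(x)) return(x)
  if (all(c("patient_id", "hour", "y") %in% names(x))) {
    wide <- tidyr::pivot_wider(x, id_cols = "patient_id",
                               names_from = "hour", values_from = "y")
    Y <- as.matrix(wide[, -1])
    rownames(Y) <- wide$patient_id
    return(Y[, order(as.integer(colnames(Y))), drop = FALSE])
  }
  if (all(slot_names() %in% names(x))) return(series_matrix(x))
  abort("cannot interpret input as hourly series (need hour/y or flag columns)")
}

#' Smooth every patient in a cohort
#'
#' Fits the penalized Fourier smooth to each patient's hourly step function
#' at a common lambda and returns the coefficient table.
#'
#' @inheritParams gcv_select_lambda
#' @param lambda Shared roughness penalty (e.g. selected by
#'   [gcv_select_lambda()]).
#' @return A tibble with one row per patient: `patient_id`, the five
#'   coefficients `alpha, a1, b1, a2, b2`, `sse` and `edf`, with the basis
#'   and lambda attached as attributes `basis` and `lambda`.
#' @export
smooth_cohort <- function(series_df, basis = fourier_basis(), lambda = 0) {
  Y <- as_series_matrix(series_df, basis)
  M <- crossprod(basis$B) + lambda * basis$R
  coefs <- t(solve(M, t(basis$B) %*% t(Y))) # N x p
  fitted <- coefs %*% t(basis$B)
  sse <- rowSums((Y - fitted)^2)
  edf <- smoother_edf(basis, lambda)
  out <- tibble::tibble(
    patient_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
    alpha = coefs[, 1], a1 = coefs[, 2], b1 = coefs[, 3],
    a2 = coefs[, 4], b2 = coefs[, 5], sse = sse, edf = edf
  )
  attr(out, "basis") <- basis
  attr(out, "lambda") <- lambda
  out
}
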