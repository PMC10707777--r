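#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot smoothed chrono-nutritional curves
#'
#' Draws each patient's fitted 24-hour eating-probability curve; an optional
#' grouping vector colours the curves (e.g. by recovered profile). Fitted
#' values may leave `[0, 1]`; they are shown unclipped.
#'
#' @param curves Coefficient tibble from [smooth_cohort()].
#' @param group Optional group label per patient.
#' @param basis The [fourier_basis()] (defaults to the attached one).
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, group = NULL, basis = NULL) {
  basis <- basis %||% attr(curves, "basis") %||% fourier_basis()
  G <- as_coef_matrix(curves)
  fitted <- G %*% t(basis$B)
  df <- tibble::tibble(
    patient_id = rep(rownames(fitted), each = basis$period),
    hour = rep(basis$grid, times = nrow(fitted)),
    f = as.vector(t(fitted)),
    group = if (is.null(group)) "all" else rep(as.character(group),
                                               each = basis$period)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$f,
                                        group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.3, ggplot2::aes(colour = .data$group)) +
    ggplot2::labs(x = "hour of day", y = "smoothed eating probability") +
    ggplot2::theme_minimal()
  if (is.null(group)) p <- p + ggplot2::guides(colour = "none")
  p
}

#' @export
autoplot.chrono_mixture <- function(object, basis = fourier_basis(), ...) {
  # cluster mean curves: back-transform the embedded means to coefficients
  Winv <- diag(1 / sqrt(diag(basis$W)))
  mu_coef <- object$mu %*% Winv
  fitted <- mu_coef %*% t(basis$B)
  sizes <- table(factor(object$assignments, levels = seq_len(object$K)))
  df <- tibble::tibble(
    cluster = factor(rep(seq_len(object$K), each = basis$period)),
    hour = rep(basis$grid, times = object$K),
    f = as.vector(t(fitted)),
    size = rep(as.numeric(sizes), each = basis$period)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$f,
                                   colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "hour of day", y = "mean eating probability",
                  colour = "profile") +
    ggplot2::theme_minimal()
}

#' Plot the GCV profile of the smoothing-parameter search
#'
#' @param diagnostics The `diagnostics` tibble from [gcv_select_lambda()].
#' @return A ggplot object.
#' @export
plot_gcv <- function(diagnostics) {
  ggplot2::ggplot(diagnostics, ggplot2::aes(x = .data$lambda, y = .data$gcv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "pooled GCV") +
    ggplot2::theme_minimal()
}

#' Convergence trace of the chained imputation
#'
#' Mean of the imputed cells per cycle and variable -- the usual graphical
#' check that the chains have stabilized.
#'
#' @param trace Trace tibble from [impute_chained()].
#' @return A ggplot object.
#' @export
plot_imputation_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$cycle, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ variable, scales = "free_y") +
    ggplot2::labs(x = "cycle", y = "mean of imputed cells") +
    ggplot2::theme_minimal()
}
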