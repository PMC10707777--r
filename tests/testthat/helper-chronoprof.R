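# build a contact tibble from a character vector of flagged slots
make_contacts <- function(..., id = NULL) {
  sets <- list(...)
  rows <- purrr::map_dfr(seq_along(sets), function(i) {
    flags <- as.list(setNames(as.numeric(slot_names() %in% sets[[i]]),
                              slot_names()))
    tibble::as_tibble(flags)
  })
  dplyr::bind_cols(
    tibble::tibble(patient_id = id %||% paste0("p", seq_along(sets))),
    rows
  )
}

# composite Simpson quadrature of f over [a, b]
simpson <- function(f, a, b, n = 2000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (b - a) / (3 * n)
}

# order-2 Fourier basis functions and their second derivatives, by column
basis_fun <- function(j, period = 24) {
  force(j)
  function(t) {
    if (j == 1) return(rep(1, length(t)))
    n <- (j %/% 2)
    w <- 2 * pi * n / period
    if (j %% 2 == 0) cos(w * t) else sin(w * t)
  }
}
basis_d2 <- function(j, period = 24) {
  force(j)
  function(t) {
    if (j == 1) return(rep(0, length(t)))
    n <- (j %/% 2)
    w <- 2 * pi * n / period
    if (j %% 2 == 0) -w^2 * cos(w * t) else -w^2 * sin(w * t)
  }
}

# complete-enumeration oracle for median regression: an optimal basic
# solution interpolates p points, so minimize the pinball objective over all
# interpolating subsets (independent of the package's MM + polish solver)
median_reg_oracle <- function(X, y, tau = 0.5) {
  n <- nrow(X); p <- ncol(X)
  best <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    b <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                  error = function(e) NULL)
    if (is.null(b)) next
    v <- sum(pinball_loss(y - X %*% b, tau))
    if (v < best) best <- v
  }
  best
}
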