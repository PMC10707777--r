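#' EM settings for the subspace-mixture clustering
#'
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations.
#' @param n_init Number of seeded k-means initializations; the best final
#'   log-likelihood is kept.
#' @param scree_threshold Cattell scree threshold for the intrinsic
#'   dimension: `d_k` is the largest index whose eigenvalue drop is at least
#'   this fraction of the largest drop.
#' @param variance_floor Lower floor for the residual noise variance `b_k`.
#' @param collapse_rel Optional collapse threshold relative to the average
#'   total variance of the embeddings (0 disables it): a component whose
#'   residual noise variance falls below
#'   `max(variance_floor, collapse_rel * tr(cov(Z))/p)` is collapsing onto
#'   duplicated observations (binary diaries make identical curves common)
#'   and the EM halts at the last valid iterate.
#' @param model Covariance sub-model: `"free_noise"` (default) is the
#'   general member with per-cluster residual noise `b_k`; when a component
#'   starts collapsing onto duplicated observations (noise variance at the
#'   floor) the EM halts at the last valid iterate rather than chasing the
#'   unbounded likelihood. `"common_noise"` shares one `b` across clusters,
#'   which keeps the likelihood bounded by construction.
#' @return Named list of settings.
#' @export
em_settings <- function(tol = 1e-6, max_iter = 200L, n_init = 25L,
                        scree_threshold = 0.2, variance_floor = 1e-6,
                        collapse_rel = 0,
                        model = c("free_noise", "common_noise")) {
  model <- match.arg(model)
  list(tol = tol, max_iter = as.integer(max_iter), n_init = as.integer(n_init),
       scree_threshold = scree_threshold, variance_floor = variance_floor,
       collapse_rel = collapse_rel, model = model)
}

#' Metric embedding of smoothed curves
#'
#' Maps each patient's basis coefficients gamma to z = W^{1/2} gamma, where
#' W is the Gram matrix of the basis. Euclidean distance between embeddings
#' then equals the L2 distance between the underlying curves, which is the
#' standard preprocessing for model-based clustering of functional data.
#'
#' @param curves Coefficient tibble from [smooth_cohort()] (or a matrix of
#'   coefficients with 5 columns).
#' @param basis The [fourier_basis()]; defaults to the basis attached to
#'   `curves`.
#' @return N x p matrix of embeddings, rownames = patient ids.
#' @export
embed_curves <- function(curves, basis = NULL) {
  basis <- basis %||% attr(curves, "basis") %||% fourier_basis()
  G <- as_coef_matrix(curves)
  Z <- G %*% diag(sqrt(diag(basis$W)))
  colnames(Z) <- colnames(basis$B)
  Z
}

as_coef_matrix <- function(curves) {
  if (is.matrix(curves)) return(curves)
  cols <- c("alpha", "a1", "b1", "a2", "b2")
  stopifnot(all(cols %in% names(curves)))
  G <- as.matrix(curves[, cols])
  rownames(G) <- curves$patient_id %||% as.character(seq_len(nrow(G)))
  G
}

# Cattell scree: largest index whose eigenvalue drop is >= threshold * max drop
cattell_d <- function(ev, threshold, d_max) {
  diffs <- -diff(ev)
  if (all(diffs <= 0) || max(diffs) <= 0) return(1L)
  d <- max(which(diffs >= threshold * max(diffs)))
  min(max(d, 1L), d_max)
}

# log densities (N x K) of the parsimonious Gaussian subspace model
subspace_logdens <- function(Z, model) {
  p <- ncol(Z)
  K <- model$K
  out <- matrix(0, nrow(Z), K)
  for (k in seq_len(K)) {
    U <- sweep(Z, 2, model$mu[k, ])
    d <- model$d[k]
    Q <- model$Q[[k]][, seq_len(d), drop = FALSE]
    a <- model$a[[k]]
    b <- model$b[k]
    proj <- U %*% Q               # N x d signal-space scores
    tot2 <- rowSums(U^2)
    sig2 <- rowSums(proj^2)
    maha <- proj^2 %*% (1 / a) + (tot2 - sig2) / b
    logdet <- sum(log(a)) + (p - d) * log(b)
    out[, k] <- -0.5 * (p * log(2 * pi) + logdet + as.vector(maha)) +
      log(model$pi[k])
  }
  out
}

# one M-step from responsibilities; returns parameter list, or a degenerate
# marker (empty cluster, or collapsed noise in the free-noise model)
subspace_mstep <- function(Z, resp, settings, d_fixed = NULL) {
  N <- nrow(Z); p <- ncol(Z); K <- ncol(resp)
  nk <- colSums(resp)
  if (any(nk < 1)) return(structure(list(), degenerate = TRUE))
  mu <- matrix(0, K, p)
  Q <- vector("list", K); a <- vector("list", K)
  d <- integer(K); b <- numeric(K)
  evs <- vector("list", K)
  for (k in seq_len(K)) {
    w <- resp[, k]
    mu[k, ] <- colSums(Z * w) / nk[k]
    U <- sweep(Z, 2, mu[k, ])
    S <- crossprod(U * sqrt(w)) / nk[k]
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    evs[[k]] <- ev
    d[k] <- if (is.null(d_fixed)) {
      cattell_d(ev, settings$scree_threshold, p - 1L)
    } else d_fixed[k]
    Q[[k]] <- e$vectors
  }
  if (settings$model == "common_noise") {
    # pooled residual variance: sum of discarded eigenvalue mass over clusters
    num <- sum(vapply(seq_len(K), function(k) {
      nk[k] * sum(evs[[k]][(d[k] + 1):p])
    }, numeric(1)))
    den <- sum(nk * (p - d))
    b_common <- max(num / den, settings$variance_floor)
    b <- rep(b_common, K)
  } else {
    for (k in seq_len(K)) {
      raw_b <- sum(evs[[k]][(d[k] + 1):p]) / (p - d[k])
      # a component collapsing onto duplicated observations drives its noise
      # variance to zero and the likelihood to infinity: degenerate, not a fit
      if (raw_b <= (settings$collapse_floor %||% settings$variance_floor)) {
        return(structure(list(), degenerate = TRUE))
      }
      b[k] <- raw_b
    }
  }
  for (k in seq_len(K)) a[k] <- list(pmax(evs[[k]][seq_len(d[k])], b[k]))
  list(K = K, pi = nk / N, mu = mu, Q = Q, a = a, d = d, b = b)
}

is_degenerate <- function(m) is.null(m) || isTRUE(attr(m, "degenerate"))

run_em <- function(Z, K, settings, init_assign, d_fixed = NULL) {
  N <- nrow(Z)
  # soft initial responsibilities: a hard start on a cluster of duplicated
  # points would be immediately singular
  resp <- matrix(if (K > 1) 0.1 / (K - 1) else 0, N, K)
  resp[cbind(seq_len(N), init_assign)] <- if (K > 1) 0.9 else 1
  model <- subspace_mstep(Z, resp, settings, d_fixed)
  if (is_degenerate(model)) return(NULL)
  # freeze the intrinsic dimensions after the first M-step: re-running the
  # scree test every iteration changes the model family mid-run and can
  # decrease the likelihood, breaking the EM monotonicity guarantee
  if (is.null(d_fixed)) d_fixed <- model$d
  loglik <- -Inf
  trace <- numeric(0)
  for (it in seq_len(settings$max_iter)) {
    ld <- subspace_logdens(Z, model)
    mx <- apply(ld, 1, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    new_ll <- sum(lse)
    resp <- exp(ld - lse)
    trace <- c(trace, new_ll)
    if (is.finite(loglik) && abs(new_ll - loglik) < settings$tol) {
      loglik <- new_ll
      break
    }
    loglik <- new_ll
    nxt <- subspace_mstep(Z, resp, settings, d_fixed)
    if (is_degenerate(nxt)) {
      # the next update would collapse a component (empty, or noise variance
      # at the floor): halt at the last valid iterate instead of chasing the
      # diverging likelihood of a point-mass solution
      model$collapsed <- TRUE
      break
    }
    model <- nxt
  }
  model$loglik <- loglik
  model$trace <- trace
  model$responsibilities <- resp
  model
}

# order-invariant seeded k-means initialization: cluster the lexicographically
# sorted copy of Z, then assign original rows to the nearest center
init_assignments <- function(Z, K, seed) {
  ord <- do.call(order, as.data.frame(Z))
  Zs <- Z[ord, , drop = FALSE]
  centers <- withr::with_seed(seed, {
    km <- suppressWarnings(kmeans(Zs, centers = K, nstart = 1, iter.max = 50))
    km$centers
  })
  d2 <- outer(rowSums(Z^2), rowSums(centers^2), "+") - 2 * Z %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Fit the parsimonious Gaussian subspace mixture
#'
#' Clusters the metric-embedded basis coefficients with a Gaussian mixture
#' whose component covariances live in cluster-specific low-dimensional
#' subspaces: per cluster an orthonormal basis `Q_k`, intrinsic dimension
#' `d_k` (Cattell scree test on the eigenvalues of the weighted covariance),
#' signal variances `a_kj` and a spherical residual noise `b_k` (the general
#' `[a_kj, b_k, Q_k, d_k]` sub-model). Fitted by EM from `n_init` seeded
#' k-means starts; the best final log-likelihood is kept.
#'
#' @param Z N x p matrix of embeddings from [embed_curves()] (a coefficient
#'   tibble is also accepted and embedded automatically).
#' @param K Number of clusters (1 <= K < N).
#' @param settings [em_settings()].
#' @param seed Integer seed controlling the random restarts.
#' @return Object of class `chrono_mixture` with elements `K`, `pi`, `mu`,
#'   `Q`, `a`, `d`, `b`, `loglik`, `bic`, `n_params`, `responsibilities`,
#'   `assignments` (hard labels by maximum posterior, ties to the lower
#'   cluster index) and `trace`.
#' @export
fit_profile_mixture <- function(Z, K, settings = em_settings(), seed = 1L) {
  if (!is.matrix(Z)) Z <- embed_curves(Z)
  N <- nrow(Z); p <- ncol(Z)
  stopifnot(K >= 1, N > K)
  # collapse threshold on the scale of the data's average total variance
  scale_var <- sum(apply(Z, 2, var)) / p
  settings$collapse_floor <- max(settings$variance_floor,
                                 (settings$collapse_rel %||% 0) * scale_var)
  best <- NULL
  for (i in seq_len(settings$n_init)) {
    init <- if (K == 1L) rep(1L, N) else {
      init_assignments(Z, K, seed = as.integer(seed) * 1000L + i)
    }
    fit <- run_em(Z, K, settings, init)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
    if (K == 1L) break # deterministic, no restarts needed
  }
  if (is.null(best)) {
    abort("all EM restarts degenerate (empty or collapsed cluster)")
  }
  m <- mixture_n_params(p, best$d, settings$model)
  best$n_params <- m
  best$bic <- -2 * best$loglik + m * log(N)
  # hard assignment, ties to the lower cluster index (max.col first)
  best$assignments <- max.col(best$responsibilities, ties.method = "first")
  best$patient_id <- rownames(Z)
  class(best) <- "chrono_mixture"
  best
}

# free parameters: mixing + means + orientations + signal variances + noises
mixture_n_params <- function(p, d, model = "common_noise") {
  K <- length(d)
  n_noise <- if (model == "common_noise") 1 else K
  (K - 1) + K * p + sum(d * (p - (d + 1) / 2)) + sum(d) + n_noise
}

#' @export
print.chrono_mixture <- function(x, ...) {
  cat("Subspace Gaussian mixture: K =", x$K,
      " loglik =", format(x$loglik, digits = 6),
      " BIC =", format(x$bic, digits = 6), "\n")
  cat("sizes:", table(factor(x$assignments, levels = seq_len(x$K))), "\n")
  invisible(x)
}

#' Select the number of profiles by BIC
#'
#' Fits the subspace mixture for each candidate K and returns the fit
#' minimizing BIC = -2 loglik + m log N, where m counts the free parameters
#' (mixing proportions, means, subspace orientations, signal variances and
#' noise variances). Ties go to the smaller K.
#'
#' @inheritParams fit_profile_mixture
#' @param k_range Candidate cluster numbers (default 2..6).
#' @return List with `model` (the best `chrono_mixture`) and `bic_table`
#'   (tibble with one row per K: `K`, `loglik`, `n_params`, `bic`).
#' @export
select_k_by_bic <- function(Z, k_range = 2:6, settings = em_settings(),
                            seed = 1L) {
  if (!length(k_range)) abort("k_range must be non-empty")
  if (!is.matrix(Z)) Z <- embed_curves(Z)
  ks <- sort(unique(as.integer(k_range)))
  fits <- purrr::map(ks, function(K) {
    tryCatch(fit_profile_mixture(Z, K, settings, seed),
             error = function(e) NULL) # K infeasible: every restart degenerate
  })
  tbl <- purrr::map2_dfr(fits, ks, function(f, K) {
    if (is.null(f)) {
      tibble::tibble(K = K, loglik = NA_real_, n_params = NA_real_,
                     bic = NA_real_)
    } else {
      tibble::tibble(K = f$K, loglik = f$loglik, n_params = f$n_params,
                     bic = f$bic)
    }
  })
  if (all(is.na(tbl$bic))) abort("no feasible mixture in k_range")
  best <- which(tbl$bic <= min(tbl$bic, na.rm = TRUE) + 1e-12)
  pick <- best[which.min(tbl$K[best])]
  list(model = fits[[pick]], bic_table = tbl)
}

#' Contact-distribution table by recovered profile
#'
#' Summarizes, per cluster and overall, the count and percentage of each of
#' the eleven contacts, with a per-slot association test: Pearson chi-squared,
#' switching to the Monte-Carlo exact test when any expected cell count
#' falls below 10. Clusters are reported in decreasing size order.
#'
#' @param cohort Cohort tibble containing the flag columns.
#' @param assignments Integer cluster labels (e.g. from
#'   [fit_profile_mixture()]); alternatively a `profile_label` column of
#'   `cohort` is used.
#' @param mc_reps Monte-Carlo replicates for the exact test.
#' @param seed Seed for the Monte-Carlo draw.
#' @return Tibble with one row per slot: count/percent columns per cluster
#'   (in decreasing size order), the overall column, the test method and
#'   p-value.
#' @export
profile_contact_table <- function(cohort, assignments = NULL,
                                  mc_reps = 10000L, seed = 1L) {
  lab <- assignments %||% cohort$profile_label
  if (is.null(lab)) abort("no assignments given and no profile_label column")
  stopifnot(length(lab) == nrow(cohort))
  sizes <- sort(table(lab), decreasing = TRUE)
  ord <- names(sizes)
  rows <- purrr::map_dfr(slot_names(), function(s) {
    f <- cohort[[s]]
    tab <- vapply(ord, function(g) sum(f[lab == g] == 1), numeric(1))
    ntab <- as.numeric(sizes)
    test <- tryCatch(
      group_contact_test(f, lab, mc_reps = mc_reps, seed = seed),
      error = function(e) list(method = NA_character_, p_value = NA_real_)
    )
    out <- tibble::tibble(slot = s,
                          overall_n = sum(f == 1),
                          overall_pct = 100 * mean(f == 1))
    for (i in seq_along(ord)) {
      out[[paste0("cluster", ord[i], "_n")]] <- unname(tab[i])
      out[[paste0("cluster", ord[i], "_pct")]] <- unname(100 * tab[i] / ntab[i])
    }
    out$method <- test$method
    out$p_value <- test$p_value
    out
  })
  rows
}

# association test of a binary flag against group labels with the
# expected-count switching rule (chi-squared vs Monte-Carlo exact)
group_contact_test <- function(flag, groups, mc_reps = 10000L, seed = 1L) {
  tab <- table(factor(flag, levels = c(0, 1)), groups)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(method = "none", p_value = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(expected) < 10) {
    r <- fisher_exact_mc(tab, reps = mc_reps, seed = seed)
  } else {
    r <- chi_square_test(tab)
  }
  list(method = r$method, p_value = r$p_value)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 means identical
#' partitions, 0 is the expected value under random labelling.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  mx <- (row_c + col_c) / 2
  if (mx == expected) return(1)
  (idx - expected) / (mx - expected)
}
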