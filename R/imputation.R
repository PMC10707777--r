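#' Chained-equation imputation with predictive mean matching
#'
#' Completes missing cells under the missing-at-random assumption by
#' chained equations: continuous targets are imputed by predictive mean
#' matching (PMM -- regress on the other variables, find the `k_donors`
#' observed cases nearest in predicted value, copy one donor's observed
#' value), binary targets by logistic draws at the predicted probability.
#' Parameter uncertainty is propagated by refitting each model on a
#' bootstrap resample each cycle. Targets are visited in increasing
#' missingness order; after `n_iter` cycles one completed dataset is
#' returned together with a convergence trace (per-cycle mean and SD of the
#' imputed cells, for the usual graphical convergence check).
#'
#' Observed cells are never modified, and every PMM-imputed value is, by
#' construction, a member of the target's observed value set.
#'
#' @param cohort Data frame with missing cells (`NA`).
#' @param targets Columns to impute; defaults to every column with missing
#'   values (excluding `patient_id`).
#' @param predictors Predictor columns; defaults to all other analysis
#'   variables (numeric, binary or factor columns except `patient_id`).
#' @param n_iter Number of chained cycles (50 in the reference analysis).
#' @param k_donors PMM donor pool size.
#' @param seed Integer seed; imputation is deterministic given
#'   `(cohort, plan, seed)`.
#' @return List with `cohort` (completed tibble), `trace` (tibble with
#'   `cycle`, `variable`, `mean`, `sd` of the imputed cells) and `notes`
#'   (character vector recording fallbacks such as ridge-stabilized
#'   logistic fits).
#' @export
impute_chained <- function(cohort, targets = NULL, predictors = NULL,
                           n_iter = 50L, k_donors = 5L, seed = 1L) {
  cohort <- tibble::as_tibble(cohort)
  miss_cols <- names(cohort)[vapply(cohort, anyNA, logical(1))]
  targets <- targets %||% setdiff(miss_cols, "patient_id")
  if (!length(targets)) {
    return(list(cohort = cohort,
                trace = tibble::tibble(cycle = integer(), variable = character(),
                                       mean = numeric(), sd = numeric()),
                notes = character()))
  }
  usable <- names(cohort)[vapply(cohort, function(x) {
    is.numeric(x) || is.factor(x) || is.character(x)
  }, logical(1))]
  predictors <- predictors %||% setdiff(usable, c("patient_id"))
  # a predictor must be complete, or itself a target (then its current
  # imputed values are used)
  predictors <- predictors[vapply(predictors, function(v) {
    !anyNA(cohort[[v]]) || v %in% targets
  }, logical(1))]
  for (v in targets) {
    if (!anyNA(cohort[[v]])) next
    if (all(is.na(cohort[[v]]))) {
      abort(paste0("target '", v, "' has no observed values"))
    }
  }
  is_binary <- function(x) all(x[!is.na(x)] %in% c(0, 1))
  method <- vapply(targets, function(v) {
    if (is_binary(cohort[[v]])) "logistic" else "pmm"
  }, character(1))
  # visit order: increasing missingness
  n_miss <- vapply(targets, function(v) sum(is.na(cohort[[v]])), numeric(1))
  targets <- targets[order(n_miss)]
  method <- method[targets]
  mask <- purrr::map(targets, ~ is.na(cohort[[.x]]))
  names(mask) <- targets

  notes <- character()
  completed <- cohort
  trace <- vector("list", 0)
  withr::with_seed(as.integer(seed), {
    # initial fill by random draws from the observed values
    for (v in targets) {
      obs <- completed[[v]][!mask[[v]]]
      completed[[v]][mask[[v]]] <- sample(obs, sum(mask[[v]]), replace = TRUE)
    }
    for (cycle in seq_len(n_iter)) {
      for (j in seq_along(targets)) {
        v <- targets[j]
        m <- mask[[v]]
        if (!any(m)) next
        preds <- setdiff(predictors, v)
        Xall <- design_for_imputation(completed, preds)
        yobs <- completed[[v]][!m]
        Xobs <- Xall[!m, , drop = FALSE]
        Xmis <- Xall[m, , drop = FALSE]
        boot <- sample.int(length(yobs), length(yobs), replace = TRUE)
        if (method[j] == "pmm") {
          bhat <- ridge_ols(Xobs, yobs)
          bstar <- ridge_ols(Xobs[boot, , drop = FALSE], yobs[boot])
          pred_obs <- as.vector(Xobs %*% bhat)
          pred_mis <- as.vector(Xmis %*% bstar)
          imp <- vapply(pred_mis, function(pm) {
            pool <- order(abs(pred_obs - pm))[seq_len(min(k_donors, length(yobs)))]
            yobs[pool[sample.int(length(pool), 1)]]
          }, numeric(1))
          completed[[v]][m] <- imp
        } else {
          fit <- logistic_irls(Xobs[boot, , drop = FALSE], yobs[boot])
          if (fit$ridged) {
            notes <- c(notes, paste0("cycle ", cycle, ", '", v,
                                      "': ridge-stabilized logistic fit"))
          }
          pr <- plogis(as.vector(Xmis %*% fit$beta))
          completed[[v]][m] <- as.numeric(runif(length(pr)) < pr)
        }
        imp_now <- completed[[v]][m]
        trace[[length(trace) + 1]] <- tibble::tibble(
          cycle = cycle, variable = v,
          mean = mean(as.numeric(imp_now)),
          sd = if (length(imp_now) > 1) sd(as.numeric(imp_now)) else NA_real_
        )
      }
    }
  })
  list(cohort = completed, trace = dplyr::bind_rows(trace), notes = notes)
}

# numeric design matrix (intercept + dummies) from the current completed data
design_for_imputation <- function(data, preds) {
  if (!length(preds)) return(matrix(1, nrow(data), 1))
  d <- data[, preds, drop = FALSE]
  d <- purrr::map_dfc(d, function(x) {
    if (is.character(x)) x <- factor(x)
    x
  })
  X <- model.matrix(~ ., data = d)
  X
}

# OLS with a tiny ridge for rank safety
ridge_ols <- function(X, y) {
  p <- ncol(X)
  A <- crossprod(X) + diag(1e-8 * (1 + colSums(X^2)), p)
  solve(A, crossprod(X, y))
}

# plain IRLS logistic with automatic ridge fallback on separation
logistic_irls <- function(X, y, max_iter = 50L) {
  fit_one <- function(lambda) {
    beta <- rep(0, ncol(X))
    for (i in seq_len(max_iter)) {
      eta <- as.vector(X %*% beta)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      A <- crossprod(X * sqrt(w)) + diag(lambda, ncol(X))
      newb <- tryCatch(solve(A, crossprod(X, w * z)), error = function(e) NULL)
      if (is.null(newb)) return(NULL)
      if (max(abs(newb - beta)) < 1e-8) { beta <- as.vector(newb); break }
      beta <- as.vector(newb)
    }
    beta
  }
  beta <- fit_one(1e-10)
  if (is.null(beta) || max(abs(beta)) > 15) {
    beta <- fit_one(1e-2)
    return(list(beta = beta, ridged = TRUE))
  }
  list(beta = beta, ridged = FALSE)
}
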