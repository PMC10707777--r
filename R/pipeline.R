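#' Analysis-ready factor coding of a cohort
#'
#' Encodes the regression factors with the reference levels of the study
#' design: gender F, education middle school, BMI tertile 1, profile 1,
#' diabetes "no". Adds `bmi_cat` (factor over `bmi_tertile`) and, when a
#' `profile_label` column is present, a `profile` factor.
#'
#' @param cohort Cohort tibble.
#' @return The cohort with factor columns ready for the model formulas.
#' @export
prepare_model_data <- function(cohort) {
  out <- cohort
  out$gender <- factor(out$gender, levels = c("F", "M"))
  if (!is.factor(out$education)) {
    out$education <- factor(out$education, levels = c("middle", "high", "degree"))
  }
  if ("bmi_tertile" %in% names(out)) {
    out$bmi_cat <- factor(out$bmi_tertile, levels = 1:3)
  }
  if ("diabetes" %in% names(out) && !is.factor(out$diabetes)) {
    out$diabetes <- factor(out$diabetes, levels = c("no", "pre", "yes"))
  }
  if ("profile_label" %in% names(out)) {
    out$profile <- factor(out$profile_label)
  }
  out
}

#' Model templates of the association analysis
#'
#' The full starting models for backward AIC selection: all outcomes adjust
#' for gender, age, education, physical activity, alcohol, smoking, BMI
#' category and chrono-nutritional profile; only the psychometric scores
#' additionally start from hypertension, diabetes and dyslipidemia.
#'
#' @return Named list with elements `logistic` (formulas for the three
#'   comorbidities), `metabolic` and `psychological` (median-regression
#'   formulas).
#' @export
model_templates <- function() {
  base <- "gender + age + education + physical_activity + alcohol + smoking + bmi_cat + profile"
  psy <- paste(base, "+ hypertension + diabetes + dyslipidemia")
  f <- function(lhs, rhs) as.formula(paste(lhs, "~", rhs))
  list(
    logistic = list(
      hypertension = f("hypertension", base),
      dyslipidemia = f("dyslipidemia", base),
      diabetes = f("diabetes_bin", base)
    ),
    metabolic = list(
      HDL = f("HDL", base), TG = f("TG", base), HOMA = f("HOMA", base)
    ),
    psychological = list(
      SF36_PH = f("SF36_PH", psy), SF36_MH = f("SF36_MH", psy),
      SCL90_GSI = f("SCL90_GSI", psy), EAT26 = f("EAT26", psy),
      BIS11 = f("BIS11", psy), BES = f("BES", psy), YFAS = f("YFAS", psy)
    )
  )
}

#' Run the full chrono-nutritional pipeline
#'
#' Executes generate -> impute -> smooth -> cluster -> summarize -> regress
#' on a synthetic cohort, writing every stage's output (CSV/JSON) into
#' `out_dir`. The run is deterministic: the same configuration and seed
#' produce identical outputs.
#'
#' Cluster labels are reported in decreasing size order (label 1 = largest
#' cluster), which also fixes profile 1 as the regression reference.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param stages Stages to run (prefix of the full sequence).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("generate", "impute", "smooth", "cluster",
                                    "summarize", "regress")) {
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.json"))
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  res <- list(config = config)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if ("generate" %in% stages) {
    res$generated <- run_stage("generate", {
      g <- generate_cohort(config$n, config$seed, config$generator)
      write_cohort(g$cohort, file.path(out_dir, "cohort.csv"))
      readr::write_csv(g$truth, file.path(out_dir, "truth.csv"))
      logf("generate: %d patients written", nrow(g$cohort))
      g
    })
  }
  if ("impute" %in% stages) {
    res$imputed <- run_stage("impute", {
      imp <- impute_chained(res$generated$cohort,
                            n_iter = config$imputation$n_iter,
                            k_donors = config$imputation$k_donors,
                            seed = config$seed)
      write_cohort(imp$cohort, file.path(out_dir, "cohort_imputed.csv"))
      readr::write_csv(imp$trace, file.path(out_dir, "imputation_trace.csv"))
      logf("impute: %d cells traced", nrow(imp$trace))
      imp
    })
  }
  if ("smooth" %in% stages) {
    res$smoothed <- run_stage("smooth", {
      basis <- fourier_basis()
      cohort <- res$imputed$cohort %||% res$generated$cohort
      sel <- gcv_select_lambda(cohort, basis, config$lambda_grid)
      curves <- smooth_cohort(cohort, basis, sel$lambda)
      readr::write_csv(curves, file.path(out_dir, "curve_coefficients.csv"))
      jsonlite::write_json(
        list(lambda = sel$lambda, diagnostics = sel$diagnostics),
        file.path(out_dir, "smoothing.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
      logf("smooth: lambda = %g, edf = %g", sel$lambda,
           sel$diagnostics$edf[which(sel$diagnostics$lambda == sel$lambda)])
      list(basis = basis, selection = sel, curves = curves)
    })
  }
  if ("cluster" %in% stages) {
    res$clustered <- run_stage("cluster", {
      Z <- embed_curves(res$smoothed$curves, res$smoothed$basis)
      sel <- select_k_by_bic(Z, config$k_range, config$em, config$seed)
      # relabel clusters in decreasing size order
      sizes <- table(factor(sel$model$assignments, levels = seq_len(sel$model$K)))
      relab <- order(order(-as.numeric(sizes), seq_len(sel$model$K)))
      labels <- relab[sel$model$assignments]
      cohort <- res$imputed$cohort %||% res$generated$cohort
      cohort$profile_label <- labels
      write_cohort(cohort, file.path(out_dir, "cohort_labeled.csv"))
      readr::write_csv(sel$bic_table, file.path(out_dir, "bic_table.csv"))
      jsonlite::write_json(
        list(K = sel$model$K, pi = sel$model$pi, bic = sel$model$bic,
             assignments = labels),
        file.path(out_dir, "cluster.json"), auto_unbox = TRUE, digits = NA)
      logf("cluster: K = %d selected by BIC", sel$model$K)
      list(selection = sel, labels = labels, cohort = cohort)
    })
  }
  if ("summarize" %in% stages) {
    res$summaries <- run_stage("summarize", {
      cohort <- res$clustered$cohort
      ptab <- profile_contact_table(cohort, cohort$profile_label,
                                    seed = config$seed)
      readr::write_csv(ptab, file.path(out_dir, "profile_contact_table.csv"))
      stab <- summary_table(prepare_model_data(cohort), group_by = "profile_label",
                            variables = c("gender", "age", "education", "BMI",
                                          "hypertension", "diabetes",
                                          "dyslipidemia", "SCL90_GSI", "BES"),
                            seed = config$seed)
      readr::write_csv(stab, file.path(out_dir, "summary_by_profile.csv"))
      logf("summarize: %d profile rows", nrow(ptab))
      list(profile_table = ptab, summary = stab)
    })
  }
  if ("regress" %in% stages) {
    res$models <- run_stage("regress", {
      d <- prepare_model_data(res$clustered$cohort)
      d$diabetes_bin <- as.numeric(d$diabetes == "yes")
      tmpl <- model_templates()
      fit_set <- function(forms, family) {
        purrr::imap(forms, function(f, nm) {
          withr::with_seed(config$seed,
                           backward_select(f, d, family = family))
        })
      }
      logi <- fit_set(tmpl$logistic, "logistic")
      med <- fit_set(c(tmpl$metabolic, tmpl$psychological), "median")
      rows <- dplyr::bind_rows(
        purrr::imap_dfr(logi, function(m, nm) {
          dplyr::mutate(tidy(m$fit), outcome = nm, family = "logistic",
                        .before = 1)
        }),
        purrr::imap_dfr(med, function(m, nm) {
          dplyr::mutate(tidy(m$fit), outcome = nm, family = "median",
                        .before = 1)
        })
      )
      readr::write_csv(rows, file.path(out_dir, "regression_results.csv"))
      traces <- c(purrr::map(logi, "trace"), purrr::map(med, "trace"))
      jsonlite::write_json(traces, file.path(out_dir, "regression_trace.json"),
                           dataframe = "columns", digits = NA)
      logf("regress: %d models fitted", length(logi) + length(med))
      list(logistic = logi, median = med, table = rows)
    })
  }
  invisible(res)
}
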