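#' Body mass index
#'
#' @param weight_kg Body weight in kg (> 0).
#' @param height_m Height in metres (> 0).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_m <= 0, na.rm = TRUE)) {
    abort("weight and height must be positive")
  }
  weight_kg / height_m^2
}

#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' HOMA = fasting insulin (uU/mL) x fasting plasma glucose (mmol/L) / 22.5.
#' Not defined for insulin-treated patients: their value is `NA`.
#'
#' @param insulin_uU_ml Fasting serum insulin, uU/mL.
#' @param fpg_mmol_l Fasting plasma glucose, mmol/L.
#' @param insulin_treated 0/1 indicator of ongoing insulin treatment.
#' @return HOMA index, `NA` where insulin-treated.
#' @export
compute_homa <- function(insulin_uU_ml, fpg_mmol_l, insulin_treated = 0) {
  if (any(insulin_uU_ml < 0, na.rm = TRUE) || any(fpg_mmol_l < 0, na.rm = TRUE)) {
    abort("insulin and glucose must be non-negative")
  }
  out <- insulin_uU_ml * fpg_mmol_l / 22.5
  out[insulin_treated == 1] <- NA_real_
  out
}

#' Friedewald estimate of LDL cholesterol (mmol/L)
#'
#' LDL = TC - HDL - TG/2.2, valid only below a triglyceride bound of
#' 4.52 mmol/L (the conventional 400 mg/dL); above it the estimate is
#' returned as `NA` with a warning.
#'
#' @param tc,hdl,tg Total, HDL cholesterol and triglycerides, all mmol/L.
#' @param tg_bound Validity bound for TG, mmol/L.
#' @return Estimated LDL, mmol/L.
#' @export
friedewald_ldl <- function(tc, hdl, tg, tg_bound = 4.52) {
  out <- tc - hdl - tg / 2.2
  over <- !is.na(tg) & tg > tg_bound
  if (any(over)) {
    warn(paste0(sum(over), " TG value(s) above the Friedewald bound (",
                tg_bound, " mmol/L); LDL set to NA"))
    out[over] <- NA_real_
  }
  out
}

#' BMI tertile categories
#'
#' By default cuts at the empirical 1/3 and 2/3 quantiles (type-7);
#' intervals are closed on the right, i.e. category 2 is `(c1, c2]`.
#' Fixed cut points (e.g. the published 40.2 / 46.2 kg/m^2) can be supplied.
#'
#' @param bmi Numeric BMI values (>= 3 non-missing unless `cuts` given).
#' @param cuts Optional fixed cut points of length 2.
#' @return List with `tertile` (integer 1/2/3 per patient) and `cuts`.
#' @export
bmi_tertiles <- function(bmi, cuts = NULL) {
  if (is.null(cuts)) {
    obs <- bmi[!is.na(bmi)]
    if (length(obs) < 3) abort("need at least 3 BMI values")
    if (length(unique(obs)) == 1L) {
      warn("all BMI values identical; single category")
      return(list(tertile = ifelse(is.na(bmi), NA_integer_, 1L),
                  cuts = c(NA_real_, NA_real_)))
    }
    # inverse-ECDF (type 1) quantiles: cuts are observed values, matching
    # right-closed interval labels like (40.2, 46.2]
    cuts <- unname(quantile(obs, c(1 / 3, 2 / 3), type = 1))
  }
  tert <- 1L + (bmi > cuts[1]) + (bmi > cuts[2])
  list(tertile = as.integer(tert), cuts = cuts)
}

#' Pearson chi-squared test of independence
#'
#' X^2 = sum (O - E)^2 / E on an r x c table, df = (r-1)(c-1), p from the
#' upper chi-squared tail (no continuity correction).
#'
#' @param tab r x c matrix of counts with positive margins.
#' @return Tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has a zero margin")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(method = "chi2",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 mc_reps = NA_integer_)
}

#' Monte-Carlo exact test for an r x c table
#'
#' Draws `reps` tables conditional on both margins and computes
#' p = (1 + #\{X2_sim >= X2_obs\}) / (reps + 1) on the Pearson statistic --
#' the Monte-Carlo version of the exact conditional test used when expected
#' cell counts are small.
#'
#' @param tab r x c matrix of counts.
#' @param reps Number of simulated tables.
#' @param seed Integer seed for the draw.
#' @return Tibble with `method`, `statistic`, `p_value`, `mc_reps`.
#' @export
fisher_exact_mc <- function(tab, reps = 100000L, seed = 1L) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- function(o) sum((o - E)^2 / E)
  obs <- x2(tab)
  sims <- withr::with_seed(as.integer(seed), {
    r2dtable(reps, rowSums(tab), colSums(tab))
  })
  exceed <- sum(vapply(sims, x2, numeric(1)) >= obs - 1e-12)
  tibble::tibble(method = "fisher_mc",
                 statistic = obs,
                 df = NA_real_,
                 p_value = (1 + exceed) / (reps + 1),
                 mc_reps = as.integer(reps))
}

#' Kruskal-Wallis rank test
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 2 non-empty groups).
#' @return Tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_test <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) abort("need at least 2 non-empty groups")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(method = "kruskal_wallis", statistic = 0,
                          df = nlevels(groups) - 1, p_value = 1,
                          mc_reps = NA_integer_))
  }
  res <- kruskal.test(values, groups)
  tibble::tibble(method = "kruskal_wallis",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 mc_reps = NA_integer_)
}

#' Wilcoxon rank-sum test (two independent groups)
#'
#' Mid-rank tie handling with the normal approximation, matching the
#' two-group member of the non-parametric battery.
#'
#' @param a,b Numeric samples.
#' @return Tibble with `method`, `statistic`, `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(tibble::tibble(method = "wilcoxon", statistic = 0, df = NA_real_,
                          p_value = 1, mc_reps = NA_integer_))
  }
  res <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  tibble::tibble(method = "wilcoxon",
                 statistic = unname(res$statistic),
                 df = NA_real_,
                 p_value = unname(res$p.value),
                 mc_reps = NA_integer_)
}

#' Grouped descriptive summary table
#'
#' One row per variable: median (IQR) for continuous variables, count (%)
#' for binary/categorical ones, per group and overall, with the matching
#' test per row -- Kruskal-Wallis (or Wilcoxon for two groups) for
#' continuous variables, chi-squared switching to the Monte-Carlo exact
#' test when any expected count is below 10 for categorical ones. A
#' `significant` flag marks p < 0.05.
#'
#' @param cohort Cohort tibble.
#' @param group_by Name of the grouping column (e.g. `"bmi_tertile"` or
#'   `"profile_label"`); `NULL` gives the overall column only, with no tests.
#' @param variables Character vector of columns to summarize; defaults to
#'   all columns except identifiers and the grouping column.
#' @param mc_reps,seed Monte-Carlo settings for the exact test.
#' @return Tibble with one row per variable (per level for categoricals).
#' @export
summary_table <- function(cohort, group_by = NULL, variables = NULL,
                          mc_reps = 10000L, seed = 1L) {
  skip <- c("patient_id", group_by)
  variables <- variables %||% setdiff(names(cohort), skip)
  grp <- if (!is.null(group_by)) factor(cohort[[group_by]]) else NULL
  fmt_cont <- function(x) {
    if (all(is.na(x))) return(NA_character_)
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
  }
  fmt_cat <- function(x, lev) {
    n <- sum(x == lev, na.rm = TRUE)
    sprintf("%d (%.0f%%)", n, 100 * n / sum(!is.na(x)))
  }
  one_var <- function(v) {
    x <- cohort[[v]]
    if (all(is.na(x))) {
      row <- tibble::tibble(variable = v, level = NA_character_,
                            overall = NA_character_)
      if (!is.null(grp)) {
        for (g in levels(grp)) row[[paste0("group_", g)]] <- NA_character_
        row$method <- NA_character_
        row$p_value <- NA_real_
      }
      return(row)
    }
    is_cat <- is.character(x) || is.factor(x) || all(x %in% c(0, 1, NA))
    if (!is_cat) {
      row <- tibble::tibble(variable = v, level = NA_character_,
                            overall = fmt_cont(x))
      if (!is.null(grp)) {
        for (g in levels(grp)) row[[paste0("group_", g)]] <- fmt_cont(x[grp == g])
        tst <- if (all(is.na(x))) NULL else if (nlevels(grp) == 2) {
          wilcoxon_rank_sum(x[grp == levels(grp)[1]], x[grp == levels(grp)[2]])
        } else kruskal_wallis_test(x, grp)
        row$method <- if (is.null(tst)) NA_character_ else tst$method
        row$p_value <- if (is.null(tst)) NA_real_ else tst$p_value
      }
      return(row)
    }
    lev <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
    if (!length(lev)) lev <- NA
    rows <- purrr::map_dfr(lev, function(l) {
      row <- tibble::tibble(variable = v, level = as.character(l),
                            overall = fmt_cat(x, l))
      if (!is.null(grp)) {
        for (g in levels(grp)) row[[paste0("group_", g)]] <- fmt_cat(x[grp == g], l)
      }
      row
    })
    if (!is.null(grp) && length(lev) >= 1 && !all(is.na(x))) {
      tab <- table(x, grp)
      tst <- tryCatch({
        if (nrow(tab) < 2) NULL else {
          E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
          if (min(E) < 10) fisher_exact_mc(tab, reps = mc_reps, seed = seed)
          else chi_square_test(tab)
        }
      }, error = function(e) NULL)
      rows$method <- if (is.null(tst)) NA_character_ else tst$method
      rows$p_value <- if (is.null(tst)) NA_real_ else tst$p_value
    }
    rows
  }
  out <- purrr::map_dfr(variables, one_var)
  if (!is.null(grp)) out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}
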