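#' Read and write cohort tables
#'
#' Cohort CSVs carry one row per patient: the eleven binary meal-contact
#' flags, demographic and lifestyle covariates, clinical outcomes and
#' psychometric total scores. Missing values are stored as empty cells and
#' surface in R as `NA` -- never as a sentinel number.
#'
#' `read_cohort()` validates that all mandatory columns are present and that
#' the flag columns are binary; unknown columns are preserved untouched.
#'
#' @param path File path of the CSV.
#' @param require_flags Should the eleven contact-flag columns be required?
#' @return A tibble, one row per patient.
#' @export
read_cohort <- function(path, require_flags = TRUE) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"patient_id" %in% names(x)) {
    abort("cohort file lacks mandatory column 'patient_id'")
  }
  x$patient_id <- as.character(x$patient_id)
  if (require_flags) validate_contacts(x)
  x
}

#' @rdname read_cohort
#' @param cohort Cohort tibble to write.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Builds a fully-resolved configuration for [run_pipeline()]. Any subset of
#' settings can be overridden; the remainder keep their defaults, which are
#' the published profile parameters for the generator (see
#' [generator_defaults()]) and standard numerical settings elsewhere.
#'
#' @param n Cohort size to generate (173 in the study design).
#' @param seed Integer seed controlling every random stage.
#' @param lambda_grid Candidate roughness penalties for GCV selection.
#' @param k_range Candidate numbers of profiles for BIC selection.
#' @param em EM settings, see [em_settings()].
#' @param imputation List with `n_iter` (cycles) and `k_donors`.
#' @param generator Generator parameters, see [generator_defaults()].
#' @return A named list of class `chrono_config`.
#' @export
pipeline_config <- function(n = 173L, seed = 1L,
                            lambda_grid = default_lambda_grid(),
                            k_range = 2:6,
                            em = em_settings(),
                            imputation = list(n_iter = 50L, k_donors = 5L),
                            generator = generator_defaults()) {
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    lambda_grid = lambda_grid, k_range = as.integer(k_range),
    em = em, imputation = imputation, generator = generator
  )
  validate_config(cfg)
  structure(cfg, class = "chrono_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n > 0, length(cfg$seed) == 1)
  if (!length(cfg$lambda_grid)) abort("lambda_grid must be non-empty")
  if (any(cfg$lambda_grid < 0)) abort("lambda_grid values must be >= 0")
  if (!length(cfg$k_range)) abort("k_range must be non-empty")
  w <- cfg$generator$mixture_weights
  if (abs(sum(w) - 1) > 1e-9) abort("mixture_weights must sum to 1")
  if (any(w < 0)) abort("mixture_weights must be non-negative")
  cp <- cfg$generator$contact_prob
  if (any(cp < 0 | cp > 1)) abort("contact probabilities must lie in [0,1]")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @export
default_lambda_grid <- function() {
  exp(seq(log(1e-4), log(1e3), length.out = 30))
}

#' Write or read a configuration as JSON
#'
#' Every pipeline run logs its fully-resolved configuration so that runs are
#' reproducible from the JSON alone.
#'
#' @param config A `chrono_config` object.
#' @param path Destination / source path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- raw$generator
  gen$contact_prob <- as.matrix(gen$contact_prob)
  pipeline_config(
    n = raw$n, seed = raw$seed, lambda_grid = raw$lambda_grid,
    k_range = raw$k_range, em = do.call(em_settings, as.list(raw$em)),
    imputation = raw$imputation, generator = gen
  )
}
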