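#' Describe a longitudinal cohort sampling design
#'
#' The design mirrors a multi-year cohort with roughly quarterly visits spread
#' uniformly over the calendar year, a subject-level insulin-resistance label
#' (IR / IS), and subject-level BMI and age covariates. The default is a
#' desk-scale cohort (40 subjects, 3 years, 4 visits/year); use
#' [full_cohort_design()] for a 105-subject preset matching the published
#' cohort size.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_years number of follow-up years.
#' @param visits_per_year sampling events per subject per year (>= 1).
#' @param frac_ir fraction of subjects labelled insulin resistant, in `[0, 1]`.
#' @param bmi_mean,bmi_sd subject BMI distribution (kg/m^2).
#' @param age_range length-2 range of ages (years) sampled uniformly.
#' @param seed integer seed making the generated cohort reproducible, or
#'   `NULL` to draw from the current RNG stream.
#' @return an object of class `cohort_design`.
#' @seealso [generate_visits()], [generate_features()], [generate_taxon_counts()]
#' @export
cohort_design <- function(n_subjects = 40, n_years = 3, visits_per_year = 4,
                          frac_ir = 0.5, bmi_mean = 28, bmi_sd = 4,
                          age_range = c(25, 75), seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stopf("n_subjects must be >= 1")
  if (!is.numeric(visits_per_year) || visits_per_year < 1)
    stopf("visits_per_year must be >= 1")
  if (!is.numeric(n_years) || n_years < 1) stopf("n_years must be >= 1")
  if (frac_ir < 0 || frac_ir > 1) stopf("frac_ir must lie in [0, 1]")
  if (bmi_sd < 0) stopf("bmi_sd must be non-negative")
  if (length(age_range) != 2 || diff(age_range) < 0)
    stopf("age_range must be an increasing length-2 vector")
  structure(
    list(n_subjects = as.integer(n_subjects), n_years = as.integer(n_years),
         visits_per_year = as.integer(visits_per_year), frac_ir = frac_ir,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, age_range = age_range,
         seed = seed),
    class = "cohort_design")
}

#' @rdname cohort_design
#' @param ... overrides passed to [cohort_design()].
#' @export
full_cohort_design <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 105, n_years = 4, visits_per_year = 4), list(...))
  do.call(cohort_design, args)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("Cohort design: %d subjects, %d years x %d visits/year, %.0f%% IR\n",
              x$n_subjects, x$n_years, x$visits_per_year, 100 * x$frac_ir))
  invisible(x)
}

#' Generate per-visit sampling records for a cohort design
#'
#' Each subject receives `n_years * visits_per_year` visits with day-of-year
#' drawn uniformly on `{1, ..., 365}` (sampling events spread evenly over the
#' calendar). The IR/IS group label is a subject-level attribute: exactly
#' `round(frac_ir * n_subjects)` subjects are labelled IR, and every visit of
#' a subject carries the same label.
#'
#' @param design a [cohort_design()].
#' @param seed overrides `design$seed` when given.
#' @return a `data.frame` with one row per visit and columns `sample_id`,
#'   `subject_id`, `day_of_year`, `year_index`, `group`, `bmi`, `age`.
#' @export
generate_visits <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    ns <- design$n_subjects
    vpy <- design$visits_per_year
    npv <- design$n_years * vpy
    n <- ns * npv
    subj <- sprintf("S%03d", seq_len(ns))
    n_ir <- round(design$frac_ir * ns)
    grp <- rep("IS", ns)
    grp[sample.int(ns, n_ir)] <- "IR"
    bmi <- stats::rnorm(ns, design$bmi_mean, design$bmi_sd)
    age <- round(stats::runif(ns, design$age_range[1], design$age_range[2]))
    out <- data.frame(
      subject_id = rep(subj, each = npv),
      day_of_year = sample.int(365L, n, replace = TRUE),
      year_index = rep(rep(seq_len(design$n_years), each = vpy), ns),
      group = rep(grp, each = npv),
      bmi = rep(bmi, each = npv),
      age = rep(age, each = npv),
      stringsAsFactors = FALSE)
    out$sample_id <- sprintf("%s_y%d_v%02d", out$subject_id, out$year_index,
                             rep(rep(seq_len(vpy), design$n_years), ns))
    out[c("sample_id", "subject_id", "day_of_year", "year_index",
          "group", "bmi", "age")]
  })
}
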