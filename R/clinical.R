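#' Clinical characteristics of the emulated amblyope cohort
#'
#' Loads the clinical table of the eleven anisometropic amblyopes whose
#' deficit structure the simulated cohort emulates: age, sex, the
#' amblyopic eye, and per-eye logMAR visual acuity.
#'
#' @return A data frame with one row per subject.
#' @export
amblyope_clinical <- function() {
  utils::read.csv(system.file("extdata", "amblyope_clinical.csv",
                              package = "onoffcsf", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Cohort aggregates from the clinical table
#'
#' Mean age with the population (n-denominator) standard deviation — the
#' convention behind the cohort's printed "mean +/- SD" — and the count of
#' subjects meeting the amblyopia criterion of an interocular acuity
#' difference of at least 0.2 logMAR (two lines).
#'
#' @param clinical Data frame from [amblyope_clinical()].
#' @param criterion_logmar Interocular-difference criterion (default 0.2).
#' @return A list with `n`, `mean_age`, `sd_age_population`,
#'   `sd_age_sample`, `n_meeting_criterion`.
#' @export
clinical_summary <- function(clinical = amblyope_clinical(),
                             criterion_logmar = 0.2) {
  n <- nrow(clinical)
  age <- clinical$age
  iod <- abs(clinical$va_logmar_od - clinical$va_logmar_os)
  list(n = n,
       mean_age = mean(age),
       sd_age_population = sqrt(sum((age - mean(age))^2) / n),
       sd_age_sample = stats::sd(age),
       n_meeting_criterion = sum(iod >= criterion_logmar - 1e-12))
}
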