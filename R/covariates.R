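#' Encode clinical and treatment covariates as model features
#'
#' Maps the cohort's clinical fields to the numeric codings used in the
#' NTCP model design matrix:
#'
#' * `age_5y` — age divided by 5 (a continuous per-5-year term, so one
#'   coefficient is the log-odds change per 5-year increase);
#' * `bmi` continuous plus indicators `bmi_ge25` / `bmi_ge30` (WHO
#'   overweight / obese cut-offs);
#' * 0/1 indicators for sex (male), smoking history, each comorbidity flag
#'   (hypertension, diabetes, cardiological, haematological, oncological),
#'   squamous-cell vs undifferentiated histology, high overall stage
#'   (III-IVB), T4 category, positive nodal status (N2+), induction
#'   chemotherapy, RT alone, VMAT technique, and fraction dose >= 2.12 Gy;
#' * `ott_days` — overall treatment time in days.
#'
#' @param cohort A cohort tibble with the clinical columns produced by
#'   [generate_cohort()] (or equivalent real data).
#' @return A tibble of numeric features, one row per patient.
#' @export
encode_covariates <- function(cohort) {
  required <- c("sex", "age", "bmi", "smoking", "comorb_hypertension",
                "comorb_diabetes", "comorb_cardiological",
                "comorb_haematological", "comorb_oncological", "histology",
                "stage_group", "t_high", "n_positive", "treatment",
                "technique", "fraction_dose", "ott_days")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort_ntcp(sprintf("Cohort is missing mandatory covariate column(s): %s.",
                       paste(missing, collapse = ", ")),
               "ntcpxero_input_error")
  }
  as01 <- function(x) as.numeric(as.logical(x))
  tibble::tibble(
    age_5y = cohort$age / 5,
    bmi = cohort$bmi,
    bmi_ge25 = as.numeric(cohort$bmi >= 25),
    bmi_ge30 = as.numeric(cohort$bmi >= 30),
    sex_male = as.numeric(cohort$sex == "M"),
    smoking = as01(cohort$smoking),
    comorb_hypertension = as01(cohort$comorb_hypertension),
    comorb_diabetes = as01(cohort$comorb_diabetes),
    comorb_cardiological = as01(cohort$comorb_cardiological),
    comorb_haematological = as01(cohort$comorb_haematological),
    comorb_oncological = as01(cohort$comorb_oncological),
    histology_scc = as.numeric(cohort$histology == "SCC"),
    histology_other = as.numeric(cohort$histology == "other"),
    stage_high = as.numeric(cohort$stage_group == "high"),
    t_high = as01(cohort$t_high),
    n_positive = as01(cohort$n_positive),
    treat_icht = as.numeric(cohort$treatment == "iCHT+RT-CHT"),
    treat_rt_alone = as.numeric(cohort$treatment == "RT alone"),
    technique_vmat = as.numeric(cohort$technique == "VMAT"),
    fraction_ge212 = as.numeric(cohort$fraction_dose >= 2.12),
    ott_days = as.numeric(cohort$ott_days)
  )
}
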