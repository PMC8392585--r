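#' Derive the acute salivary dysfunction endpoint from weekly CTCAE grades
#'
#' Grades are CTCAE dry-mouth scores (0-3) assessed at baseline (first
#' entry, which must be 0: patients symptomatic before radiotherapy are
#' excluded) and then weekly over the treatment course; week indices count
#' from 1 at the first assessment. The binary endpoint is any grade >= 2 at
#' any weekly assessment. The longitudinal endpoint is a mean grade of at
#' least 1.5 over the recorded assessments.
#'
#' @param grades Integer vector of weekly grades in `{0,1,2,3}`, first
#'   entry (baseline) 0.
#' @return A one-row tibble: `event` (0/1), `first_event_week` (week index
#'   or `NA`), `mean_grade`, `longitudinal_event` (0/1), `n_weeks`.
#' @examples
#' derive_endpoint(c(0, 1, 2, 1, 1))  # event at week 3, mean grade 1.0
#' @export
derive_endpoint <- function(grades) {
  if (length(grades) == 0L || anyNA(grades)) {
    abort_ntcp("`grades` must be a non-empty vector without missing values.",
               "ntcpxero_endpoint_error")
  }
  if (!all(grades %in% 0:3)) {
    abort_ntcp("CTCAE grades must be integers between 0 and 3.",
               "ntcpxero_endpoint_error")
  }
  if (grades[1L] != 0) {
    abort_ntcp(paste0("Baseline (pre-RT) grade must be 0: patients with salivary ",
                      "symptoms before RT initiation are excluded."),
               "ntcpxero_endpoint_error")
  }
  hit <- which(grades >= 2)
  mg <- mean(grades)
  tibble::tibble(
    event = as.integer(length(hit) > 0),
    first_event_week = if (length(hit)) hit[1L] else NA_integer_,
    mean_grade = mg,
    longitudinal_event = as.integer(mg >= 1.5),
    n_weeks = length(grades)
  )
}

#' Derive endpoints for every patient in a cohort
#'
#' @param cohort A cohort tibble with a list-column of weekly grade vectors.
#' @param grades_col Name of the grades list-column.
#' @return `cohort` with the [derive_endpoint()] columns appended.
#' @export
derive_endpoints <- function(cohort, grades_col = "weekly_grades") {
  grades <- cohort[[grades_col]]
  if (is.null(grades)) {
    abort_ntcp(sprintf("Column `%s` not found in cohort.", grades_col),
               "ntcpxero_input_error")
  }
  ep <- dplyr::bind_rows(purrr::map(grades, derive_endpoint))
  dplyr::bind_cols(dplyr::select(cohort, -dplyr::any_of(names(ep))), ep)
}

#' Actuarial incidence of the endpoint by week
#'
#' The fraction of patients whose first event occurred at or before each
#' week, among patients still under observation then: a patient leaves the
#' risk set once their assessment series ends, unless they already had the
#' event (events are never lost). With no early exits this reduces to the
#' crude cumulative event proportion.
#'
#' @param cohort A cohort tibble; endpoints are derived on the fly if the
#'   `first_event_week` column is absent.
#' @param weeks Week indices to evaluate (default: 1 to the longest series).
#' @param grades_col Name of the grades list-column.
#' @return A tibble with `week`, `at_risk`, `cum_events`, `incidence`.
#' @export
actuarial_incidence <- function(cohort, weeks = NULL,
                                grades_col = "weekly_grades") {
  if (!all(c("first_event_week", "n_weeks") %in% names(cohort))) {
    cohort <- derive_endpoints(cohort, grades_col)
  }
  if (is.null(weeks)) weeks <- seq_len(max(cohort$n_weeks))
  if (any(weeks < 1)) {
    abort_ntcp("Week indices must be >= 1.", "ntcpxero_input_error")
  }
  few <- cohort$first_event_week
  nw <- cohort$n_weeks
  purrr::map_dfr(weeks, function(w) {
    evented <- !is.na(few) & few <= w
    in_obs <- evented | nw >= w
    tibble::tibble(
      week = w,
      at_risk = sum(in_obs),
      cum_events = sum(evented),
      incidence = if (sum(in_obs)) sum(evented) / sum(in_obs) else NA_real_
    )
  })
}
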