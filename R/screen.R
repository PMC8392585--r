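#' Screen one dose metric against the toxicity endpoint
#'
#' Two-sample t-test comparing a per-patient dose metric between patients
#' with and without the endpoint. The pooled-variance (Student) test is the
#' default; Welch's unequal-variance form is available. A screen with fewer
#' than two patients in either group, or zero pooled variance, cannot be
#' tested and is rejected as non-convergent.
#'
#' @param values Per-patient metric values (Gy or volume fraction).
#' @param event Per-patient binary endpoint (0/1 or logical).
#' @param metric Name recorded in the result (e.g. `"EUD n=0.05"`).
#' @param var_equal Pooled-variance test if `TRUE` (default), Welch otherwise.
#' @return A one-row tibble: `metric`, `t_statistic`, `p_value`,
#'   `mean_event`, `mean_nonevent`, `n_event`, `n_nonevent`.
#' @export
screen_metric <- function(values, event, metric = "metric", var_equal = TRUE) {
  event <- check_binary_vector(event, "event")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    abort_ntcp("`values` must be finite numeric values without missing entries.",
               "ntcpxero_input_error")
  }
  if (length(values) != length(event)) {
    abort_ntcp("`values` and `event` must have the same length.",
               "ntcpxero_input_error")
  }
  x1 <- values[event == 1]
  x0 <- values[event == 0]
  if (length(x1) < 2L || length(x0) < 2L) {
    abort_ntcp(sprintf("Screen for %s does not converge: fewer than 2 patients in a group.", metric),
               "ntcpxero_screen_error")
  }
  if (stats::var(x1) + stats::var(x0) <= 0) {
    abort_ntcp(sprintf("Screen for %s does not converge: zero variance in both groups.", metric),
               "ntcpxero_screen_error")
  }
  tt <- stats::t.test(x1, x0, var.equal = var_equal)
  tibble::tibble(
    metric = metric,
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    mean_event = mean(x1),
    mean_nonevent = mean(x0),
    n_event = length(x1),
    n_nonevent = length(x0)
  )
}

# Cut-point / point-metric family screened when the EUD scan fails:
# D98%, D2%, Dmean, Dmax and VxGy for x = 30, 35, ..., 70 Gy.
cutpoint_metrics <- function(dvh) {
  dd <- as_cumulative(dvh)
  vx <- function(x) {
    if (x <= min(dd$dose_edges)) return(1)
    if (x >= max(dd$dose_edges)) return(0)
    stats::approx(dd$dose_edges, dd$volume / dd$total_volume, xout = x)$y
  }
  s <- summarize_dvh(dvh)
  out <- c(
    "D98%" = s$d98,
    "D2%" = dose_at_volume(dvh, 0.02),
    "Dmean" = s$mean_dose,
    "Dmax" = s$max_dose
  )
  for (x in seq(30, 70, by = 5)) out[[sprintf("V%dGy", x)]] <- vx(x)
  out
}

#' Screen all candidate dose metrics for one organ
#'
#' Runs the endpoint t-test over the full volume-effect EUD grid
#' (`n` = 0.05 to 1.00) and over the cut-point family (D98%, D2%, Dmean,
#' Dmax, V30Gy-V70Gy in 5 Gy steps) for every patient's DVH of one organ.
#'
#' @param dvhs List of `dvh` objects, one per patient.
#' @param event Binary endpoint, same length.
#' @param var_equal Passed to [screen_metric()].
#' @return A tibble of screen results with a `family` column
#'   (`"eud"` or `"cutpoint"`) and an `n` column for EUD rows; metrics whose
#'   screen does not converge are kept with `NA` statistics.
#' @export
screen_dose_metrics <- function(dvhs, event, var_equal = TRUE) {
  event <- check_binary_vector(event, "event")
  if (length(dvhs) != length(event)) {
    abort_ntcp("`dvhs` and `event` must have the same length.", "ntcpxero_input_error")
  }
  n_grid <- seq(0.05, 1, by = 0.05)
  euds <- vapply(dvhs, function(d) eud_grid(d, n_grid)$eud, numeric(length(n_grid)))
  cuts <- vapply(dvhs, cutpoint_metrics, cutpoint_metrics(dvhs[[1]]))
  screen_row <- function(values, name, family, n = NA_real_) {
    res <- tryCatch(
      screen_metric(values, event, metric = name, var_equal = var_equal),
      ntcpxero_screen_error = function(e) {
        tibble::tibble(metric = name, t_statistic = NA_real_, p_value = NA_real_,
                       mean_event = NA_real_, mean_nonevent = NA_real_,
                       n_event = sum(event == 1), n_nonevent = sum(event == 0))
      }
    )
    dplyr::mutate(res, family = family, n = n, .after = "metric")
  }
  eud_rows <- purrr::map(seq_along(n_grid), function(i) {
    screen_row(euds[i, ], sprintf("EUD n=%.2f", n_grid[i]), "eud", n_grid[i])
  })
  cut_rows <- purrr::map(rownames(cuts), function(nm) {
    screen_row(cuts[nm, ], nm, "cutpoint")
  })
  dplyr::bind_rows(eud_rows, cut_rows)
}

#' Select the best dose metric for one organ
#'
#' Applies the screening rule: the volume-effect parameter whose EUD shows
#' the smallest t-test p-value describes the organ's dose-response best;
#' ties are broken toward larger `n` (the weaker serial assumption). If no
#' EUD screen converges, the cut-point family (D98%, D2%, Dmean, Dmax,
#' VxGy) is screened instead. A selection whose minimum p-value exceeds
#' `alpha` is flagged as non-significant rather than suppressed.
#'
#' @param cohort A cohort tibble with a list-column of DVHs.
#' @param dvh_col Name of the DVH list-column (e.g. `"dvh_oc"`).
#' @param event Binary endpoint vector, or the name of a 0/1 column in
#'   `cohort`.
#' @param alpha Significance flag threshold (default 0.05).
#' @param var_equal Passed to [screen_metric()].
#' @return The full screen tibble with logical columns `selected` and
#'   `significant`; the selected row carries the chosen metric.
#' @export
select_best_metric <- function(cohort, dvh_col, event, alpha = 0.05,
                               var_equal = TRUE) {
  if (is.character(event) && length(event) == 1L) event <- cohort[[event]]
  event <- check_binary_vector(event, "event")
  if (nrow(cohort) < 4L) {
    abort_ntcp("Metric screening needs at least 4 patients.", "ntcpxero_input_error")
  }
  dvhs <- cohort[[dvh_col]]
  if (is.null(dvhs)) {
    abort_ntcp(sprintf("Column `%s` not found in cohort.", dvh_col),
               "ntcpxero_input_error")
  }
  scr <- screen_dose_metrics(dvhs, event, var_equal = var_equal)
  pick_from <- function(fam) {
    cand <- dplyr::filter(scr, .data$family == fam, !is.na(.data$p_value))
    if (!nrow(cand)) return(NA_character_)
    pmin_ <- min(cand$p_value)
    cand <- dplyr::filter(cand, .data$p_value <= pmin_ + 1e-12)
    if (fam == "eud") cand <- dplyr::arrange(cand, dplyr::desc(.data$n))
    cand$metric[1L]
  }
  chosen <- pick_from("eud")
  if (is.na(chosen)) chosen <- pick_from("cutpoint")
  if (is.na(chosen)) {
    abort_ntcp("No dose-metric screen converged for this organ.",
               "ntcpxero_screen_error")
  }
  dplyr::mutate(
    scr,
    selected = .data$metric == chosen,
    significant = .data$selected & !is.na(.data$p_value) & .data$p_value <= alpha
  )
}
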