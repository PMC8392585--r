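#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the proportion of event/non-event
#' pairs in which the event patient has the higher predicted risk, ties
#' counting one half.
#'
#' @param predicted Predicted probabilities (any monotone risk score works).
#' @param observed Binary outcomes.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(predicted, observed) {
  observed <- check_binary_vector(observed)
  if (!is.numeric(predicted) || anyNA(predicted)) {
    abort_ntcp("`predicted` must be numeric without missing values.",
               "ntcpxero_input_error")
  }
  if (length(predicted) != length(observed)) {
    abort_ntcp("`predicted` and `observed` must have the same length.",
               "ntcpxero_input_error")
  }
  n1 <- sum(observed == 1); n0 <- sum(observed == 0)
  if (n1 == 0L || n0 == 0L) {
    abort_ntcp("AUC needs both outcome classes present.", "ntcpxero_input_error")
  }
  r <- rank(predicted, ties.method = "average")
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normal-approximation p-value for the AUC
#'
#' Tests AUC = 0.5 via the large-sample normal approximation to the
#' Mann-Whitney statistic (Hanley-McNeil variance under the null).
#'
#' @inheritParams roc_auc
#' @return Two-sided p-value.
#' @export
roc_auc_p <- function(predicted, observed) {
  observed <- check_binary_vector(observed)
  auc <- roc_auc(predicted, observed)
  n1 <- sum(observed == 1); n0 <- sum(observed == 0)
  se0 <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  2 * stats::pnorm(-abs(auc - 0.5) / se0)
}

#' Calibration slope and calibration-in-the-large
#'
#' Regresses the observed outcome on the logit of the predicted
#' probability: the slope of that logistic regression is the calibration
#' slope (1 = ideal, < 1 = predictions too extreme, typical of
#' overfitting); the intercept of a second logistic regression with the
#' logit prediction entered as a fixed offset is the
#' calibration-in-the-large (0 = ideal; > 0 = observed risk exceeds
#' predicted). The probability-scale difference `mean(observed) -
#' mean(predicted)` is also reported for transparency.
#'
#' @param predicted Predicted probabilities strictly inside (0, 1).
#' @param observed Binary outcomes.
#' @return A one-row tibble: `slope`, `slope_se`, `in_the_large`,
#'   `in_the_large_se`, `in_the_large_prob`.
#' @export
calibration <- function(predicted, observed) {
  observed <- check_binary_vector(observed)
  check_prob_vector(predicted)
  if (length(predicted) != length(observed)) {
    abort_ntcp("`predicted` and `observed` must have the same length.",
               "ntcpxero_input_error")
  }
  if (stats::sd(predicted) == 0) {
    abort_ntcp("Calibration slope is undefined for constant predictions.",
               "ntcpxero_input_error")
  }
  lp <- stats::qlogis(predicted)
  slope_fit <- stats::glm(observed ~ lp, family = stats::binomial())
  citl_fit <- stats::glm(observed ~ 1 + offset(lp), family = stats::binomial())
  tibble::tibble(
    slope = unname(stats::coef(slope_fit)[2]),
    slope_se = sqrt(stats::vcov(slope_fit)[2, 2]),
    in_the_large = unname(stats::coef(citl_fit)[1]),
    in_the_large_se = sqrt(stats::vcov(citl_fit)[1, 1]),
    in_the_large_prob = mean(observed) - mean(predicted)
  )
}

# Equal-count risk groups: patients ranked by predicted probability, split
# into `groups` groups; remainder patients go to the leading (lowest-risk)
# groups; tied predictions stay in the group of their first occurrence.
risk_groups <- function(predicted, groups) {
  n <- length(predicted)
  ord <- order(predicted)
  base <- n %/% groups
  rem <- n %% groups
  sizes <- rep(base, groups) + c(rep(1L, rem), rep(0L, groups - rem))
  g <- rep(seq_len(groups), times = sizes)
  grp <- integer(n)
  grp[ord] <- g
  # keep ties together: every duplicate of a predicted value inherits the
  # group of the first (lowest-group) occurrence
  for (v in unique(predicted[duplicated(predicted)])) {
    idx <- which(predicted == v)
    grp[idx] <- min(grp[idx])
  }
  grp
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Patients are ranked by predicted probability and split into equal-size
#' risk groups (default six); the statistic sums `(O - E)^2 / E` over both
#' outcome cells of every group and is referred to a chi-squared
#' distribution with `groups - 2` degrees of freedom.
#'
#' @param predicted Predicted probabilities.
#' @param observed Binary outcomes.
#' @param groups Number of risk groups (default 6).
#' @return A list with `chi2`, `p`, `groups`, and the per-group `table`
#'   (n, mean predicted, observed and expected events).
#' @export
hosmer_lemeshow <- function(predicted, observed, groups = 6) {
  observed <- check_binary_vector(observed)
  check_prob_vector(predicted, open = FALSE)
  if (length(predicted) < groups) {
    abort_ntcp("Fewer patients than requested risk groups.", "ntcpxero_input_error")
  }
  grp <- risk_groups(predicted, groups)
  tab <- tibble::tibble(group = grp, p = predicted, y = observed) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted = mean(.data$p),
      observed_events = sum(.data$y),
      expected_events = sum(.data$p),
      .groups = "drop"
    )
  e1 <- tab$expected_events
  e0 <- tab$n - tab$expected_events
  if (any(e1 <= 0) || any(e0 <= 0)) {
    abort_ntcp("A Hosmer-Lemeshow expected cell is zero; try fewer groups.",
               "ntcpxero_input_error")
  }
  o1 <- tab$observed_events
  o0 <- tab$n - tab$observed_events
  chi2 <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  list(
    chi2 = chi2,
    p = stats::pchisq(chi2, df = max(length(unique(tab$group)) - 2, 1),
                      lower.tail = FALSE),
    groups = length(unique(tab$group)),
    table = tab
  )
}

#' Predictive values at a probability cutoff
#'
#' Calls a patient positive when the predicted probability is at least
#' `cutoff` and cross-tabulates calls against outcomes. A predictive value
#' whose denominator is empty (no positive or no negative calls) is
#' reported as `NA`, not 0.
#'
#' @param predicted Predicted probabilities.
#' @param observed Binary outcomes.
#' @param cutoff Positive-call threshold (default 0.65).
#' @return A one-row tibble: `cutoff`, `tp`, `fp`, `tn`, `fn`, `ppv`,
#'   `npv`, `sensitivity`, `specificity`.
#' @export
classification_at_cutoff <- function(predicted, observed, cutoff = 0.65) {
  observed <- check_binary_vector(observed)
  if (length(predicted) != length(observed)) {
    abort_ntcp("`predicted` and `observed` must have the same length.",
               "ntcpxero_input_error")
  }
  call_pos <- predicted >= cutoff
  tp <- sum(call_pos & observed == 1)
  fp <- sum(call_pos & observed == 0)
  tn <- sum(!call_pos & observed == 0)
  fn <- sum(!call_pos & observed == 1)
  tibble::tibble(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Flag patients with large prediction residuals
#'
#' The residual is `observed (0/1) - predicted`. Patients with residual at
#' or above the threshold experienced toxicity despite a low prediction
#' (candidate radiosensitive); residuals at or below minus the threshold
#' mark patients spared despite a high prediction (candidate
#' radioresistant).
#'
#' @param predicted Predicted probabilities.
#' @param observed Binary outcomes.
#' @param threshold Absolute residual flag level (default 0.7).
#' @param patient_id Optional ids; defaults to row numbers.
#' @return A tibble of all patients with `residual` and `flag`
#'   (`"radiosensitive"`, `"radioresistant"` or `NA`).
#' @export
residual_flags <- function(predicted, observed, threshold = 0.7,
                           patient_id = NULL) {
  observed <- check_binary_vector(observed)
  res <- observed - predicted
  tibble::tibble(
    patient_id = patient_id %||% as.character(seq_along(res)),
    observed = observed,
    predicted = predicted,
    residual = res,
    flag = dplyr::case_when(
      res >= threshold ~ "radiosensitive",
      res <= -threshold ~ "radioresistant",
      TRUE ~ NA_character_
    )
  )
}

#' Externally validate a frozen NTCP model on a new cohort
#'
#' Computes predicted probabilities from the frozen coefficients (never
#' refitting them) and evaluates discrimination (AUC with
#' normal-approximation p-value), calibration (slope,
#' calibration-in-the-large, Hosmer-Lemeshow), classification at the
#' probability cutoff, and residual flags. Optionally also refits per-term
#' odds ratios on the validation cohort for effect-size comparison; the
#' frozen model itself is untouched.
#'
#' @param model An `ntcp_model` (or a path to a model JSON file).
#' @param cohort A tibble holding every model term column plus the binary
#'   endpoint.
#' @param event Endpoint column name (default `"event"`) or a 0/1 vector.
#' @param cohort_label Label stored in the report.
#' @param cutoff Classification cutoff (default 0.65).
#' @param hl_groups Hosmer-Lemeshow groups (default 6).
#' @param residual_threshold Residual flag level (default 0.7).
#' @param refit_effects Also report the cohort's own refitted odds ratios
#'   (default `TRUE`; skipped automatically if the refit fails).
#' @return An object of class `ntcp_validation`.
#' @export
external_validate <- function(model, cohort, event = "event",
                              cohort_label = "validation",
                              cutoff = 0.65, hl_groups = 6,
                              residual_threshold = 0.7,
                              refit_effects = TRUE) {
  if (is.character(model) && length(model) == 1L) model <- read_ntcp_model(model)
  if (!inherits(model, "ntcp_model")) {
    abort_ntcp("`model` must be an <ntcp_model> or a model JSON path.",
               "ntcpxero_model_error")
  }
  observed <- if (is.character(event) && length(event) == 1L) {
    if (!event %in% names(cohort)) {
      abort_ntcp(sprintf("Endpoint column `%s` not found in cohort.", event),
                 "ntcpxero_input_error")
    }
    cohort[[event]]
  } else {
    event
  }
  observed <- check_binary_vector(observed)
  predicted <- predict_ntcp(model, cohort)
  cal <- calibration(predicted, observed)
  hl <- hosmer_lemeshow(predicted, observed, groups = hl_groups)
  cls <- classification_at_cutoff(predicted, observed, cutoff = cutoff)
  res <- residual_flags(predicted, observed, threshold = residual_threshold,
                        patient_id = cohort[["patient_id"]])
  refit <- NULL
  if (refit_effects) {
    refit <- tryCatch({
      feats <- dplyr::select(cohort, dplyr::all_of(model$terms$term))
      odds_ratios(fit_ntcp(feats, observed))
    }, error = function(e) NULL)
  }
  structure(
    list(
      cohort_label = cohort_label,
      n = length(observed), events = sum(observed),
      predicted = predicted, observed = observed,
      auc = roc_auc(predicted, observed),
      auc_p = roc_auc_p(predicted, observed),
      calibration = cal,
      hl = hl,
      classification = cls,
      residuals = res,
      refit_odds_ratios = refit,
      model = model
    ),
    class = "ntcp_validation"
  )
}

#' @export
print.ntcp_validation <- function(x, ...) {
  cat(sprintf("<ntcp_validation> %s: n = %d, events = %d (%.1f%%)\n",
              x$cohort_label, x$n, x$events, 100 * x$events / x$n))
  cat(sprintf("  AUC %.3f (p = %.3g)\n", x$auc, x$auc_p))
  cat(sprintf("  calibration slope %.3f, in-the-large %.3f\n",
              x$calibration$slope, x$calibration$in_the_large))
  cat(sprintf("  Hosmer-Lemeshow chi2 %.2f (p = %.3f, %d groups)\n",
              x$hl$chi2, x$hl$p, x$hl$groups))
  cat(sprintf("  PPV %.3f / NPV %.3f at cutoff %.2f\n",
              x$classification$ppv, x$classification$npv,
              x$classification$cutoff))
  flagged <- sum(!is.na(x$residuals$flag))
  cat(sprintf("  %d patient(s) with |residual| >= threshold\n", flagged))
  invisible(x)
}
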