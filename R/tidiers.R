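#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an NTCP model
#'
#' @param x An `ntcp_model`.
#' @param exponentiate Report odds ratios and exponentiated confidence
#'   bounds instead of log-odds coefficients.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per term (intercept included) and columns
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.ntcp_model <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = c("(Intercept)", x$terms$term),
    estimate = c(x$intercept, x$terms$estimate),
    std.error = c(x$fit_meta$intercept_se %||% NA_real_, x$terms$std_error)
  )
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  out$conf.low <- out$estimate - z * out$std.error
  out$conf.high <- out$estimate + z * out$std.error
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' @export
glance.ntcp_model <- function(x, ...) {
  tibble::tibble(
    n = x$fit_meta$n %||% NA_integer_,
    events = x$fit_meta$events %||% NA_integer_,
    logLik = x$fit_meta$logLik %||% NA_real_,
    AIC = x$fit_meta$aic %||% NA_real_,
    n_terms = nrow(x$terms)
  )
}

#' @export
tidy.ntcp_fit <- function(x, ...) tidy(x$model, ...)

#' @export
glance.ntcp_fit <- function(x, ...) {
  m <- x$bootstrap$metrics
  tibble::tibble(
    n = x$model$fit_meta$n,
    events = x$model$fit_meta$events,
    n_terms = nrow(x$model$terms),
    auc_apparent = m$apparent[m$metric == "auc"],
    auc_corrected = m$corrected[m$metric == "auc"],
    slope_corrected = m$corrected[m$metric == "slope"],
    citl_corrected = m$corrected[m$metric == "in_the_large"],
    hl_chi2 = x$apparent$hl$chi2,
    hl_p = x$apparent$hl$p,
    B = x$bootstrap$B
  )
}

#' @export
tidy.ntcp_validation <- function(x, ...) {
  tibble::tribble(
    ~metric, ~value,
    "auc", x$auc,
    "auc_p", x$auc_p,
    "calibration_slope", x$calibration$slope,
    "calibration_in_the_large", x$calibration$in_the_large,
    "calibration_in_the_large_prob", x$calibration$in_the_large_prob,
    "hl_chi2", x$hl$chi2,
    "hl_p", x$hl$p,
    "ppv", x$classification$ppv,
    "npv", x$classification$npv,
    "event_rate", x$events / x$n
  )
}

#' @export
glance.ntcp_validation <- function(x, ...) {
  tibble::tibble(
    cohort = x$cohort_label, n = x$n, events = x$events,
    auc = x$auc, auc_p = x$auc_p,
    calibration_slope = x$calibration$slope,
    calibration_in_the_large = x$calibration$in_the_large,
    hl_chi2 = x$hl$chi2, hl_p = x$hl$p,
    ppv = x$classification$ppv, npv = x$classification$npv,
    cutoff = x$classification$cutoff,
    n_radiosensitive = sum(x$residuals$flag %in% "radiosensitive"),
    n_radioresistant = sum(x$residuals$flag %in% "radioresistant")
  )
}

#' @export
augment.ntcp_validation <- function(x, ...) {
  dplyr::mutate(x$residuals, cohort = x$cohort_label)
}
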