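# Publication-style figures: DVH curves, calibration and ROC plots,
# dose-response curves and the nomogram.

#' @export
autoplot.dvh <- function(object, ...) {
  cum <- as_cumulative(object)
  df <- tibble::tibble(dose = cum$dose_edges,
                       volume = 100 * cum$volume / cum$total_volume)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$volume)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = sprintf("Cumulative DVH: %s (%.1f cc)",
                                  object$organ, object$total_volume)) +
    ggplot2::theme_minimal()
}

#' Calibration plot with risk-group points
#'
#' Observed event rate against mean predicted probability in equal-size
#' risk groups, with normal-approximation error bars on the observed
#' frequencies, the identity (perfect calibration) line and the fitted
#' logistic calibration line.
#'
#' @param predicted Predicted probabilities.
#' @param observed Binary outcomes.
#' @param groups Number of risk groups (default 6).
#' @param label Plot title label.
#' @return A ggplot object.
#' @export
plot_calibration <- function(predicted, observed, groups = 6, label = NULL) {
  observed <- check_binary_vector(observed)
  grp <- risk_groups(predicted, groups)
  df <- tibble::tibble(grp = grp, p = predicted, y = observed) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(n = dplyr::n(), pred = mean(.data$p), obs = mean(.data$y),
                     .groups = "drop") |>
    dplyr::mutate(se = sqrt(pmax(.data$obs * (1 - .data$obs), 1e-10) / .data$n),
                  lo = pmax(0, .data$obs - 1.959964 * .data$se),
                  hi = pmin(1, .data$obs + 1.959964 * .data$se))
  cal <- calibration(predicted, observed)
  curve_df <- tibble::tibble(p = seq(min(predicted), max(predicted), length.out = 100))
  a <- unname(stats::coef(stats::glm(observed ~ stats::qlogis(predicted),
                                     family = stats::binomial())))
  curve_df$fit <- stats::plogis(a[1] + a[2] * stats::qlogis(curve_df$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = .data$p, y = .data$fit),
                       colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.01) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Mean predicted probability", y = "Observed event rate",
      title = label,
      subtitle = sprintf("slope %.2f, in-the-large %.2f",
                         cal$slope, cal$in_the_large)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve
#'
#' @param predicted Predicted probabilities.
#' @param observed Binary outcomes.
#' @param label Plot title label.
#' @return A ggplot object.
#' @export
plot_roc <- function(predicted, observed, label = NULL) {
  observed <- check_binary_vector(observed)
  thr <- c(Inf, sort(unique(predicted), decreasing = TRUE), -Inf)
  df <- purrr::map_dfr(thr, function(t) {
    pos <- predicted >= t
    tibble::tibble(
      tpr = sum(pos & observed == 1) / sum(observed == 1),
      fpr = sum(pos & observed == 0) / sum(observed == 0)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", title = label,
                  subtitle = sprintf("AUC %.3f", roc_auc(predicted, observed))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ntcp_validation <- function(object, type = c("calibration", "roc"), ...) {
  type <- match.arg(type)
  if (type == "calibration") {
    plot_calibration(object$predicted, object$observed,
                     label = object$cohort_label)
  } else {
    plot_roc(object$predicted, object$observed, label = object$cohort_label)
  }
}

#' Dose-response curves from an NTCP model
#'
#' Predicted complication probability as a function of one dose term, with
#' the remaining covariates held at chosen values; several covariate
#' profiles can be overlaid (e.g. oral-cavity EUD levels by smoking
#' status).
#'
#' @param model An `ntcp_model`.
#' @param dose_term Model term swept along the x axis.
#' @param dose_range `c(min, max)` sweep range in Gy.
#' @param profiles A data frame of covariate settings (one curve per row;
#'   columns for every remaining model term, plus an optional `label`).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(model, dose_term, dose_range, profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (!"label" %in% names(profiles)) {
    profiles$label <- paste("profile", seq_len(nrow(profiles)))
  }
  xs <- seq(dose_range[1], dose_range[2], length.out = 200)
  df <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    cov <- profiles[rep(i, length(xs)), setdiff(names(profiles), "label"),
                    drop = FALSE]
    cov[[dose_term]] <- xs
    tibble::tibble(dose = xs, p = predict_ntcp(model, cov),
                   label = profiles$label[i])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$p,
                                   colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("%s (Gy)", dose_term),
                  y = "Probability of grade ≥ 2 toxicity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ntcp_nomogram <- function(object, ticks = 5, ...) {
  ax <- object$axes
  rows <- purrr::map_dfr(seq_len(nrow(ax)), function(i) {
    vals <- seq(ax$x_min[i], ax$x_max[i], length.out = ticks)
    tibble::tibble(
      term = ax$term[i],
      value = vals,
      points = ax$points_per_unit[i] * (vals - ax$x_min[i]),
      y = nrow(ax) - i + 1
    )
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$points, y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$term)) +
    ggplot2::geom_point(shape = 3) +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_y_continuous(
      breaks = seq_len(nrow(ax)),
      labels = rev(ax$term),
      limits = c(0.5, nrow(ax) + 0.5)
    ) +
    ggplot2::labs(x = "Points", y = NULL, title = "Nomogram") +
    ggplot2::theme_minimal()
}
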