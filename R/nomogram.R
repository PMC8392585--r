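#' Build a nomogram from a fitted NTCP model
#'
#' Converts the logistic model to the usual points scale: for term *i* with
#' coefficient \eqn{\beta_i} over value range \eqn{[x_{min}, x_{max}]},
#' \deqn{points_i(x) = 100 \, \beta_i (x - x_{min}) / \max_j [\beta_j (x_{j,max} - x_{j,min})]}
#' so the term with the largest coefficient-times-range spans exactly
#' 0-100 points, and total points map back to predicted probability through
#' the linear predictor. Point allocations are invariant to rescaling all
#' coefficients by a common factor (only the probability axis changes).
#'
#' @param model An `ntcp_model`.
#' @param ranges Named list of `c(min, max)` value ranges, one per model
#'   term; binary terms default to `c(0, 1)` when omitted.
#' @return An object of class `ntcp_nomogram`: per-term point tables and a
#'   total-points-to-probability mapping.
#' @export
build_nomogram <- function(model, ranges = list()) {
  if (!inherits(model, "ntcp_model")) {
    abort_ntcp("`model` must be an <ntcp_model>.", "ntcpxero_model_error")
  }
  terms <- model$terms
  full_ranges <- purrr::map(seq_len(nrow(terms)), function(i) {
    r <- ranges[[terms$term[i]]] %||% c(0, 1)
    r <- as.numeric(r)
    if (length(r) != 2L || anyNA(r) || diff(r) <= 0) {
      abort_ntcp(sprintf("Range for term `%s` must be c(min, max) with max > min.",
                         terms$term[i]),
                 "ntcpxero_model_error")
    }
    r
  })
  names(full_ranges) <- terms$term
  spans <- purrr::map2_dbl(terms$estimate, full_ranges, ~ abs(.x * diff(.y)))
  scale <- max(spans)
  if (scale <= 0) {
    abort_ntcp("All terms have zero coefficient-times-range; no nomogram possible.",
               "ntcpxero_model_error")
  }
  axes <- purrr::map2_dfr(seq_len(nrow(terms)), full_ranges, function(i, r) {
    tibble::tibble(
      term = terms$term[i],
      x_min = r[1], x_max = r[2],
      estimate = terms$estimate[i],
      points_per_unit = 100 * terms$estimate[i] / scale,
      max_points = 100 * terms$estimate[i] * diff(r) / scale
    )
  })
  # probability at total points T: lp = intercept + sum(beta_i x_min_i) + T*scale/100
  base_lp <- model$intercept +
    sum(terms$estimate * purrr::map_dbl(full_ranges, 1))
  structure(
    list(axes = axes, scale = scale, base_lp = base_lp, model = model),
    class = "ntcp_nomogram"
  )
}

#' @export
print.ntcp_nomogram <- function(x, ...) {
  cat("<ntcp_nomogram>\n")
  print(x$axes)
  cat(sprintf("total points -> p via lp = %.4f + points * %.6f\n",
              x$base_lp, x$scale / 100))
  invisible(x)
}

#' Score covariates on the nomogram points scale
#'
#' @param nomogram An `ntcp_nomogram`.
#' @param covariates Data frame (or named list for one patient) with every
#'   model term.
#' @param round_points Round each term's points to this many decimals
#'   before totalling (`NULL`, the default, keeps exact points; `0`
#'   emulates reading integer points off the printed scale).
#' @return A tibble with per-term points, `total_points` and the implied
#'   `probability`.
#' @export
nomogram_points <- function(nomogram, covariates, round_points = NULL) {
  if (!inherits(nomogram, "ntcp_nomogram")) {
    abort_ntcp("`nomogram` must be an <ntcp_nomogram>.", "ntcpxero_model_error")
  }
  if (!is.data.frame(covariates)) covariates <- tibble::as_tibble(as.list(covariates))
  missing <- setdiff(nomogram$axes$term, names(covariates))
  if (length(missing)) {
    abort_ntcp(sprintf("Covariate(s) missing for nomogram axis(es): %s.",
                       paste(missing, collapse = ", ")),
               "ntcpxero_model_error")
  }
  pts <- purrr::map(seq_len(nrow(nomogram$axes)), function(i) {
    ax <- nomogram$axes[i, ]
    p <- ax$points_per_unit * (as.numeric(covariates[[ax$term]]) - ax$x_min)
    if (!is.null(round_points)) p <- round(p, round_points)
    p
  })
  total <- Reduce(`+`, pts)
  out <- tibble::as_tibble(stats::setNames(pts, nomogram$axes$term))
  out$total_points <- total
  out$probability <- nomogram_probability(nomogram, total)
  out
}

#' Convert total nomogram points to predicted probability
#'
#' @param nomogram An `ntcp_nomogram`.
#' @param total_points Total points value(s).
#' @return Probability vector.
#' @export
nomogram_probability <- function(nomogram, total_points) {
  stats::plogis(nomogram$base_lp + total_points * nomogram$scale / 100)
}
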