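#' Construct an NTCP model object
#'
#' A frozen multivariable logistic NTCP model: an intercept plus per-term
#' log-odds coefficients with standard errors. Such an object can come from
#' [fit_ntcp()] or be written down from published coefficients and used for
#' frozen-coefficient external validation.
#'
#' @param intercept Model constant on the logit scale.
#' @param terms A data frame with columns `term`, `estimate`, `std_error`
#'   and optionally `unit`.
#' @param eud_params Named list mapping organ labels to the DVH reduction
#'   used for their dose term (e.g. `list(cPG = "D98%", OC = "EUD n=0.05")`).
#' @param fit_meta Optional list of fit metadata (`n`, `events`, `logLik`).
#' @return An object of class `ntcp_model`.
#' @export
ntcp_model <- function(intercept, terms, eud_params = list(), fit_meta = list()) {
  terms <- tibble::as_tibble(terms)
  needed <- c("term", "estimate")
  if (!all(needed %in% names(terms))) {
    abort_ntcp("`terms` must have columns `term` and `estimate`.",
               "ntcpxero_model_error")
  }
  if (!"std_error" %in% names(terms)) terms$std_error <- NA_real_
  if (!"unit" %in% names(terms)) terms$unit <- NA_character_
  if (anyNA(terms$estimate) || any(!is.finite(terms$estimate))) {
    abort_ntcp("All term coefficients must be finite.", "ntcpxero_model_error")
  }
  if (any(!is.na(terms$std_error) & terms$std_error <= 0)) {
    abort_ntcp("Standard errors must be positive where present.",
               "ntcpxero_model_error")
  }
  structure(
    list(intercept = as.numeric(intercept),
         terms = terms[, c("term", "estimate", "std_error", "unit")],
         eud_params = eud_params,
         fit_meta = fit_meta),
    class = "ntcp_model"
  )
}

#' @export
print.ntcp_model <- function(x, ...) {
  cat(sprintf("<ntcp_model> logistic, %d term(s), intercept %.3f\n",
              nrow(x$terms), x$intercept))
  print(x$terms)
  invisible(x)
}

#' Reference multivariable model for grade >= 2 acute salivary dysfunction
#'
#' The package's built-in 4-variable logistic NTCP model for grade >= 2
#' acute salivary dysfunction during radiotherapy for nasopharyngeal
#' cancer (development cohort of 132 patients, 90 events): near-minimum
#' dose (D98%) to the combined parotid glands, oral-cavity EUD at
#' `n = 0.05`, age in 5-year units, and smoking history. It is the default
#' "true" model of the synthetic cohort generator and the frozen model of
#' the worked examples.
#'
#' @return An `ntcp_model`.
#' @examples
#' m <- reference_model()
#' odds_ratios(m)
#' @export
reference_model <- function() {
  ntcp_model(
    intercept = -7.233,
    terms = tibble::tibble(
      term = c("cpg_d98", "oc_eud", "age_5y", "smoking"),
      estimate = c(0.038, 0.103, 0.079, 0.318),
      std_error = c(0.023, 0.043, 0.074, 0.540),
      unit = c("Gy", "Gy", "5-year interval", "yes vs no")
    ),
    eud_params = list(cPG = "D98%", OC = "EUD n=0.05"),
    fit_meta = list(n = 132, events = 90,
                    intercept_se = 2.620)
  )
}

#' LASSO predictor selection with cross-validated deviance
#'
#' Screens a candidate feature matrix with an L1-penalized logistic model:
#' the penalty is chosen by `folds`-fold cross-validation of the binomial
#' deviance, and the features with non-zero coefficients at that penalty
#' are returned. Features are standardized internally before penalization;
#' zero-variance features are dropped with a warning. The fold assignment
#' is fixed by `seed` so selection is reproducible.
#'
#' @param features A data frame or matrix of numeric candidate features.
#' @param outcome Binary outcome vector.
#' @param folds Number of cross-validation folds (default 5).
#' @param rule `"min"` for the deviance-minimising penalty (default) or
#'   `"1se"` for the sparser one-standard-error choice.
#' @param seed Optional integer fixing the fold assignment.
#' @param nlambda Length of the penalty path (default 100).
#' @return Character vector of selected feature names (possibly empty).
#' @export
lasso_select <- function(features, outcome, folds = 5, rule = c("min", "1se"),
                         seed = NULL, nlambda = 100) {
  rule <- match.arg(rule)
  outcome <- check_binary_vector(outcome, "outcome")
  x <- as.matrix(features)
  if (!is.numeric(x) || anyNA(x)) {
    abort_ntcp("`features` must be numeric without missing values.",
               "ntcpxero_input_error")
  }
  if (length(unique(outcome)) < 2L) {
    abort_ntcp("Outcome must contain both classes for LASSO selection.",
               "ntcpxero_model_error")
  }
  if (nrow(x) < 2L * folds) {
    abort_ntcp("Need at least 2 patients per cross-validation fold.",
               "ntcpxero_input_error")
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(sprintf("Dropping zero-variance feature(s): %s.",
                        paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) == 0L) return(character(0))
  if (ncol(x) == 1L) {
    # cv.glmnet requires >= 2 columns; pad with a noise-free constant copy
    x <- cbind(x, `..pad..` = 0)
  }
  cv <- with_seed(seed, glmnet::cv.glmnet(
    x, outcome, family = "binomial", nfolds = folds,
    type.measure = "deviance", standardize = TRUE, nlambda = nlambda
  ))
  lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- stats::coef(cv, s = lambda)[-1, 1]
  sel <- names(beta)[beta != 0]
  setdiff(sel, "..pad..")
}

#' Fit the multivariable logistic NTCP model
#'
#' Unpenalized maximum-likelihood logistic regression of the binary
#' endpoint on the selected features (the final model after LASSO
#' screening, so Wald standard errors are valid). Perfect separation and
#' non-convergence are detected and reported as errors rather than
#' returning unstable coefficients.
#'
#' @param features Data frame of numeric model features (the design matrix
#'   without intercept).
#' @param outcome Binary endpoint vector.
#' @param eud_params Optional organ-to-reduction map stored in the model.
#' @param units Optional named character vector of term units.
#' @param max_abs_coef Coefficient magnitude beyond which the fit is
#'   declared separated (default 15 on the logit scale).
#' @return An `ntcp_model` with coefficients, standard errors and fit
#'   metadata (`n`, `events`, `logLik`, `aic`).
#' @export
fit_ntcp <- function(features, outcome, eud_params = list(), units = NULL,
                     max_abs_coef = 15) {
  outcome <- check_binary_vector(outcome, "outcome")
  features <- tibble::as_tibble(features)
  if (nrow(features) != length(outcome)) {
    abort_ntcp("`features` and `outcome` must have the same length.",
               "ntcpxero_input_error")
  }
  dat <- dplyr::mutate(features, .outcome = outcome)
  fml <- stats::as.formula(paste(
    ".outcome ~",
    if (ncol(features)) paste(sprintf("`%s`", names(features)), collapse = " + ") else "1"
  ))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    abort_ntcp("Logistic fit did not converge within the iteration cap.",
               "ntcpxero_model_error")
  }
  cf <- stats::coef(fit)
  slopes <- cf[-1]
  if (length(slopes) && any(abs(slopes) > max_abs_coef)) {
    worst <- names(slopes)[which.max(abs(slopes))]
    abort_ntcp(sprintf("Perfect separation detected (runaway coefficient for %s).",
                       gsub("`", "", worst)),
               "ntcpxero_model_error")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  term_names <- gsub("`", "", names(cf)[-1])
  units <- units %||% character(0)
  ntcp_model(
    intercept = unname(cf[1]),
    terms = tibble::tibble(
      term = term_names,
      estimate = unname(cf[-1]),
      std_error = unname(se[-1]),
      unit = ifelse(term_names %in% names(units), units[term_names], NA_character_)
    ),
    eud_params = eud_params,
    fit_meta = list(
      n = length(outcome), events = sum(outcome),
      logLik = as.numeric(stats::logLik(fit)), aic = stats::AIC(fit),
      intercept_se = unname(se[1])
    )
  )
}

#' Predict complication probability from an NTCP model
#'
#' Evaluates `p = 1 / (1 + exp(-(intercept + sum(beta * x))))` for each
#' patient. Covariates must be supplied in model units (Gy for dose terms,
#' 5-year units for `age_5y`, 0/1 indicators); an `age_5y` column whose
#' values look like raw years (> 25 units) triggers a warning.
#'
#' @param model An `ntcp_model`.
#' @param covariates A data frame (or named list/vector for one patient)
#'   holding every model term.
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' predict_ntcp(reference_model(),
#'              list(cpg_d98 = 25.5, oc_eud = 60, age_5y = 10, smoking = 0))
#' @export
predict_ntcp <- function(model, covariates) {
  if (!inherits(model, "ntcp_model")) {
    abort_ntcp("`model` must be an <ntcp_model>.", "ntcpxero_model_error")
  }
  if (!is.data.frame(covariates)) covariates <- tibble::as_tibble(as.list(covariates))
  missing <- setdiff(model$terms$term, names(covariates))
  if (length(missing)) {
    abort_ntcp(sprintf("Covariate(s) missing for model term(s): %s.",
                       paste(missing, collapse = ", ")),
               "ntcpxero_model_error")
  }
  if ("age_5y" %in% model$terms$term &&
      any(covariates[["age_5y"]] > 25, na.rm = TRUE)) {
    rlang::warn("`age_5y` exceeds 25 units; values look like raw years rather than 5-year units.")
  }
  lp <- linear_predictor(model, covariates)
  stats::plogis(lp)
}

linear_predictor <- function(model, covariates) {
  lp <- rep(model$intercept, nrow(covariates))
  for (i in seq_len(nrow(model$terms))) {
    x <- covariates[[model$terms$term[i]]]
    if (anyNA(x)) {
      abort_ntcp(sprintf("Missing values in covariate `%s`.", model$terms$term[i]),
                 "ntcpxero_model_error")
    }
    lp <- lp + model$terms$estimate[i] * as.numeric(x)
  }
  lp
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(beta)`, `CI = exp(beta +/- z * SE)` per term.
#'
#' @param model An `ntcp_model` with standard errors.
#' @param z Normal quantile for the interval (default 1.959964, a 95% CI).
#' @param digits Optional rounding for reporting; `NULL` (default) leaves
#'   values unrounded.
#' @return A tibble with `term`, `or`, `ci_low`, `ci_high`.
#' @export
odds_ratios <- function(model, z = 1.959964, digits = NULL) {
  if (!inherits(model, "ntcp_model")) {
    abort_ntcp("`model` must be an <ntcp_model>.", "ntcpxero_model_error")
  }
  out <- tibble::tibble(
    term = model$terms$term,
    or = exp(model$terms$estimate),
    ci_low = exp(model$terms$estimate - z * model$terms$std_error),
    ci_high = exp(model$terms$estimate + z * model$terms$std_error)
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(c("or", "ci_low", "ci_high"),
                                            ~ round(.x, digits)))
  }
  out
}

#' Write / read a frozen NTCP model as JSON
#'
#' The JSON file carries the intercept, per-term coefficients with standard
#' errors and units, the organ-to-reduction map, fit metadata and
#' provenance (package version plus any seed recorded by the caller).
#' External validation reads exactly this file and never refits it.
#'
#' @param model An `ntcp_model`.
#' @param path Output (or input) JSON path.
#' @param seed Optional seed recorded in the provenance block.
#' @return `write_ntcp_model()` returns `path` invisibly;
#'   `read_ntcp_model()` returns the `ntcp_model`.
#' @export
write_ntcp_model <- function(model, path, seed = NULL) {
  if (!inherits(model, "ntcp_model")) {
    abort_ntcp("`model` must be an <ntcp_model>.", "ntcpxero_model_error")
  }
  payload <- list(
    intercept = model$intercept,
    terms = model$terms,
    eud_params = model$eud_params,
    fit_meta = model$fit_meta,
    provenance = list(
      package = "ntcpxero",
      version = as.character(utils::packageVersion("ntcpxero")),
      seed = seed
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ntcp_model
#' @export
read_ntcp_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ntcp_model(
    intercept = payload$intercept,
    terms = tibble::as_tibble(payload$terms),
    eud_params = as.list(payload$eud_params),
    fit_meta = as.list(payload$fit_meta)
  )
}
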