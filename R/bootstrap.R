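#' Bootstrap optimism correction (internal validation)
#'
#' Harrell's procedure: the full modelling recipe is repeated on each
#' bootstrap resample; each resampled model is evaluated both on its own
#' bootstrap sample (apparent performance) and on the original cohort
#' (test performance), and the average difference is the optimism, which
#' is subtracted from the original model's apparent performance. Repeating
#' the *whole* recipe — variable selection included — inside the loop is
#' the default, since selection itself contributes optimism; a fit-only
#' recipe is available.
#'
#' Resamples in which the outcome is a single class, or the refit fails,
#' are skipped and counted; more than 10% skips aborts the procedure.
#'
#' @param features Data frame of candidate (full recipe) or selected
#'   (fit-only) numeric features.
#' @param outcome Binary endpoint vector.
#' @param B Number of bootstrap resamples (default 1000). `B = 0` returns
#'   apparent performance unchanged.
#' @param recipe `"full"` (LASSO selection then refit, default) or
#'   `"refit"` (logistic refit of all supplied features).
#' @param seed Integer seed making the whole procedure reproducible.
#' @param folds,rule Passed to [lasso_select()] for the full recipe.
#' @param force_in Feature names exempted from selection and always
#'   refitted by the full recipe (kept in step with the development call).
#' @param max_skip_frac Maximum tolerated skipped-resample fraction.
#' @param min_cell Sparse-cell guard for the full recipe: binary candidate
#'   features need at least this many patients in every outcome-by-level
#'   cell of the (re)sample to enter selection (default 5; rare flags with
#'   near-empty cells cause quasi-separation rather than information).
#' @return A list with tibble `metrics` (per-metric apparent, optimism,
#'   corrected for AUC, calibration slope and calibration-in-the-large),
#'   counts `B`, `skipped`, and the original-fit `model`.
#' @export
bootstrap_optimism <- function(features, outcome, B = 1000,
                               recipe = c("full", "refit"), seed = NULL,
                               folds = 5, rule = "min",
                               max_skip_frac = 0.1, min_cell = 5,
                               force_in = NULL) {
  recipe <- match.arg(recipe)
  outcome <- check_binary_vector(outcome, "outcome")
  features <- tibble::as_tibble(features)
  n <- length(outcome)

  fit_recipe <- function(feats, y, sub_seed) {
    if (recipe == "full") {
      feats <- feats[, union(filter_sparse_features(feats, y, min_cell),
                             intersect(force_in, names(feats))), drop = FALSE]
      sel <- union(
        suppressWarnings(
          lasso_select(feats, y, folds = folds, rule = rule, seed = sub_seed)
        ),
        intersect(force_in, names(feats))
      )
      if (!length(sel)) return(fit_ntcp(feats[, 0], y))
      fit_ntcp(dplyr::select(feats, dplyr::all_of(sel)), y)
    } else {
      fit_ntcp(feats, y)
    }
  }

  eval_metrics <- function(model, feats, y) {
    p <- predict_ntcp(model, feats)
    if (stats::sd(p) == 0) {
      # intercept-only model: no discrimination, calibration slope undefined;
      # in-the-large still well defined through the constant linear predictor
      return(c(auc = 0.5, slope = NA_real_,
               in_the_large = stats::qlogis(mean(y)) - stats::qlogis(p[1])))
    }
    cal <- calibration(p, y)
    c(auc = roc_auc(p, y), slope = cal$slope, in_the_large = cal$in_the_large)
  }

  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, B + 1L)
    original <- fit_recipe(features, outcome, seeds[1L])
    apparent <- eval_metrics(original, features, outcome)

    opt <- matrix(NA_real_, nrow = B, ncol = 3,
                  dimnames = list(NULL, names(apparent)))
    skipped <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- outcome[idx]
      if (length(unique(yb)) < 2L) { skipped <- skipped + 1L; next }
      fb <- features[idx, , drop = FALSE]
      mb <- tryCatch(fit_recipe(fb, yb, seeds[b + 1L]), error = function(e) NULL)
      if (is.null(mb)) { skipped <- skipped + 1L; next }
      opt[b, ] <- eval_metrics(mb, fb, yb) - eval_metrics(mb, features, outcome)
    }
    if (B > 0 && skipped / B > max_skip_frac) {
      abort_ntcp(sprintf("Bootstrap aborted: %d of %d resamples skipped.", skipped, B),
                 "ntcpxero_bootstrap_error")
    }
    optimism <- if (B > 0) colMeans(opt, na.rm = TRUE) else
      stats::setNames(rep(0, 3), names(apparent))
    optimism[is.nan(optimism)] <- 0
    list(
      metrics = tibble::tibble(
        metric = names(apparent),
        apparent = unname(apparent),
        optimism = unname(optimism),
        corrected = unname(apparent - optimism)
      ),
      B = B, skipped = skipped, model = original
    )
  })
}
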