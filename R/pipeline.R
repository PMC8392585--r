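# End-to-end modelling pipeline: DVH reduction -> feature encoding ->
# LASSO selection -> logistic refit -> bootstrap optimism correction.

# Candidate-feature guard against quasi-separation: a binary feature whose
# outcome-by-level cross-table has a cell below `min_cell` carries almost no
# information and routinely separates the logistic fit, so it is excluded
# from the candidate set (continuous features are untouched). Returns the
# names of the features kept.
filter_sparse_features <- function(features, outcome, min_cell = 5) {
  keep <- vapply(features, function(x) {
    ux <- unique(x)
    if (length(ux) > 2L) return(TRUE)
    all(table(factor(x, levels = ux), factor(outcome, levels = 0:1)) >= min_cell)
  }, logical(1))
  names(features)[keep]
}

# Per-patient value of a named dose metric ("EUD n=0.30", "D98%", "V40Gy", ...)
metric_values <- function(dvhs, metric) {
  if (grepl("^EUD n=", metric)) {
    nn <- as.numeric(sub("^EUD n=", "", metric))
    return(purrr::map_dbl(dvhs, compute_eud, n = nn))
  }
  purrr::map_dbl(dvhs, function(d) cutpoint_metrics(d)[[metric]])
}

#' Reduce a cohort's DVHs to summary dose metrics
#'
#' Batch DVH reduction: per patient and organ, the summary metrics
#' (volume, mean, max, D98%) and the full 20-point EUD grid.
#'
#' @param cohort Cohort tibble with DVH list-columns.
#' @param dvh_cols Named character vector mapping organ labels to DVH
#'   list-column names.
#' @return A long tibble: `patient_id`, `organ`, `volume_cc`, `mean_dose`,
#'   `max_dose`, `d98`, and one `eud_n*` column per grid value.
#' @export
reduce_dvhs <- function(cohort, dvh_cols = c(cPG = "dvh_cpg", OC = "dvh_oc")) {
  ids <- cohort[["patient_id"]] %||% as.character(seq_len(nrow(cohort)))
  purrr::imap_dfr(dvh_cols, function(col, organ) {
    dvhs <- cohort[[col]]
    if (is.null(dvhs)) {
      abort_ntcp(sprintf("Column `%s` not found in cohort.", col),
                 "ntcpxero_input_error")
    }
    summaries <- purrr::map_dfr(dvhs, summarize_dvh)
    grids <- purrr::map_dfr(seq_along(dvhs), function(i) {
      g <- eud_grid(dvhs[[i]])
      tidyr::pivot_wider(
        dplyr::transmute(g, patient_id = ids[i],
                         name = sprintf("eud_n%.2f", .data$n),
                         eud = .data$eud),
        names_from = "name", values_from = "eud"
      )
    })
    dplyr::bind_cols(
      tibble::tibble(patient_id = ids, organ = organ),
      dplyr::select(summaries, -"organ"),
      dplyr::select(grids, -"patient_id")
    )
  })
}

default_clinical_features <- function() {
  c("age_5y", "bmi", "bmi_ge25", "bmi_ge30", "sex_male", "smoking",
    "comorb_hypertension", "comorb_diabetes", "comorb_cardiological",
    "comorb_haematological", "comorb_oncological", "histology_scc",
    "histology_other", "stage_high", "t_high", "n_positive", "treat_icht",
    "treat_rt_alone", "technique_vmat", "fraction_ge212", "ott_days")
}

#' Develop an NTCP model on a cohort
#'
#' The full development recipe on one cohort tibble:
#'
#' 1. derive the grade >= 2 endpoint from weekly grades (if not present);
#' 2. reduce each organ's DVH to its dose feature — either the canonical
#'    reduction (`dose_metrics = "fixed"`: combined-parotid D98% and
#'    oral-cavity EUD at n = 0.05) or the metric chosen by t-test screening
#'    over the EUD grid with cut-point fallback (`"screen"`);
#' 3. encode clinical covariates and run cross-validated LASSO over the
#'    candidate feature matrix;
#' 4. refit the selected variables by unpenalized logistic regression;
#' 5. internally validate with `B` bootstrap resamples of the whole recipe
#'    (optimism-corrected AUC, calibration slope, calibration-in-the-large)
#'    and compute apparent calibration, Hosmer-Lemeshow, classification
#'    and residual diagnostics.
#'
#' @param cohort Cohort tibble (as from [generate_cohort()] or read from
#'   the documented CSV layout).
#' @param clinical_features Candidate clinical feature names (defaults to
#'   the full encoded set).
#' @param dose_metrics `"fixed"` or `"screen"`.
#' @param force_in Feature names exempted from selection and always
#'   refitted (e.g. the dosimetric terms); default none.
#' @param folds,rule,B Passed to [lasso_select()] / [bootstrap_optimism()].
#' @param boot_recipe `"full"` repeats selection inside each resample
#'   (default); `"refit"` only refits the selected terms.
#' @param cutoff,hl_groups,residual_threshold Reporting settings.
#' @param min_cell Sparse-cell guard: binary candidate features need at
#'   least this many patients in each outcome-by-level cell (default 5).
#' @param seed Seed fixing fold assignment, bootstrap and any ties.
#' @return An object of class `ntcp_fit`: the fitted `model`, the
#'   candidate `features`, selection and screening detail, the bootstrap
#'   table and the apparent-performance report.
#' @export
develop_ntcp <- function(cohort,
                         clinical_features = default_clinical_features(),
                         dose_metrics = c("fixed", "screen"),
                         force_in = NULL,
                         folds = 5, rule = "min", B = 1000,
                         boot_recipe = c("full", "refit"),
                         cutoff = 0.65, hl_groups = 6,
                         residual_threshold = 0.7,
                         min_cell = 5,
                         seed = NULL) {
  dose_metrics <- match.arg(dose_metrics)
  boot_recipe <- match.arg(boot_recipe)
  if (nrow(cohort) < 2L * folds) {
    abort_ntcp("Cohort too small to develop a model.", "ntcpxero_input_error")
  }
  if (!"event" %in% names(cohort)) cohort <- derive_endpoints(cohort)
  outcome <- check_binary_vector(cohort$event, "event")

  screens <- list()
  if (dose_metrics == "screen") {
    sel_cpg <- select_best_metric(cohort, "dvh_cpg", outcome)
    sel_oc <- select_best_metric(cohort, "dvh_oc", outcome)
    screens <- list(cPG = sel_cpg, OC = sel_oc)
    cpg_metric <- sel_cpg$metric[sel_cpg$selected]
    oc_metric <- sel_oc$metric[sel_oc$selected]
  } else {
    cpg_metric <- "D98%"
    oc_metric <- "EUD n=0.05"
  }
  dose_feats <- tibble::tibble(
    cpg_d98 = metric_values(cohort$dvh_cpg, cpg_metric),
    oc_eud = metric_values(cohort$dvh_oc, oc_metric)
  )
  eud_params <- list(cPG = cpg_metric, OC = oc_metric)

  clin <- dplyr::select(encode_covariates(cohort),
                        dplyr::all_of(clinical_features))
  features <- dplyr::bind_cols(clin, dose_feats)
  features <- features[, union(filter_sparse_features(features, outcome, min_cell),
                               force_in), drop = FALSE]

  selected <- union(
    suppressWarnings(
      lasso_select(features, outcome, folds = folds, rule = rule, seed = seed)
    ),
    force_in
  )
  model <- if (length(selected)) {
    fit_ntcp(dplyr::select(features, dplyr::all_of(selected)), outcome,
             eud_params = eud_params)
  } else {
    fit_ntcp(features[, 0], outcome, eud_params = eud_params)
  }

  boot <- bootstrap_optimism(features, outcome, B = B, recipe = boot_recipe,
                             seed = seed, folds = folds, rule = rule,
                             min_cell = min_cell, force_in = force_in)

  apparent <- external_validate(
    model, dplyr::mutate(features, event = outcome,
                         patient_id = cohort$patient_id %||%
                           as.character(seq_len(nrow(features)))),
    cohort_label = "development (apparent)", cutoff = cutoff,
    hl_groups = hl_groups, residual_threshold = residual_threshold,
    refit_effects = FALSE
  )

  structure(
    list(model = model, features = features, outcome = outcome,
         selected = selected, screens = screens, eud_params = eud_params,
         bootstrap = boot, apparent = apparent,
         settings = list(folds = folds, rule = rule, B = B,
                         boot_recipe = boot_recipe, seed = seed,
                         dose_metrics = dose_metrics, cutoff = cutoff,
                         hl_groups = hl_groups)),
    class = "ntcp_fit"
  )
}

#' @export
print.ntcp_fit <- function(x, ...) {
  cat(sprintf("<ntcp_fit> n = %d, events = %d; %d term(s) selected\n",
              x$model$fit_meta$n, x$model$fit_meta$events, nrow(x$model$terms)))
  print(x$model$terms)
  cat(sprintf("\nBootstrap internal validation (B = %d, %d skipped):\n",
              x$bootstrap$B, x$bootstrap$skipped))
  print(x$bootstrap$metrics)
  invisible(x)
}

#' Simulate a development study with external validation cohorts
#'
#' Convenience wrapper generating a development cohort plus the two
#' validation cohorts (NPC and mixed head-and-neck), the latter with
#' systematically increased event odds to emulate the incidence shift
#' typically seen between historical development data and later
#' prospective validation data.
#'
#' @param seed Integer seed (sub-seeds are derived deterministically).
#' @param n_dev,n_npc,n_hnc Cohort sizes (defaults 132 / 38 / 93).
#' @param validation_odds_multiplier Odds multiplier applied to both
#'   validation cohorts (default 3).
#' @param true_model Outcome-generating model.
#' @return Named list of three cohort tibbles.
#' @export
simulate_study <- function(seed = NULL, n_dev = 132, n_npc = 38, n_hnc = 93,
                           validation_odds_multiplier = 3,
                           true_model = reference_model()) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 3))
  list(
    development = generate_cohort(
      cohort_spec(n_dev, "development", seed = seeds[1], true_model = true_model)
    ),
    npc_validation = generate_cohort(
      cohort_spec(n_npc, "npc_validation", seed = seeds[2],
                  true_model = true_model,
                  odds_multiplier = validation_odds_multiplier)
    ),
    hnc_validation = generate_cohort(
      cohort_spec(n_hnc, "hnc_validation", seed = seeds[3],
                  true_model = true_model,
                  odds_multiplier = validation_odds_multiplier)
    )
  )
}
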