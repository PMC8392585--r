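#' Organ DVH-shape templates
#'
#' A template holds the target joint distribution of per-patient DVH
#' summary metrics for one organ at risk: organ volume, mean dose, maximum
#' dose and near-minimum dose (D98%), with the D98%-mean correlation that
#' clinical plans show (strongly positive: plans delivering higher mean
#' dose also lift the cold spots). Defaults reproduce the development
#' cohort's dosimetric moments for the combined parotid glands and the
#' oral cavity.
#'
#' @param organ Organ label.
#' @param volume_mean,volume_sd Organ volume moments (cc).
#' @param mean_mean,mean_sd Mean dose moments (Gy).
#' @param max_mean,max_sd Maximum dose moments (Gy).
#' @param d98_mean,d98_sd Near-minimum dose moments (Gy).
#' @param d98_mean_cor Target Pearson correlation between D98% and mean dose.
#' @param step Dose-grid step of generated DVHs (Gy, default 0.5).
#' @return A list of class `organ_template`.
#' @export
organ_template <- function(organ, volume_mean, volume_sd, mean_mean, mean_sd,
                           max_mean, max_sd, d98_mean, d98_sd,
                           d98_mean_cor = 0.88, step = 0.5) {
  stopifnot(volume_sd >= 0, mean_sd >= 0, max_sd >= 0, d98_sd >= 0,
            abs(d98_mean_cor) < 1)
  if (d98_mean >= max_mean) {
    abort_ntcp("Template implies D98% above the maximum dose.",
               "ntcpxero_synthetic_error")
  }
  structure(
    list(organ = organ, volume_mean = volume_mean, volume_sd = volume_sd,
         mean_mean = mean_mean, mean_sd = mean_sd,
         max_mean = max_mean, max_sd = max_sd,
         d98_mean = d98_mean, d98_sd = d98_sd,
         d98_mean_cor = d98_mean_cor, step = step),
    class = "organ_template"
  )
}

#' @rdname organ_template
#' @export
cpg_template <- function() {
  organ_template("cPG", volume_mean = 53.3, volume_sd = 19.3,
                 mean_mean = 47.2, mean_sd = 9.5,
                 max_mean = 74.2, max_sd = 3.5,
                 d98_mean = 26.8, d98_sd = 9.5, d98_mean_cor = 0.88)
}

#' @rdname organ_template
#' @export
oc_template <- function() {
  # oral cavity: volume and mean/max dose moments from the development
  # cohort; no D98% is tabulated for the OC, so its location/spread is an
  # assumption (same D98-mean correlation as the parotids)
  organ_template("OC", volume_mean = 64.8, volume_sd = 20.4,
                 mean_mean = 46.7, mean_sd = 6.4,
                 max_mean = 71.9, max_sd = 3.7,
                 d98_mean = 24.0, d98_sd = 8.0, d98_mean_cor = 0.88)
}

# Solve the cumulative-curve geometry that interpolates drawn summary
# metrics exactly: volume fraction 1 up to knee `a`, falling linearly to
# level `q` at knot `c`, then to 0 at the maximum dose. For a given knot
# level q the knee and knot positions follow from
#   d98  = a + 0.02 (c - a) / (1 - q)
#   mean = a (1 - q) / 2 + c / 2 + max q / 2      (bin-centre mean = area)
# The knot level is chosen adaptively from a grid so that plans with mean
# dose anywhere between the near-minimum and maximum dose admit a valid
# curve (high-mean plans need a heavy high-dose tail, i.e. large q).
solve_dvh_geometry <- function(d98, mean_dose, max_dose) {
  for (q in c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.4, 0.3, 0.2, 0.1, 0.05)) {
    k <- 0.02 / (1 - q)
    denom <- 1 - k * (2 - q)
    if (denom <= 0) next
    a <- (d98 - 2 * k * mean_dose + k * q * max_dose) / denom
    cc <- 2 * mean_dose - a * (1 - q) - max_dose * q
    if (a > 0.2 && cc > a + 0.3 && cc < max_dose - 0.3) {
      return(list(a = a, c = cc, q = q))
    }
  }
  NULL
}

# Draw n rows of (volume, mean, max, d98) from the template's joint
# distribution. Volume is truncated below at 5 cc; (mean, max) pairs are
# redrawn when ordering fails; d98 is clamped into (0, mean) where the
# normal tail would violate it (both events are rare, so sample moments
# stay at the template targets).
draw_organ_metrics <- function(template, n) {
  rho <- template$d98_mean_cor
  draw_once <- function(m) {
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    mean_dose <- template$mean_mean + template$mean_sd * z1
    d98 <- template$d98_mean + template$d98_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    max_dose <- stats::rnorm(m, template$max_mean, template$max_sd)
    tibble::tibble(mean_dose = mean_dose, max_dose = max_dose, d98 = d98)
  }
  valid <- function(d) {
    ok <- d$mean_dose > 5 & d$mean_dose < d$max_dose - 2
    geo <- purrr::pmap_lgl(d, function(mean_dose, max_dose, d98) {
      d98c <- min(max(d98, 1), mean_dose - 1)
      !is.null(solve_dvh_geometry(d98c, mean_dose, max_dose))
    })
    ok & geo
  }
  out <- draw_once(n)
  ok <- valid(out)
  tries <- 0L
  while (!all(ok) && tries < 50L) {
    redo <- draw_once(sum(!ok))
    out[!ok, ] <- redo
    ok[!ok] <- valid(redo)
    tries <- tries + 1L
  }
  if (!all(ok)) {
    abort_ntcp("Could not draw valid DVH metrics from this template.",
               "ntcpxero_synthetic_error")
  }
  out$d98 <- pmin(pmax(out$d98, 1), out$mean_dose - 1)
  out$volume <- rtruncnorm1(n, template$volume_mean, template$volume_sd, 5, Inf)
  out[, c("volume", "mean_dose", "max_dose", "d98")]
}

# Piecewise-linear cumulative DVH reproducing the drawn summary metrics
# exactly (see solve_dvh_geometry for the construction).
build_dvh_from_metrics <- function(d98, mean_dose, max_dose, volume,
                                   organ = "organ", step = 0.5) {
  geo <- solve_dvh_geometry(d98, mean_dose, max_dose)
  if (is.null(geo)) {
    abort_ntcp("Requested metrics admit no valid DVH geometry.",
               "ntcpxero_synthetic_error")
  }
  edges <- sort(unique(c(seq(0, max_dose, by = step), geo$a, geo$c, max_dose)))
  vfrac <- stats::approx(c(0, geo$a, geo$c, max_dose), c(1, 1, geo$q, 0),
                         xout = edges, rule = 2)$y
  dvh(edges, volume * vfrac, organ = organ, form = "cumulative",
      total_volume = volume)
}

#' Generate a synthetic DVH from an organ template
#'
#' Draws one patient's (volume, mean dose, max dose, D98%) from the
#' template's joint distribution and constructs a cumulative DVH that
#' reproduces those summary metrics exactly; over many draws the sample
#' moments and the D98%-mean correlation converge to the template targets.
#'
#' @param template An [organ_template()].
#' @param n Number of DVHs (default 1).
#' @return A `dvh` for `n = 1`, otherwise a list of `dvh` objects.
#' @export
generate_dvh <- function(template, n = 1) {
  if (!inherits(template, "organ_template")) {
    abort_ntcp("`template` must be an <organ_template>.", "ntcpxero_synthetic_error")
  }
  met <- draw_organ_metrics(template, n)
  out <- purrr::pmap(met, function(volume, mean_dose, max_dose, d98) {
    build_dvh_from_metrics(d98, mean_dose, max_dose, volume,
                           organ = template$organ, step = template$step)
  })
  if (n == 1L) out[[1L]] else out
}

#' Synthetic cohort specification
#'
#' Bundles everything that defines a simulated study population: cohort
#' size, the clinical-covariate distributions (with presets reproducing the
#' development, NPC-validation and mixed head-and-neck-validation
#' populations), the organ DVH templates, the true outcome-generating NTCP
#' model ([reference_model()] by default), an odds multiplier emulating
#' calibration-in-the-large shift, and the conditional first-event-week
#' profile tuned to the development cohort's actuarial incidence pattern
#' (12%, 26.5%, 42%, 53%, 60% and 68.2% cumulative at weeks 2-7).
#'
#' @param n_patients Cohort size.
#' @param cohort `"development"`, `"npc_validation"` or `"hnc_validation"`
#'   (chooses the covariate-prevalence preset).
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @param true_model The outcome-generating `ntcp_model`.
#' @param odds_multiplier Multiplies every patient's event odds (default 1).
#' @param templates List of organ templates (`cpg`, `oc`).
#' @param n_weeks Weekly assessments recorded per patient (default 7:
#'   baseline plus six on-treatment weeks).
#' @param week_profile Conditional probabilities of the first event falling
#'   in weeks 2..`n_weeks` (normalised internally).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 132,
                        cohort = c("development", "npc_validation", "hnc_validation"),
                        seed = NULL,
                        true_model = reference_model(),
                        odds_multiplier = 1,
                        templates = list(cpg = cpg_template(), oc = oc_template()),
                        n_weeks = 7,
                        week_profile = c(12, 14.5, 15.5, 11, 7, 8.2)) {
  cohort <- match.arg(cohort)
  if (odds_multiplier <= 0) {
    abort_ntcp("`odds_multiplier` must be positive.", "ntcpxero_synthetic_error")
  }
  if (length(week_profile) != n_weeks - 1L || any(week_profile < 0)) {
    abort_ntcp("`week_profile` needs one non-negative weight per week 2..n_weeks.",
               "ntcpxero_synthetic_error")
  }
  prev <- switch(
    cohort,
    development = list(
      male = 0.697, age_med = 49, age_range = c(18, 81), age_sd = 12,
      bmi_med = 25.9, bmi_range = c(16.6, 42.9), bmi_sd = 4.5,
      smoking = 0.182,
      comorb = c(hypertension = 0.144, diabetes = 0.030, cardiological = 0.045,
                 haematological = 0.053, oncological = 0.038),
      histology = c(undifferentiated = 0.902, SCC = 0.098, other = 0),
      stage_high = 0.849, t_high = 0.30, n_positive = 0.80,
      treatment = c("RT-CHT" = 0.227, "iCHT+RT-CHT" = 0.773, "RT alone" = 0),
      vmat = 0.470, fraction_ge212 = 0.235
    ),
    npc_validation = list(
      male = 0.789, age_med = 52, age_range = c(24, 72), age_sd = 11,
      bmi_med = 25.8, bmi_range = c(18.2, 32.9), bmi_sd = 3.5,
      smoking = 0.526,
      comorb = c(hypertension = 0.263, diabetes = 0.026, cardiological = 0.079,
                 haematological = 0, oncological = 0.079),
      histology = c(undifferentiated = 0.895, SCC = 0.105, other = 0),
      stage_high = 0.842, t_high = 0.30, n_positive = 0.868,
      treatment = c("RT-CHT" = 0.500, "iCHT+RT-CHT" = 0.421, "RT alone" = 0.079),
      vmat = 1, fraction_ge212 = 0.974
    ),
    hnc_validation = list(
      male = 0.731, age_med = 62, age_range = c(23, 83), age_sd = 12,
      bmi_med = 24.8, bmi_range = c(14.7, 36.4), bmi_sd = 4.5,
      smoking = 0.677,
      comorb = c(hypertension = 0.398, diabetes = 0.043, cardiological = 0.215,
                 haematological = 0.021, oncological = 0.161),
      histology = c(undifferentiated = 0, SCC = 0.903, other = 0.097),
      stage_high = 0.925, t_high = 0.40, n_positive = 0.70,
      treatment = c("RT-CHT" = 0.602, "iCHT+RT-CHT" = 0.118, "RT alone" = 0.280),
      vmat = 1, fraction_ge212 = 0.656
    )
  )
  structure(
    list(n_patients = n_patients, cohort = cohort, seed = seed,
         true_model = true_model, odds_multiplier = odds_multiplier,
         templates = templates, n_weeks = n_weeks,
         week_profile = week_profile / sum(week_profile),
         prevalences = prev),
    class = "cohort_spec"
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

# Assemble a weekly grade trajectory consistent with a drawn event status:
# baseline 0, grade-1 background before (or without) the event, grade >= 2
# from the first event week onward.
make_weekly_grades <- function(event, event_week, n_weeks) {
  g <- integer(n_weeks)
  if (n_weeks >= 2L) {
    ramp <- seq(0.15, 0.6, length.out = n_weeks - 1L)
    g[2:n_weeks] <- stats::rbinom(n_weeks - 1L, 1L, ramp)
  }
  if (event) {
    if (event_week > 2L) g[2:(event_week - 1L)] <- pmin(g[2:(event_week - 1L)], 1L)
    post <- event_week:n_weeks
    g[post] <- 2L + stats::rbinom(length(post), 1L, 0.15)
  }
  g
}

#' Generate a synthetic patient cohort
#'
#' Draws clinical covariates from the spec's prevalence preset, per-organ
#' DVHs from the organ templates, the binary endpoint from the true NTCP
#' model (`event ~ Bernoulli(p)` with
#' `p = plogis(linear predictor + log(odds multiplier))`), and weekly CTCAE
#' grade trajectories whose derived endpoint reproduces the drawn event and
#' whose first-event weeks follow the spec's week profile.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient: identifiers, clinical
#'   covariates, `weekly_grades` / `dvh_cpg` / `dvh_oc` list-columns, the
#'   reduced dose metrics `cpg_d98` and `oc_eud` (EUD at n = 0.05), the
#'   model features `age_5y` and `smoking`, the generating probability
#'   `p_true`, and the drawn `event` with `first_event_week`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort_ntcp("`spec` must be a <cohort_spec>.", "ntcpxero_synthetic_error")
  }
  n <- spec$n_patients
  pr <- spec$prevalences
  with_seed(spec$seed, {
    cohort <- tibble::tibble(
      patient_id = sprintf("%s_%04d", toupper(substr(spec$cohort, 1, 3)), seq_len(n)),
      cohort = spec$cohort,
      sex = ifelse(stats::runif(n) < pr$male, "M", "F"),
      age = rtruncnorm1(n, pr$age_med, pr$age_sd, pr$age_range[1], pr$age_range[2]),
      bmi = rtruncnorm1(n, pr$bmi_med, pr$bmi_sd, pr$bmi_range[1], pr$bmi_range[2]),
      smoking = stats::rbinom(n, 1L, pr$smoking),
      comorb_hypertension = stats::rbinom(n, 1L, pr$comorb[["hypertension"]]),
      comorb_diabetes = stats::rbinom(n, 1L, pr$comorb[["diabetes"]]),
      comorb_cardiological = stats::rbinom(n, 1L, pr$comorb[["cardiological"]]),
      comorb_haematological = stats::rbinom(n, 1L, pr$comorb[["haematological"]]),
      comorb_oncological = stats::rbinom(n, 1L, pr$comorb[["oncological"]]),
      histology = sample(names(pr$histology), n, replace = TRUE, prob = pr$histology),
      stage_group = ifelse(stats::runif(n) < pr$stage_high, "high", "low-intermediate"),
      t_high = stats::rbinom(n, 1L, pr$t_high),
      n_positive = stats::rbinom(n, 1L, pr$n_positive),
      treatment = sample(names(pr$treatment), n, replace = TRUE, prob = pr$treatment),
      technique = ifelse(stats::runif(n) < pr$vmat, "VMAT", "IMRT"),
      fraction_dose = ifelse(stats::runif(n) < pr$fraction_ge212, 2.12, 2.00),
      ott_days = round(rtruncnorm1(n, 50, 4, 43, 61))
    )
    cpg_met <- draw_organ_metrics(spec$templates$cpg, n)
    oc_met <- draw_organ_metrics(spec$templates$oc, n)
    cohort$dvh_cpg <- purrr::pmap(cpg_met, function(volume, mean_dose, max_dose, d98) {
      build_dvh_from_metrics(d98, mean_dose, max_dose, volume,
                             organ = spec$templates$cpg$organ,
                             step = spec$templates$cpg$step)
    })
    cohort$dvh_oc <- purrr::pmap(oc_met, function(volume, mean_dose, max_dose, d98) {
      build_dvh_from_metrics(d98, mean_dose, max_dose, volume,
                             organ = spec$templates$oc$organ,
                             step = spec$templates$oc$step)
    })
    cohort$cpg_d98 <- cpg_met$d98
    cohort$oc_eud <- purrr::map_dbl(cohort$dvh_oc, compute_eud, n = 0.05)
    feats <- dplyr::bind_cols(
      encode_covariates(cohort),
      cohort[, c("cpg_d98", "oc_eud")]
    )
    lp <- linear_predictor(spec$true_model, feats) + log(spec$odds_multiplier)
    cohort$age_5y <- feats$age_5y
    cohort$p_true <- stats::plogis(lp)
    event <- stats::rbinom(n, 1L, cohort$p_true)
    event_week <- rep(NA_integer_, n)
    if (any(event == 1L)) {
      event_week[event == 1L] <- sample(
        2:spec$n_weeks, sum(event), replace = TRUE, prob = spec$week_profile
      )
    }
    cohort$weekly_grades <- purrr::map2(
      event, event_week,
      function(e, w) make_weekly_grades(e == 1L, w, spec$n_weeks)
    )
    cohort$event <- event
    cohort$first_event_week <- event_week
    cohort$n_weeks <- spec$n_weeks
    cohort
  })
}

#' Generate a validation cohort with shifted event odds
#'
#' As [generate_cohort()], but every patient's event odds are multiplied by
#' `odds_multiplier` before the outcome draw. Frozen-coefficient external
#' validation on such a cohort recovers a calibration-in-the-large close to
#' `log(odds_multiplier)` with slope close to 1, emulating the systematic
#' incidence shift between a development and a later validation population;
#' discrimination (AUC) is unaffected by this pure recalibration shift.
#'
#' @param spec A [cohort_spec()].
#' @param odds_multiplier Positive odds multiplier.
#' @return A cohort tibble.
#' @export
generate_validation_shift <- function(spec, odds_multiplier) {
  if (!inherits(spec, "cohort_spec")) {
    abort_ntcp("`spec` must be a <cohort_spec>.", "ntcpxero_synthetic_error")
  }
  spec$odds_multiplier <- spec$odds_multiplier * odds_multiplier
  generate_cohort(spec)
}
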