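# Independent oracles and fixture builders used across the suite.

# Random valid differential DVH (caller sets the seed).
random_dvh <- function(max_bins = 8, max_dose = 80) {
  k <- sample(2:max_bins, 1)
  edges <- sort(stats::runif(k + 1, 0, max_dose))
  while (any(diff(edges) < 1e-3)) edges <- sort(stats::runif(k + 1, 0, max_dose))
  vols <- stats::runif(k, 0.1, 10)
  dvh(edges, vols, organ = "rand", form = "differential")
}

# Textbook pooled-variance two-sample t statistic.
pooled_t_oracle <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2)
  tstat <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2)
  list(t = tstat, p = p)
}

# AUC by exhaustive concordant-pair enumeration (ties count 1/2).
auc_pairs_oracle <- function(predicted, observed) {
  pos <- predicted[observed == 1]
  neg <- predicted[observed == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Hosmer-Lemeshow chi-squared from a hand-built grouping.
hl_chi2_oracle <- function(n, obs_events, exp_events) {
  sum((obs_events - exp_events)^2 / exp_events +
        ((n - obs_events) - (n - exp_events))^2 / (n - exp_events))
}

# DVH bundle for screening simulations: n patients from the parotid
# template plus the per-patient metric driving the outcome.
simulated_organ_cohort <- function(n, driver = c("nearmax", "mean")) {
  driver <- match.arg(driver)
  tpl <- cpg_template()
  dvhs <- generate_dvh(tpl, n)
  x <- switch(driver,
    nearmax = purrr::map_dbl(dvhs, compute_eud, n = 0.05),
    mean = purrr::map_dbl(dvhs, function(d) summarize_dvh(d)$mean_dose)
  )
  list(cohort = tibble::tibble(dvh_cpg = dvhs), metric = x)
}

# Integral dose (sum of bin volume times bin-centre dose) of a DVH.
integral_dose <- function(d) {
  dd <- ntcpxero:::as_differential(d)
  k <- length(dd$volume)
  centers <- (dd$dose_edges[-(k + 1)] + dd$dose_edges[-1]) / 2
  sum(dd$volume * centers)
}
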