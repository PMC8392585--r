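test_that("generated parotid DVHs reproduce the template moments", {
  set.seed(201)
  dvhs <- generate_dvh(cpg_template(), 2000)
  s <- purrr::map_dfr(dvhs, summarize_dvh)
  expect_equal(mean(s$mean_dose), 47.2, tolerance = 0.5 / 47.2)
  expect_equal(sd(s$mean_dose), 9.5, tolerance = 0.5 / 9.5)
  expect_equal(mean(s$d98), 26.8, tolerance = 0.5 / 26.8)
  expect_equal(sd(s$d98), 9.5, tolerance = 0.5 / 9.5)
  expect_equal(mean(s$max_dose), 74.2, tolerance = 0.5 / 74.2)
  expect_equal(mean(s$volume_cc), 53.3, tolerance = 1 / 53.3)
  expect_equal(cor(s$d98, s$mean_dose), 0.88, tolerance = 0.05 / 0.88)
  # every generated DVH is internally consistent
  expect_true(all(s$d98 <= s$mean_dose & s$mean_dose <= s$max_dose))
})

test_that("oral cavity template hits its tabulated moments", {
  set.seed(202)
  dvhs <- generate_dvh(oc_template(), 1500)
  s <- purrr::map_dfr(dvhs, summarize_dvh)
  expect_equal(mean(s$mean_dose), 46.7, tolerance = 0.5 / 46.7)
  expect_equal(sd(s$mean_dose), 6.4, tolerance = 0.6 / 6.4)
  expect_equal(mean(s$max_dose), 71.9, tolerance = 0.5 / 71.9)
  expect_equal(mean(s$volume_cc), 64.8, tolerance = 1 / 64.8)
})

test_that("a degenerate template yields identical DVHs", {
  tpl <- organ_template("uniform", volume_mean = 50, volume_sd = 0,
                        mean_mean = 45, mean_sd = 0, max_mean = 70,
                        max_sd = 0, d98_mean = 25, d98_sd = 0)
  set.seed(203)
  ds <- generate_dvh(tpl, 3)
  expect_equal(ds[[1]]$volume, ds[[2]]$volume)
  expect_equal(ds[[2]]$volume, ds[[3]]$volume)
  s <- summarize_dvh(ds[[1]])
  expect_equal(s$mean_dose, 45, tolerance = 1e-6)
  expect_equal(s$d98, 25, tolerance = 1e-6)

  expect_error(organ_template("bad", 50, 1, 45, 1, 70, 1, d98_mean = 75,
                              d98_sd = 1),
               "D98% above the maximum")
})

test_that("cohort generation is bit-identical under a seed", {
  spec <- cohort_spec(60, seed = 314)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # and leaves the caller's RNG stream alone
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_cohort(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated cohorts are self-consistent with the true model", {
  spec <- cohort_spec(5000, seed = 271)
  co <- generate_cohort(spec)
  # event rate matches the mean model-implied probability
  mc_se <- sqrt(mean(co$p_true * (1 - co$p_true)) / nrow(co))
  expect_lt(abs(mean(co$event) - mean(co$p_true)), 2 * mc_se)
  # weekly grades reproduce the drawn endpoint exactly
  ep <- dplyr::bind_rows(purrr::map(co$weekly_grades, derive_endpoint))
  expect_equal(ep$event, co$event)
  expect_equal(ep$first_event_week, co$first_event_week)
  # dose features equal the DVH reductions
  expect_equal(purrr::map_dbl(co$dvh_cpg, function(d) summarize_dvh(d)$d98),
               co$cpg_d98, tolerance = 1e-6)
  expect_equal(purrr::map_dbl(co$dvh_oc, compute_eud, n = 0.05),
               co$oc_eud, tolerance = 1e-9)
})

test_that("a slope-free spec reproduces the development event rate", {
  null_model <- ntcp_model(log(0.682 / 0.318),
                           tibble::tibble(term = character(0),
                                          estimate = numeric(0),
                                          std_error = numeric(0)))
  spec <- cohort_spec(5000, seed = 272, true_model = null_model)
  co <- generate_cohort(spec)
  expect_equal(unique(co$p_true), 0.682, tolerance = 1e-9)
  expect_equal(mean(co$event), 0.682,
               tolerance = 2 * sqrt(0.682 * 0.318 / 5000) / 0.682)
  # and its actuarial incidence tracks the tabulated weekly pattern
  inc <- actuarial_incidence(co, weeks = 2:7)
  expect_equal(inc$incidence, c(12, 26.5, 42, 53, 60, 68.2) / 100,
               tolerance = 0.05)
})

test_that("covariate prevalences follow the cohort presets", {
  spec <- cohort_spec(4000, seed = 273)
  co <- generate_cohort(spec)
  expect_equal(mean(co$smoking), 0.182, tolerance = 0.1)
  expect_equal(mean(co$sex == "M"), 0.697, tolerance = 0.05)
  expect_true(all(co$age >= 18 & co$age <= 81))
  spec_v <- cohort_spec(4000, "npc_validation", seed = 274)
  cov <- generate_cohort(spec_v)
  expect_equal(mean(cov$smoking), 0.526, tolerance = 0.05)
  expect_true(all(cov$technique == "VMAT"))
})

test_that("odds multiplier 1 behaves exactly as generate_cohort", {
  spec <- cohort_spec(80, seed = 275)
  expect_identical(generate_validation_shift(spec, 1), generate_cohort(spec))
})

test_that("a recalibration shift leaves discrimination unchanged", {
  base <- generate_cohort(cohort_spec(4000, seed = 276))
  shifted <- generate_validation_shift(cohort_spec(4000, seed = 277), 3)
  auc_base <- roc_auc(predict_ntcp(reference_model(), base), base$event)
  auc_shift <- roc_auc(predict_ntcp(reference_model(), shifted), shifted$event)
  expect_equal(auc_shift, auc_base, tolerance = 0.05)
})
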