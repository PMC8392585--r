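test_that("roc_auc equals exhaustive pair counting", {
  # perfectly separated predictions
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)

  # 6-point hand example with a tie
  p <- c(0.9, 0.6, 0.6, 0.4, 0.3, 0.2)
  y <- c(1, 1, 0, 1, 0, 0)
  expect_equal(roc_auc(p, y), auc_pairs_oracle(p, y))

  set.seed(151)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 2)  # rounded to force ties sometimes
    expect_equal(roc_auc(p, y), auc_pairs_oracle(p, y), tolerance = 1e-12)
  }

  expect_error(roc_auc(c(0.2, 0.4), c(1, 1)), "both outcome classes")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(152)
  y <- rbinom(200, 1, 0.4)
  p <- plogis(rnorm(200) + y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(p, y), ref, tolerance = 1e-12)
})

test_that("random predictions give chance-level discrimination", {
  set.seed(153)
  y <- rbinom(4000, 1, 0.5)
  p <- runif(4000)
  expect_equal(roc_auc(p, y), 0.5, tolerance = 0.03)
  expect_gt(roc_auc_p(p, y), 0.01)
})

test_that("calibration recovers slope and in-the-large by construction", {
  set.seed(161)
  p <- plogis(rnorm(10000, 0, 1.2))
  y <- rbinom(length(p), 1, p)
  cal <- calibration(p, y)
  expect_lt(abs(cal$slope - 1), 3 * cal$slope_se)
  expect_lt(abs(cal$in_the_large), 3 * cal$in_the_large_se)

  # predictions with halved logits: true logits are 2x the stated ones
  p_half <- plogis(stats::qlogis(p) / 2)
  cal2 <- calibration(p_half, y)
  expect_equal(cal2$slope, 2, tolerance = 0.15)

  # uniformly higher observed risk gives positive in-the-large
  y_up <- rbinom(length(p), 1, plogis(stats::qlogis(p) + 1))
  expect_gt(calibration(p, y_up)$in_the_large, 0)

  expect_error(calibration(rep(0.4, 50), rbinom(50, 1, 0.4)),
               "constant predictions")
  expect_error(calibration(c(0, 0.5), c(0, 1)), "strictly in")
})

test_that("Hosmer-Lemeshow equals the hand-computed statistic", {
  # two groups built by hand: group risks 0.2 and 0.6, 10 patients each
  p <- c(rep(0.2, 10), rep(0.6, 10))
  y <- c(rep(1, 3), rep(0, 7), rep(1, 7), rep(0, 3))
  hl <- hosmer_lemeshow(p, y, groups = 2)
  expect_equal(hl$chi2, hl_chi2_oracle(c(10, 10), c(3, 7), c(2, 6)))
  expect_equal(hl$p, stats::pchisq(hl$chi2, df = 1, lower.tail = FALSE))

  # observed equal to expected in every group: chi2 = 0, p = 1
  p0 <- c(rep(0.25, 4), rep(0.5, 4), rep(0.75, 4))
  y0 <- c(1, 0, 0, 0, 1, 1, 0, 0, 1, 1, 1, 0)
  hl0 <- hosmer_lemeshow(p0, y0, groups = 3)
  expect_equal(hl0$chi2, 0)
  expect_equal(hl0$p, 1)

  # random instances against the brute-force oracle
  set.seed(171)
  for (i in 1:10) {
    n <- 60
    p <- runif(n, 0.05, 0.95)
    y <- rbinom(n, 1, p)
    g <- 6
    hl <- hosmer_lemeshow(p, y, groups = g)
    tab <- hl$table
    expect_equal(hl$chi2,
                 hl_chi2_oracle(tab$n, tab$observed_events, tab$expected_events),
                 tolerance = 1e-12)
    expect_equal(sum(tab$n), n)
  }
})

test_that("Hosmer-Lemeshow grouping keeps equal sizes and ties together", {
  p <- seq(0.1, 0.9, length.out = 20)
  grp <- ntcpxero:::risk_groups(p, 6)
  expect_equal(as.numeric(table(grp)), c(4, 4, 3, 3, 3, 3))
  # tied predictions share a group
  p2 <- c(rep(0.3, 5), seq(0.4, 0.9, length.out = 7))
  grp2 <- ntcpxero:::risk_groups(p2, 4)
  expect_equal(length(unique(grp2[p2 == 0.3])), 1L)
})

test_that("fitted well-specified models give uniform-ish HL p-values", {
  # the chi-squared reference with groups - 2 degrees of freedom applies to
  # probabilities fitted on the same data, as in the development setting
  set.seed(181)
  ps <- replicate(40, {
    lp <- rnorm(300, 0.5, 1)
    y <- rbinom(300, 1, plogis(lp))
    fit <- stats::glm(y ~ lp, family = stats::binomial())
    hosmer_lemeshow(stats::fitted(fit), y)$p
  })
  # coarse Kolmogorov check against uniformity
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("classification at the cutoff counts the confusion table", {
  # constructed 2x2: TP=6, FP=2, TN=5, FN=3
  p <- c(rep(0.8, 8), rep(0.3, 8))
  y <- c(rep(1, 6), rep(0, 2), rep(0, 5), rep(1, 3))
  cls <- classification_at_cutoff(p, y, cutoff = 0.65)
  expect_equal(cls$ppv, 0.75)
  expect_equal(cls$npv, 0.625)
  expect_equal(c(cls$tp, cls$fp, cls$tn, cls$fn), c(6, 2, 5, 3))

  perfect <- classification_at_cutoff(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.65)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  # cutoff 0 calls everyone positive: NPV undefined, not zero
  all_pos <- classification_at_cutoff(c(0.2, 0.8), c(0, 1), cutoff = 0)
  expect_true(is.na(all_pos$npv))
  expect_equal(all_pos$ppv, 0.5)
})

test_that("residual flags split radiosensitive from radioresistant", {
  r <- residual_flags(c(0.25, 0.75, 0.5, 0.5), c(1, 0, 1, 0))
  expect_equal(r$flag[1], "radiosensitive")   # 1 - 0.25 = 0.75
  expect_equal(r$flag[2], "radioresistant")   # 0 - 0.75 = -0.75
  expect_true(all(is.na(r$flag[3:4])))        # 0.5 never flagged at 0.7
})

test_that("bootstrap optimism corrects null-data discrimination to chance", {
  set.seed(191)
  x <- as.data.frame(matrix(rnorm(100 * 10), 100))
  names(x) <- paste0("f", 1:10)
  y <- rbinom(100, 1, 0.5)
  boot <- bootstrap_optimism(x, y, B = 200, recipe = "refit", seed = 555)
  m <- boot$metrics
  app <- m$apparent[m$metric == "auc"]
  corr <- m$corrected[m$metric == "auc"]
  expect_gt(app, 0.5)
  # correction removes most of the spurious discrimination
  expect_lt(corr, app)
  expect_lt(abs(corr - 0.5), 0.5 * abs(app - 0.5))
  # apparent slope of an MLE on its own data is 1; correction shrinks it
  expect_equal(m$apparent[m$metric == "slope"], 1, tolerance = 1e-6)
  expect_lte(m$corrected[m$metric == "slope"],
             m$apparent[m$metric == "slope"] + 1e-9)
})

test_that("B = 0 leaves apparent performance uncorrected", {
  set.seed(192)
  x <- data.frame(f1 = rnorm(60))
  y <- rbinom(60, 1, plogis(x$f1))
  boot <- bootstrap_optimism(x, y, B = 0, recipe = "refit")
  expect_equal(boot$metrics$optimism, rep(0, 3))
  expect_equal(boot$metrics$corrected, boot$metrics$apparent)
})

test_that("bootstrap is reproducible under a seed", {
  set.seed(193)
  x <- data.frame(f1 = rnorm(80), f2 = rnorm(80))
  y <- rbinom(80, 1, plogis(0.8 * x$f1))
  b1 <- bootstrap_optimism(x, y, B = 30, recipe = "refit", seed = 777)
  b2 <- bootstrap_optimism(x, y, B = 30, recipe = "refit", seed = 777)
  expect_identical(b1$metrics, b2$metrics)
})

test_that("external validation of a self-generated cohort is calibrated", {
  spec <- cohort_spec(3000, seed = 2024)
  co <- generate_cohort(spec)
  rep <- external_validate(reference_model(), co, cohort_label = "self")
  expect_lt(abs(rep$calibration$slope - 1), 3 * rep$calibration$slope_se)
  expect_lt(abs(rep$calibration$in_the_large),
            3 * rep$calibration$in_the_large_se)
  expect_gt(rep$auc, 0.55)
  expect_equal(rep$n, 3000)
})

test_that("a tripled-odds cohort shifts calibration-in-the-large by log 3", {
  spec <- cohort_spec(5000, seed = 2025)
  co <- generate_validation_shift(spec, odds_multiplier = 3)
  rep <- external_validate(reference_model(), co, cohort_label = "shifted")
  expect_equal(rep$calibration$in_the_large, log(3), tolerance = 0.1)
  expect_equal(rep$calibration$slope, 1, tolerance = 0.15)
})

test_that("external validation demands every model term", {
  spec <- cohort_spec(50, seed = 5)
  co <- generate_cohort(spec)
  co$smoking <- NULL
  expect_error(external_validate(reference_model(), co), "smoking")
})

test_that("external validation is a pure function of model file and cohort", {
  spec <- cohort_spec(300, seed = 77)
  co <- generate_cohort(spec)
  f <- withr::local_tempfile(fileext = ".json")
  write_ntcp_model(reference_model(), f)
  r1 <- external_validate(f, co)
  r2 <- external_validate(f, co)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$model$terms$estimate, reference_model()$terms$estimate)
})
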