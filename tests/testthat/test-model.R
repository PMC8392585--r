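test_that("intercept-only fit reproduces the closed-form MLE", {
  y <- rep(c(1L, 0L), c(90, 42))
  m <- fit_ntcp(tibble::tibble(.rows = 132), y)
  expect_equal(m$intercept, log(90 / 42), tolerance = 1e-8)
  expect_equal(m$fit_meta$n, 132)
  expect_equal(m$fit_meta$events, 90)
})

test_that("predict_ntcp evaluates the logistic linear predictor", {
  m <- reference_model()
  p <- predict_ntcp(m, list(cpg_d98 = 25.5, oc_eud = 60, age_5y = 10, smoking = 0))
  expect_equal(p, stats::plogis(-7.233 + 0.038 * 25.5 + 0.103 * 60 + 0.079 * 10),
               tolerance = 1e-12)
  expect_equal(p, 0.670, tolerance = 5e-3)

  # smoking multiplies the odds by exp(0.318)
  p_s <- predict_ntcp(m, list(cpg_d98 = 25.5, oc_eud = 60, age_5y = 10, smoking = 1))
  expect_equal((p_s / (1 - p_s)) / (p / (1 - p)), exp(0.318), tolerance = 1e-10)
  expect_gt(p_s, p)

  # all-zero covariates with a zero intercept give one half
  m0 <- ntcp_model(0, tibble::tibble(term = "x", estimate = 1, std_error = 1))
  expect_equal(predict_ntcp(m0, list(x = 0)), 0.5)

  expect_error(predict_ntcp(m, list(cpg_d98 = 25, oc_eud = 60, age_5y = 10)),
               "smoking")
  expect_warning(
    predict_ntcp(m, list(cpg_d98 = 25, oc_eud = 60, age_5y = 50, smoking = 0)),
    "5-year units"
  )
})

test_that("predict_ntcp is increasing in positive-coefficient covariates", {
  m <- reference_model()
  base <- list(cpg_d98 = 25, oc_eud = 60, age_5y = 10, smoking = 0)
  p0 <- predict_ntcp(m, base)
  for (term in c("cpg_d98", "oc_eud", "age_5y", "smoking")) {
    up <- base
    up[[term]] <- up[[term]] + 1
    expect_gt(predict_ntcp(m, up), p0)
  }
})

test_that("odds ratios exponentiate coefficients and Wald bounds", {
  m <- ntcp_model(0, tibble::tibble(term = c("a", "b"),
                                    estimate = c(0.103, 0),
                                    std_error = c(0.043, 0.2)))
  or <- odds_ratios(m)
  expect_equal(log(or$or), m$terms$estimate, tolerance = 1e-15)
  expect_equal(or$or[2], 1)
  # CI symmetric in log space
  expect_equal(log(or$ci_high[2]), -log(or$ci_low[2]), tolerance = 1e-12)
  rounded <- odds_ratios(m, digits = 2)
  expect_equal(rounded$or[1], 1.11)
  expect_equal(rounded$ci_low[1], 1.02)
  expect_equal(rounded$ci_high[1], 1.21)
})

test_that("coefficients are recovered from cohorts simulated at n = 5000", {
  spec <- cohort_spec(5000, seed = 4242)
  co <- generate_cohort(spec)
  feats <- co[, c("cpg_d98", "oc_eud", "age_5y", "smoking")]
  fit <- fit_ntcp(feats, co$event)
  truth <- reference_model()$terms
  for (i in seq_len(nrow(truth))) {
    est <- fit$terms[fit$terms$term == truth$term[i], ]
    expect_lt(abs(est$estimate - truth$estimate[i]), 2 * est$std_error)
  }
  expect_lt(abs(fit$intercept - (-7.233)), 2 * fit$fit_meta$intercept_se)
})

test_that("fit_ntcp flags separation and degenerate outcomes", {
  x <- tibble::tibble(z = c(rep(0, 10), rep(1, 10)))
  y <- c(rep(0L, 10), rep(1L, 10))
  expect_error(fit_ntcp(x, y), "separation")
  expect_error(lasso_select(tibble::tibble(a = rnorm(30), b = rnorm(30)),
                            rep(1L, 30)),
               "both classes")
})

test_that("LASSO screens noise out and true signals in", {
  set.seed(131)
  empty_ish <- replicate(10, {
    x <- as.data.frame(matrix(rnorm(200 * 10), 200))
    names(x) <- paste0("f", 1:10)
    y <- rbinom(200, 1, 0.5)
    length(lasso_select(x, y, rule = "1se", seed = sample.int(1e6, 1)))
  })
  expect_gte(mean(empty_ish <= 1), 0.9)

  set.seed(132)
  hits <- replicate(10, {
    x <- data.frame(f1 = rnorm(400), f2 = rnorm(400), f3 = rnorm(400))
    y <- rbinom(400, 1, plogis(1.0 * x$f1))
    "f1" %in% lasso_select(x, y, seed = sample.int(1e6, 1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("LASSO drops zero-variance features and survives duplicates", {
  set.seed(133)
  x <- data.frame(f1 = rnorm(100), const = rep(1, 100))
  x$dup <- x$f1
  y <- rbinom(100, 1, plogis(1.5 * x$f1))
  expect_warning(sel <- lasso_select(x, y, seed = 1), "zero-variance")
  expect_false("const" %in% sel)
  expect_true(all(sel %in% c("f1", "dup")))
})

test_that("fold seeding makes selection reproducible", {
  set.seed(134)
  x <- as.data.frame(matrix(rnorm(150 * 6), 150))
  names(x) <- paste0("f", 1:6)
  y <- rbinom(150, 1, plogis(0.8 * x$f1 - 0.5 * x$f2))
  expect_identical(lasso_select(x, y, seed = 99), lasso_select(x, y, seed = 99))
})

test_that("model JSON round-trips losslessly", {
  m <- reference_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_ntcp_model(m, f, seed = 7)
  m2 <- read_ntcp_model(f)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$terms$estimate, m$terms$estimate)
  expect_equal(m2$terms$std_error, m$terms$std_error)
  expect_equal(m2$eud_params, m$eud_params)
  # byte-identical rewrite
  f2 <- withr::local_tempfile(fileext = ".json")
  write_ntcp_model(m2, f2, seed = 7)
  expect_identical(readLines(f), readLines(f2))
})

test_that("nomogram points agree with direct prediction", {
  m <- reference_model()
  ranges <- list(cpg_d98 = c(5, 55), oc_eud = c(40, 75),
                 age_5y = c(3.6, 16.2), smoking = c(0, 1))
  nom <- build_nomogram(m, ranges)
  # the widest beta*range axis spans exactly 0-100 points
  expect_equal(max(nom$axes$max_points), 100)

  set.seed(141)
  for (i in 1:20) {
    cov <- list(cpg_d98 = runif(1, 5, 55), oc_eud = runif(1, 40, 75),
                age_5y = runif(1, 3.6, 16.2), smoking = sample(0:1, 1))
    pts <- nomogram_points(nom, cov)
    expect_equal(pts$probability, predict_ntcp(m, cov), tolerance = 1e-12)
    # reading rounded points off the printed scale stays within the
    # half-point rounding budget on the probability scale
    pts_r <- nomogram_points(nom, cov, round_points = 0)
    expect_lt(abs(pts_r$total_points - pts$total_points), 0.5 * 4 + 1e-9)
    expect_lt(abs(pts_r$probability - pts$probability),
              0.25 * 2 * nom$scale / 100 + 1e-9)
  }
})

test_that("nomogram point allocation is scale invariant", {
  m <- reference_model()
  doubled <- m
  doubled$terms$estimate <- doubled$terms$estimate * 2
  ranges <- list(cpg_d98 = c(5, 55), oc_eud = c(40, 75),
                 age_5y = c(3.6, 16.2), smoking = c(0, 1))
  n1 <- build_nomogram(m, ranges)
  n2 <- build_nomogram(doubled, ranges)
  expect_equal(n2$axes$points_per_unit, n1$axes$points_per_unit)
  cov <- list(cpg_d98 = 30, oc_eud = 60, age_5y = 10, smoking = 1)
  expect_equal(nomogram_points(n2, cov)$total_points,
               nomogram_points(n1, cov)$total_points)
  expect_false(isTRUE(all.equal(nomogram_points(n2, cov)$probability,
                                nomogram_points(n1, cov)$probability)))

  # a single binary term scores the full 100 points
  m1 <- ntcp_model(-2, tibble::tibble(term = "smoking", estimate = 0.7,
                                      std_error = 0.2))
  nb <- build_nomogram(m1, list(smoking = c(0, 1)))
  expect_equal(nomogram_points(nb, list(smoking = 1))$total_points, 100)
  expect_error(build_nomogram(m1, list(smoking = c(1, 1))), "max > min")
})
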