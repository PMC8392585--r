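test_that("read_dvh parses and normalises planning-system exports", {
  tab <- data.frame(dose = c(0, 40, 70), volume = c(50, 50, 0))
  d <- read_dvh(tab, dvh_dialect(form = "cumulative", organ = "cPG"))
  expect_s3_class(d, "dvh")
  expect_equal(d$total_volume, 50)
  expect_equal(d$dose_edges, c(0, 40, 70))

  # same curve in cGy and percent converts to the identical DVH
  tab2 <- data.frame(dose = c(0, 4000, 7000), volume = c(100, 100, 0))
  d2 <- read_dvh(tab2, dvh_dialect(units_dose = "cGy", units_volume = "percent",
                                   form = "cumulative", total_volume_cc = 50,
                                   organ = "cPG"))
  expect_equal(d2$dose_edges, d$dose_edges)
  expect_equal(d2$volume, d$volume)
  expect_equal(d2$total_volume, d$total_volume)

  # CSV file round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_dvh(d, f)
  d3 <- read_dvh(f, dvh_dialect(form = "cumulative", organ = "cPG"))
  expect_equal(d3$volume, d$volume)
})

test_that("invalid curves are rejected with the offending row", {
  tab <- data.frame(dose = c(0, 40, 70), volume = c(50, 55, 0))
  expect_error(read_dvh(tab, dvh_dialect(form = "cumulative")),
               "increases with dose at row 2")
  expect_error(dvh(c(0, 40, 40), c(1, 1, 0), form = "cumulative"),
               "strictly increasing")
  expect_error(dvh(c(0, 40, 70), c(5, -1), form = "differential"),
               "non-negative")
  expect_error(dvh_dialect(units_volume = "percent"), "total_volume_cc")
})

test_that("cumulative differencing matches the worked example", {
  d <- dvh(c(0, 40, 70), c(50, 50, 0), form = "cumulative")
  dd <- to_differential(d)
  expect_equal(dd$volume, c(0, 50))
  expect_equal(sum(dd$volume), d$total_volume)
  expect_error(to_differential(dd), "already differential")

  u <- uniform_dvh(50, 60)
  expect_equal(sum(u$volume > 0), 1L)
})

test_that("cumulative and differential forms are exact inverses", {
  set.seed(11)
  for (i in 1:25) {
    d <- random_dvh()
    back <- to_differential(to_cumulative(d))
    expect_equal(back$volume, d$volume, tolerance = 1e-9)
    expect_equal(back$dose_edges, d$dose_edges)
    cum <- to_cumulative(d)
    back2 <- to_cumulative(to_differential(cum))
    expect_equal(back2$volume, cum$volume, tolerance = 1e-9)
  }
})

test_that("combine_organs pools volumes and conserves dose", {
  a <- uniform_dvh(20, 30, "PG_L")
  b <- uniform_dvh(40, 30, "PG_R")
  comb <- combine_organs(a, b, organ = "cPG")
  s <- summarize_dvh(comb)
  expect_equal(s$volume_cc, 60)
  expect_equal(s$mean_dose, 30)  # (30*20 + 30*40) / 60

  # identity against an empty organ
  empty <- dvh(c(0, 1), 0, form = "differential")
  same <- combine_organs(a, empty)
  expect_equal(summarize_dvh(same)$mean_dose, 20)
  expect_equal(same$total_volume, 30)

  # self-combination doubles volume but leaves the relative DVH and the
  # EUD unchanged at every n
  dbl <- combine_organs(a, a)
  expect_equal(dbl$total_volume, 2 * a$total_volume)
  expect_equal(eud_grid(dbl)$eud, eud_grid(a)$eud, tolerance = 1e-9)

  # conservation on random pairs: total volume and integral dose
  set.seed(21)
  for (i in 1:15) {
    x <- random_dvh(); y <- random_dvh()
    cxy <- combine_organs(x, y)
    expect_equal(cxy$total_volume, x$total_volume + y$total_volume,
                 tolerance = 1e-9)
    expect_equal(integral_dose(cxy), integral_dose(x) + integral_dose(y),
                 tolerance = 1e-6)
  }
})

test_that("dose_at_volume interpolates the cumulative curve", {
  # v(D) = 1 for D <= 30, (70 - D)/40 for 30 < D <= 70
  d <- dvh(c(0, 30, 70), c(50, 50, 0), form = "cumulative")
  expect_equal(dose_at_volume(d, 0.98), 30.8)
  expect_equal(dose_at_volume(d, 1.0), 30)
  expect_equal(dose_at_volume(d, 0.5), 50)
  expect_error(dose_at_volume(d, 0), "in \\(0, 1\\]")
  expect_error(dose_at_volume(d, 1.2), "in \\(0, 1\\]")

  u <- uniform_dvh(50, 60)
  expect_equal(dose_at_volume(u, 0.98), 50, tolerance = 0.1)

  # non-increasing in the volume fraction
  set.seed(31)
  for (i in 1:10) {
    r <- random_dvh()
    fr <- sort(runif(8, 0.05, 1))
    ds <- vapply(fr, function(f) dose_at_volume(r, f), numeric(1))
    expect_true(all(diff(ds) <= 1e-9))
  }
})

test_that("summarize_dvh returns consistent dose metrics", {
  u <- uniform_dvh(50, 60)
  s <- summarize_dvh(u)
  expect_equal(s$mean_dose, 50)
  expect_equal(s$max_dose, 50, tolerance = 0.1)
  expect_equal(s$d98, 50, tolerance = 0.1)
  expect_equal(s$volume_cc, 60)

  two <- dvh(c(15, 25, 55, 65), c(30, 0, 30), form = "differential")
  expect_equal(summarize_dvh(two)$mean_dose, 40)

  expect_error(summarize_dvh(dvh(c(0, 1), 0, form = "differential")),
               "zero total volume")

  set.seed(41)
  for (i in 1:25) {
    s <- summarize_dvh(random_dvh())
    expect_true(s$d98 <= s$mean_dose + 1e-9)
    expect_true(s$mean_dose <= s$max_dose + 1e-9)
    expect_true(s$d98 >= 0)
  }
})
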