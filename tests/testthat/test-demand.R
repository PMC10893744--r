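test_that("trend fit recovers flat and geometric series", {
  flat <- fit_incidence_trend(data.frame(year = 2019:2021,
                                         count = c(1000, 1000, 1000)))
  expect_equal(flat$growth, 1.0)

  yrs <- 2010:2021
  geo <- 900 * 1.025^(yrs - 2010)
  fit <- fit_incidence_trend(data.frame(year = yrs, count = geo))
  expect_equal(fit$growth, 1.025, tolerance = 1e-6)
  # closed-form least-squares oracle agrees
  expect_equal(fit$slope, ols_log_slope(yrs, geo), tolerance = 1e-10)
  # fit -> project reproduces the generating series
  proj <- project_incidence(fit, 2022:2026)
  expect_equal(unname(year_totals(proj)),
               900 * 1.025^(2022:2026 - 2010), tolerance = 1e-6)
})

test_that("trend fit rejects degenerate inputs", {
  expect_error(fit_incidence_trend(data.frame(year = 2020:2021, count = c(1, 2))),
               "at least 3", class = "pancwf_validation_error")
  expect_error(fit_incidence_trend(data.frame(year = 2019:2021, count = c(0, 0, 0))),
               "degenerate", class = "pancwf_validation_error")
  # zero counts are handled through the log offset
  withzero <- fit_incidence_trend(data.frame(year = 2019:2022,
                                             count = c(0, 2, 4, 8)))
  expect_gt(withzero$growth, 1)
})

test_that("fitted growth interval covers the truth in most Poisson replicates", {
  set.seed(42)
  yrs <- 2010:2021
  mu <- 900 * 1.025^(yrs - 2010)
  covered <- vapply(seq_len(500), function(i) {
    fit <- fit_incidence_trend(data.frame(year = yrs, count = rpois(12, mu)))
    ci <- confint(fit)
    ci[1] <= 1.025 && 1.025 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("projection with growth factor 1 holds the last observed level", {
  fit <- fit_incidence_trend(data.frame(year = 2019:2022, count = rep(991, 4)))
  proj <- project_incidence(fit, 2023:2027)
  expect_equal(unname(year_totals(proj)), rep(991, 5))
  expect_error(project_incidence(fit, 2022:2025),
               class = "pancwf_validation_error")
})

test_that("one year of constant growth from 991 lands near 1013.8", {
  yrs <- 2012:2023
  fit <- fit_incidence_trend(data.frame(year = yrs,
                                        count = 991 * 1.023^(yrs - 2023)))
  expect_equal(unname(predict(fit, 2024)), 1013.8, tolerance = 0.1)
})

test_that("stage decomposition multiplies totals by shares and conserves them", {
  tot <- case_table_totals(2023, 991)
  ct <- apply_stage_distribution(tot, fixture_shares)
  expect_equal(unname(pancwf:::stage_cells(ct, 2023)), c(198.2, 297.3, 495.5))
  expect_equal(unname(round_display(pancwf:::stage_cells(ct, 2023))),
               c(198, 297, 496))
  expect_equal(sum(pancwf:::stage_cells(ct, 2023)), 991)

  zeros <- apply_stage_distribution(case_table_totals(2023, 0), fixture_shares)
  expect_equal(unname(pancwf:::stage_cells(zeros, 2023)), c(0, 0, 0))

  exact <- apply_stage_distribution(case_table_totals(2023, 1000), fixture_shares)
  expect_equal(unname(pancwf:::stage_cells(exact, 2023)), c(200, 300, 500))

  expect_error(apply_stage_distribution(exact, fixture_shares),
               class = "pancwf_validation_error")
})

test_that("remoteness allocation is proportional and conserves every cell", {
  ct <- make_ct(years = 2023, cells = rbind(c(400, 0, 0)), totals = 400)
  strat <- allocate_by_remoteness(ct, fixture_bands)
  early <- strat[strat$stage == "I-II", ]
  expect_equal(round_display(early$cases[match(mm_bands(), early$band)]),
               c(324, 23, 24, 29))

  all_metro <- allocate_by_remoteness(ct, remoteness_shares(c(1, 0, 0, 0)))
  metro <- all_metro[all_metro$band == "metropolitan" & all_metro$stage == "I-II", ]
  expect_equal(metro$cases, 400)

  # conservation property over randomised tables
  set.seed(7)
  for (i in 1:20) {
    rct <- make_ct(cells = matrix(runif(9, 0, 600), 3))
    w <- runif(4); w <- w / sum(w)
    st <- allocate_by_remoteness(rct, remoteness_shares(w))
    agg <- stats::aggregate(cases ~ year + stage, data = as.data.frame(st), FUN = sum)
    m <- merge(agg, as.data.frame(rct), by = c("year", "stage"))
    expect_true(all(abs(m$cases.x - m$cases.y) < 1e-9))
  }

  expect_error(allocate_by_remoteness(strat, fixture_bands),
               class = "pancwf_validation_error")
})
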