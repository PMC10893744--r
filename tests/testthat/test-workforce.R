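test_that("supply trends recover constant and geometric series", {
  flat <- workforce_series(data.frame(profession = "x", year = 2019:2023,
                                      headcount = rep(500, 5)))
  expect_equal(fit_supply_trend(flat, "x")$growth, 1.0)

  geo <- workforce_series(data.frame(profession = "x", year = 2019:2023,
                                     headcount = round(1000 * 1.056^(0:4))))
  fit <- fit_supply_trend(geo, "x")
  expect_equal(fit$growth, 1.056, tolerance = 1e-3)
  exact <- fit_incidence_trend(data.frame(year = 2019:2023,
                                          count = 1000 * 1.056^(0:4)))
  expect_equal(exact$growth, 1.056, tolerance = 1e-6)

  expect_error(fit_supply_trend(flat, "endocrinology"),
               "endocrinology", class = "pancwf_validation_error")
})

test_that("the endocrinology fixture series grows about 5.6% per year", {
  fx <- victoria_fixture()
  fit <- fit_supply_trend(fx$workforce, "endocrinology")
  expect_equal(fit$growth, 1.056, tolerance = 0.003)
  # closed-form least-squares oracle on the printed series
  endo <- fx$workforce[fx$workforce$profession == "endocrinology", ]
  expect_equal(fit$slope, ols_log_slope(endo$year, endo$headcount),
               tolerance = 1e-10)
})

test_that("supply projection is geometric from the base year", {
  base <- workforce_series(data.frame(profession = "y", year = 2019:2023,
                                      headcount = rep(100, 5)))
  trend <- fit_supply_trend(base, "y")
  trend$slope <- log(1.1); trend$growth <- 1.1 # known growth, base 100 at 2023
  expect_equal(unname(predict(trend, 2024:2026)),
               c(110, 121, 133.1), tolerance = 1e-9)
  proj <- project_supply(trend, 2024:2026)
  expect_equal(proj$headcount, c(110, 121, 133))
  expect_error(project_supply(trend, 2023:2025),
               class = "pancwf_validation_error")
})

test_that("gap ratios divide demand by supply and flag zero-supply cells", {
  fx <- victoria_fixture()
  demand <- case_table(data.frame(
    year = 2023, stage = "I-II", band = mm_bands(),
    cases = c(324, 23, 24, 29)))
  gap <- compute_gap(demand, fx$workforce_by_band)
  gs_metro <- gap[gap$profession == "general_surgery" & gap$band == "metropolitan", ]
  expect_equal(gs_metro$cases_per_specialist, 324 / 3174, tolerance = 1e-9)
  expect_equal(round(gs_metro$cases_per_specialist, 3), 0.102)

  ro <- gap[gap$profession == "radiation_oncology" &
              gap$band == "medium_small_rural_plus", ]
  expect_equal(ro$supply, 0)
  expect_true(ro$shortage)
  expect_true(is.na(ro$cases_per_specialist))
  tn <- attr(gap, "travel_necessity")
  expect_true(nrow(tn) >= 1)
  expect_true(any(tn$profession == "radiation_oncology"))

  # no demand, no shortage, whatever the supply
  none <- case_table(data.frame(year = 2023, stage = "I-II", band = mm_bands(),
                                cases = rep(0, 4)))
  gap0 <- compute_gap(none, fx$workforce_by_band)
  expect_false(any(gap0$shortage))

  expect_error(compute_gap(demand, fx$workforce_by_band,
                           professions = "astrology"),
               "astrology", class = "pancwf_validation_error")
  expect_error(compute_gap(fx$cases, fx$workforce_by_band),
               class = "pancwf_validation_error")
})

test_that("gap ratios scale linearly with demand and inversely with supply", {
  fx <- victoria_fixture()
  d1 <- case_table(data.frame(year = 2023, stage = "I-II", band = mm_bands(),
                              cases = c(100, 10, 10, 10)))
  d2 <- case_table(data.frame(year = 2023, stage = "I-II", band = mm_bands(),
                              cases = 2 * c(100, 10, 10, 10)))
  g1 <- compute_gap(d1, fx$workforce_by_band, professions = "general_surgery")
  g2 <- compute_gap(d2, fx$workforce_by_band, professions = "general_surgery")
  expect_equal(g2$cases_per_specialist, 2 * g1$cases_per_specialist)
  expect_equal(g1$cases_per_specialist * g1$supply, g1$demand, tolerance = 1e-12)
})
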