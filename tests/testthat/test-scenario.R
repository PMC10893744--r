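fixture_2023 <- c("I-II" = 198, "III" = 297, "IV" = 495)

test_that("single-year stage shift reproduces the published 2023 scenario cells", {
  sc70 <- stage_shift_scenario("base case", r = 0.7)
  out <- apply_stage_shift(fixture_2023, 991, sc70)
  expect_equal(unname(round_display(out)), c(598, 244, 149))
  expect_equal(sum(out), 991)

  sc20 <- stage_shift_scenario("20%", r = 0.2)
  expect_equal(unname(round_display(apply_stage_shift(fixture_2023, 991, sc20))),
               c(351, 244, 396))
})

test_that("the identity scenario is a no-op and infeasible scenarios error", {
  ident <- stage_shift_scenario("identity", r = 0, q = 1)
  expect_identical(apply_stage_shift(fixture_2023, 991, ident), fixture_2023)

  ct <- victoria_fixture()$cases
  expect_identical(build_scenario_table(ct, ident)$cases, ct$cases)

  infeasible <- stage_shift_scenario("bad", r = 0.1, q = 1)
  expect_error(apply_stage_shift(c("I-II" = 0, "III" = 600, "IV" = 500), 1000,
                                 infeasible),
               class = "pancwf_infeasible_error")
})

test_that("scenario tables match the published rows", {
  ct <- victoria_fixture()$cases
  sc50 <- stage_shift_scenario("50%", r = 0.5)
  t50 <- build_scenario_table(ct, sc50)
  expect_equal(unname(round_display(pancwf:::stage_cells(t50, 2023))),
               c(499, 244, 248))

  sc70 <- stage_shift_scenario("70%", r = 0.7)
  t70 <- build_scenario_table(ct, sc70)
  expect_equal(round_display(pancwf:::stage_cells(t70, 2024)[["IV"]]), 154)

  empty <- case_table(data.frame(year = integer(), stage = character(),
                                 cases = numeric()))
  expect_equal(nrow(build_scenario_table(empty, sc70)), 0L)
})

test_that("every scenario conserves year totals exactly and is monotone in r", {
  ct <- victoria_fixture()$cases
  set.seed(11)
  for (r in c(runif(10), 0, 1)) {
    sct <- build_scenario_table(ct, stage_shift_scenario("s", r = r))
    sums <- rowSums(pancwf:::case_matrix(sct))
    expect_equal(unname(sums), unname(year_totals(ct)), tolerance = 1e-12)
  }
  rs <- seq(0, 1, by = 0.1)
  early <- vapply(rs, function(r)
    pancwf:::stage_cells(build_scenario_table(ct, stage_shift_scenario("s", r = r)),
                         2023)[["I-II"]], numeric(1))
  late <- vapply(rs, function(r)
    pancwf:::stage_cells(build_scenario_table(ct, stage_shift_scenario("s", r = r)),
                         2023)[["IV"]], numeric(1))
  expect_true(all(diff(early) > 0))
  expect_true(all(diff(late) < 0))
})

test_that("stage shift commutes with remoteness allocation", {
  ct <- victoria_fixture()$cases
  sc <- stage_shift_scenario("base case", r = 0.7)
  shift_then_alloc <- allocate_by_remoteness(build_scenario_table(ct, sc),
                                             fixture_bands)
  alloc_then_shift <- build_scenario_table(allocate_by_remoteness(ct, fixture_bands),
                                           sc)
  a <- as.data.frame(shift_then_alloc)
  b <- as.data.frame(alloc_then_shift)
  m <- merge(a, b, by = c("year", "stage", "band"))
  expect_equal(nrow(m), nrow(a))
  expect_true(all(abs(m$cases.x - m$cases.y) < 1e-9))
})

test_that("additional early-stage cases match the published 2023 increase", {
  fx <- victoria_fixture()
  t70 <- build_scenario_table(fx$cases, fx$scenarios[[3]])
  add <- additional_early_cases(t70, fx$cases)
  expect_equal(add$per_year$additional_display[add$per_year$year == 2023], 400)

  ident <- build_scenario_table(fx$cases, stage_shift_scenario("id", r = 0, q = 1))
  add0 <- additional_early_cases(ident, fx$cases)
  expect_true(all(add0$per_year$additional == 0))
  expect_equal(add0$cumulative, 0)

  short <- make_ct(years = 2023, cells = rbind(c(1, 1, 1)))
  expect_error(additional_early_cases(t70, short),
               class = "pancwf_validation_error")
})

test_that("lead time of one year equals the plain scenario table", {
  fx <- victoria_fixture()
  sc <- stage_shift_scenario("base case", r = 0.7, lead_time_years = 1)
  expect_equal(apply_lead_time(fx$cases, sc)$cases,
               build_scenario_table(fx$cases, sc)$cases)
})

test_that("five-year lead time pulls later early-stage gains into year one", {
  fx <- victoria_fixture()
  sc <- stage_shift_scenario("base case", r = 0.7, lead_time_years = 5)
  led <- apply_lead_time(fx$cases, sc)
  expect_true(isTRUE(attr(led, "experimental")))

  # direct-sum oracle, recomputed from the fixture cells without the engine:
  # first-year early cell = shifted early cell + following years' gains
  q <- 0.8216
  cells <- printed_status_quo
  tot <- printed_totals
  early_shift <- tot - q * cells[, 2] - 0.3 * cells[, 3]
  expected_first <- early_shift[["2023"]] +
    sum(early_shift[-1] - cells[-1, 1])
  got <- pancwf:::stage_cells(led, 2023)[["I-II"]]
  expect_equal(got, unname(expected_first), tolerance = 1e-9)
  # the first-year total grows by the pulled-forward gains
  expect_equal(unname(year_totals(led)["2023"]),
               991 + unname(sum(early_shift[-1] - cells[-1, 1])),
               tolerance = 1e-9)
  # later years are untouched
  expect_equal(pancwf:::stage_cells(led, 2025),
               pancwf:::stage_cells(build_scenario_table(fx$cases, sc), 2025))
})

test_that("lead time with no growth and no shift leaves year one unchanged", {
  flat <- make_ct(years = 2023:2027,
                  cells = matrix(rep(c(200, 300, 500), 5), ncol = 3, byrow = TRUE))
  sc <- stage_shift_scenario("null", r = 0, q = 1, lead_time_years = 5)
  led <- apply_lead_time(flat, sc)
  expect_equal(unname(pancwf:::stage_cells(led, 2023)), c(200, 300, 500))

  sc_long <- stage_shift_scenario("too long", r = 0.7, lead_time_years = 9)
  expect_error(apply_lead_time(flat, sc_long), class = "pancwf_validation_error")
})
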