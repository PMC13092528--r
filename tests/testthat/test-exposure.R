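test_that("the named drugs classify into their efficacy classes and
           unknown drugs are an explicit error", {
  expect_identical(classify_efficacy("natalizumab"), "high")
  expect_identical(classify_efficacy("fingolimod"), "intermediate")
  expect_identical(classify_efficacy("teriflunomide"), "low")
  expect_identical(classify_efficacy(" Ocrelizumab "), "high")
  expect_error(classify_efficacy("aspirin"), "unknown DMT")
})

test_that("exposure fractions follow the interval-intersection definition", {
  ws <- as.Date("2010-01-01"); we <- as.Date("2015-01-01")
  fr0 <- exposure_fractions(empty_treatments(), ws, we)
  expect_equal(fr0[["none"]], 1)
  expect_equal(sum(fr0), 1)

  half <- data.frame(patient_id = "A", dmt_name = "interferon-beta",
                     start_date = ws, stop_date = ws +
                       as.numeric(we - ws) / 2)
  fr <- exposure_fractions(half, ws, we)
  expect_equal(fr[["low"]], 0.5)
  expect_equal(fr[["none"]], 0.5)

  expect_error(exposure_fractions(half, ws, ws), "window")
})

test_that("exposure fractions equal a day-by-day enumeration oracle on
           random episode sets", {
  ws <- as.Date("2010-01-01"); we <- as.Date("2014-01-01")
  set.seed(17)
  for (i in 1:50) {
    ep <- normalize_episodes(rand_episodes(rpois(1, 3) + 1, ws, we))
    fr <- exposure_fractions(ep, ws, we)
    oracle <- daily_fraction_oracle(ep, ws, we)
    expect_equal(unname(fr[c("low", "intermediate", "high", "none")]),
                 unname(oracle), tolerance = 1e-12)
  }
})

test_that("majority and switch flags follow the strict >50% / >25% rules", {
  ws <- as.Date("2010-01-01"); we <- ws + 1000
  ep <- data.frame(
    patient_id = "A",
    dmt_name = c("interferon-beta", "natalizumab"),
    start_date = c(ws, ws + 600),
    stop_date = c(ws + 600, ws + 900))
  e <- daae_exposure(ep, ws, we)   # low 0.60, high 0.30, none 0.10
  expect_identical(e$majority, "low")
  expect_true(e$switch_flag)

  full <- data.frame(patient_id = "A", dmt_name = "interferon-beta",
                     start_date = ws, stop_date = we)
  e2 <- daae_exposure(full, ws, we)
  expect_identical(e2$majority, "low")
  expect_false(e2$switch_flag)

  exact_half <- data.frame(patient_id = "A", dmt_name = "interferon-beta",
                           start_date = ws, stop_date = ws + 500)
  expect_identical(daae_exposure(exact_half, ws, we)$majority,
                   "no_majority")
})

test_that("daae exposure is invariant to scaling the window and episodes", {
  ws <- as.Date("2010-01-01")
  for (scale in c(1, 2, 5)) {
    we <- ws + 400 * scale
    ep <- data.frame(patient_id = "A",
                     dmt_name = c("fingolimod", "rituximab"),
                     start_date = c(ws, ws + 240 * scale),
                     stop_date = c(ws + 240 * scale, ws + 360 * scale))
    e <- daae_exposure(ep, ws, we)
    expect_identical(e$majority, "intermediate")
    expect_true(e$switch_flag)   # high covers 0.30 > 0.25
  }
})

test_that("baseline DMT uses half-open episode intervals", {
  b <- as.Date("2012-06-01")
  cover <- data.frame(patient_id = "A", dmt_name = "interferon-beta",
                      start_date = b - 365, stop_date = b + 365)
  expect_identical(baseline_dmt(cover, b), "low")
  expect_identical(baseline_dmt(empty_treatments(), b), "none")
  ends_before <- data.frame(patient_id = "A", dmt_name = "interferon-beta",
                            start_date = b - 365, stop_date = b - 1)
  expect_identical(baseline_dmt(ends_before, b), "none")
  ends_on <- data.frame(patient_id = "A", dmt_name = "interferon-beta",
                        start_date = b - 365, stop_date = b)
  expect_identical(baseline_dmt(ends_on, b), "none")
})

test_that("the ELIE categories match the catalogue and the stated
           precedence for multi-pattern histories", {
  for (id in fixture_catalogue()) {
    fx <- make_fixture(id)
    got <- elie_history_category(fx$record$treatments,
                                 fx$record$baseline_date,
                                 max(fx$record$visits$date))$category
    expect_identical(got, fx$expected$elie_category, info = id)
  }
  # none -> low -> high: escalation outranks initiation
  ws <- as.Date("2010-01-01"); we <- ws + 1200
  ep <- data.frame(patient_id = "A",
                   dmt_name = c("interferon-beta", "natalizumab"),
                   start_date = c(ws + 400, ws + 800),
                   stop_date = c(ws + 800, NA))
  expect_identical(elie_history_category(ep, ws, we)$category,
                   "switcher_escalation")
})

test_that("the ELIE switcher flag uses the treated-time denominator", {
  ws <- as.Date("2010-01-01"); we <- ws + 1000
  # treated 70% of window; ~26% of treated time on high, but only 18% of
  # the whole window, so the two denominators disagree
  ep <- data.frame(patient_id = "A",
                   dmt_name = c("interferon-beta", "natalizumab"),
                   start_date = c(ws, ws + 520),
                   stop_date = c(ws + 520, ws + 700))
  e <- elie_history_category(ep, ws, we)
  expect_true(e$switch_flag)
  expect_false(daae_exposure(ep, ws, we)$switch_flag)
  expect_identical(daae_exposure(ep, ws, we)$majority, "low")
})

test_that("category assignment is total and single-valued on random
           histories and fractions always sum to one", {
  ws <- as.Date("2010-01-01"); we <- ws + 1500
  set.seed(8)
  cats <- elie_categories()
  for (i in 1:500) {
    ep <- normalize_episodes(rand_episodes(rpois(1, 4), ws, we))
    e <- elie_history_category(ep, ws, we)
    expect_length(e$category, 1L)
    expect_true(e$category %in% cats)
    expect_equal(sum(e$fractions), 1, tolerance = 1e-9)
  }
})
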