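test_that("the additive score hits its floor and ceiling and matches an
           independent re-summation on random inputs", {
  wt <- demo_weight_table()
  expect_identical(compute_daae_score(1, 25, 24, 0), 0L)
  expect_identical(compute_daae_score(10, 50, 40, 6.5), 12L)

  set.seed(21)
  dur <- runif(200, 0, 30); age <- runif(200, 18, 75)
  onset <- pmax(age - dur, 12); edss <- sample(seq(0, 8, 0.5), 200, TRUE)
  got <- compute_daae_score(dur, age, onset, edss, wt)
  # brute-force re-evaluation of the bin lookups
  lk <- function(x, b) {
    vapply(x, function(v) b$points[max(which(b$lower <= v))], 0L)
  }
  oracle <- lk(dur, wt$bins$disease_duration) + lk(age, wt$bins$age) +
    lk(onset, wt$bins$age_at_onset) + lk(edss, wt$bins$edss)
  expect_identical(got, as.integer(pmin(oracle, 12)))
  expect_error(compute_daae_score(NA, 40, 30, 2), "disease_duration")
})

test_that("the score is monotone non-decreasing in EDSS with the demo
           table", {
  for (e in seq(0, 9, 0.5)) {
    expect_lte(compute_daae_score(5, 40, 35, e),
               compute_daae_score(5, 40, 35, e + 0.5))
  }
})

test_that("risk groups follow the outcome-specific cutoffs", {
  cl <- risk_group_schema("clinical"); ob <- risk_group_schema("objective")
  expect_identical(as.character(assign_risk_group(2, cl)), "very_low")
  expect_identical(as.character(assign_risk_group(3, cl)), "low")
  expect_identical(as.character(assign_risk_group(8, cl)), "medium")
  expect_identical(as.character(assign_risk_group(10, cl)), "high")
  expect_identical(as.character(assign_risk_group(1, ob)), "very_low")
  expect_identical(as.character(assign_risk_group(5, ob)), "medium")
  expect_identical(as.character(assign_risk_group(7, ob)), "high")
  # both schemas partition 0-12
  for (sch in list(cl, ob)) {
    expect_identical(sch$lower[1], 0); expect_identical(sch$upper[4], 12)
    expect_true(all(sch$lower[-1] == sch$upper[-4] + 1))
  }
})

test_that("the embedded risk table serves the published cells and rejects
           switch contexts", {
  tab <- daae_risk_table()
  expect_identical(nrow(tab), 56L)   # 7 contexts x 4 groups x 2 outcomes
  r <- lookup_risk("medium", "clinical", "unspecified", tab)
  expect_equal(unlist(r), c(risk = 22.6, ci_low = 21.1, ci_high = 24.1))
  r2 <- lookup_risk("low", "clinical", "majority_none", tab)
  expect_equal(r2$risk, 16.7)
  r3 <- lookup_risk("high", "objective", "majority_high", tab)
  expect_equal(unlist(r3), c(risk = 13.8, ci_low = 9.9, ci_high = 18.5))
  expect_error(lookup_risk("low", "clinical", "majority_switch", tab),
               "unsupported")
  # every risk sits inside its interval
  expect_true(all(tab$risk >= tab$ci_low & tab$risk <= tab$ci_high))
  # non-monotone published contexts are flagged, monotone ones are not
  expect_true(all(tab$nonmonotone_context[tab$outcome == "objective" &
                                            tab$dmt_context ==
                                              "baseline_high"]))
  expect_false(any(tab$nonmonotone_context[tab$dmt_context ==
                                             "unspecified"]))
})

test_that("the risk table round-trips its serialized form exactly", {
  tab <- daae_risk_table()
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$risk, tab$risk)
  expect_equal(back$ci_low, tab$ci_low)
  expect_equal(back$ci_high, tab$ci_high)
  expect_identical(back$dmt_context, tab$dmt_context)
})

test_that("risk ratios reproduce printed two-decimal values and the
           count-based CI agrees with a bootstrap oracle", {
  expect_equal(risk_ratio(6.6, 10.3), 0.64)
  expect_equal(risk_ratio(1, 1), 1)
  expect_error(risk_ratio(1, 0), "> 0")

  rr <- risk_ratio_counts(66, 1000, 103, 1000)
  expect_equal(rr$rr, 0.6407767, tolerance = 1e-6)
  set.seed(99)
  boot <- replicate(1e5, {
    (rbinom(1, 1000, 66 / 1000) / 1000) /
      max(rbinom(1, 1000, 103 / 1000) / 1000, 1e-9)
  })
  ci_boot <- unname(quantile(boot, c(0.025, 0.975)))
  expect_lt(max(abs(rr$ci - ci_boot)), 0.02)
})

test_that("derived weights give EDSS the largest point share when EDSS
           dominates the generative hazard and flag null outcomes", {
  set.seed(14)
  n <- 3000
  age <- runif(n, 20, 60); dur <- runif(n, 0, 20)
  onset <- pmax(age - dur, 12); edss <- sample(seq(0, 7, 0.5), n, TRUE)
  lp <- -2.5 + 0.9 * (edss - 2) + 0.02 * (age - 40)
  y <- rbinom(n, 1, plogis(lp))
  rows <- data.frame(disease_duration = dur, age = age,
                     age_at_onset = onset, edss = edss, label = y)
  dv <- derive_score_weights(rows, seed = 2)
  expect_false(dv$degenerate)
  shares <- vapply(dv$weights$bins, function(b) max(b$points), 0L)
  expect_identical(names(which.max(shares)), "edss")
  expect_lte(sum(shares), 12L)

  rows$label <- rbinom(n, 1, 0.2)   # outcome independent of everything
  dv0 <- derive_score_weights(rows, seed = 2)
  expect_true(dv0$degenerate)

  rows$label <- 1
  expect_error(derive_score_weights(rows), "degenerate outcome")
})
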