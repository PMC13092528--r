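make_lm_registry <- function() {
  # one patient with a clinician transition 3 years after the second visit,
  # one event-free patient with short follow-up
  b <- as.Date("2010-01-01")
  tiny_registry(list(
    list(id = "ev", baseline = "2010-01-01", n_visits = 8,
         spms = as.character(b + 183 + round(3 * 365.25))),
    list(id = "short", baseline = "2010-01-01", n_visits = 5)))
}

test_that("landmark labelling follows the half-open 5-year horizon and
           censors undeterminable rows", {
  reg <- make_lm_registry()
  lm <- build_landmark_dataset(reg, "clinical")
  ev_rows <- lm[lm$patient_id == "ev", ]
  # all retained visits precede the outcome date
  spms <- reg$patients$spms_transition_date[reg$patients$patient_id == "ev"]
  expect_true(all(ev_rows$landmark_date < spms))
  # the event is within 5 years of every such landmark here
  expect_true(all(ev_rows$outcome_label == 1L))
  # event-free patient with < 5y residual follow-up contributes nothing
  expect_false("short" %in% lm$patient_id)
  expect_gt(attr(lm, "dropped"), 0L)
})

test_that("an event exactly at landmark + horizon counts; one day later
           does not", {
  reg <- make_lm_registry()
  b <- as.Date("2010-01-01")
  reg$patients$spms_transition_date[1] <- b + 1826
  lm <- build_landmark_dataset(reg, "clinical")
  expect_identical(lm$outcome_label[lm$patient_id == "ev" &
                                      lm$landmark_date == b], 1L)
  reg$patients$spms_transition_date[1] <- b + 1827
  lm2 <- build_landmark_dataset(reg, "clinical")
  expect_identical(lm2$outcome_label[lm2$patient_id == "ev" &
                                       lm2$landmark_date == b], 0L)
})

test_that("predictors never use post-landmark information", {
  sim <- shared_sim()
  reg <- filter_registry(
    sim$registry,
    included_ids(apply_inclusion_criteria(sim$registry, "base")))
  lm <- build_landmark_dataset(reg, "clinical")
  # permute all visit data after each patient's FIRST landmark and check
  # that first-landmark rows are unchanged
  first <- lm[!duplicated(lm$patient_id), ]
  reg2 <- reg
  set.seed(33)
  for (pid in utils::head(first$patient_id, 40)) {
    lmd <- first$landmark_date[first$patient_id == pid]
    sel <- reg2$visits$patient_id == pid & reg2$visits$date > lmd
    reg2$visits$edss[sel] <-
      sample(seq(0, 9.5, 0.5), sum(sel), replace = TRUE)
  }
  lm2 <- build_landmark_dataset(reg2, "clinical")
  first2 <- lm2[!duplicated(lm2$patient_id), ]
  cols <- c("age", "disease_duration", "edss", "age_at_onset",
            "time_since_baseline", "dmt_history_category")
  key <- utils::head(first$patient_id, 40)
  expect_equal(first[match(key, first$patient_id), cols],
               first2[match(key, first2$patient_id), cols],
               ignore_attr = TRUE)
})

test_that("train/test and CV folds never split a patient, across seeds", {
  sim <- shared_sim()
  reg <- filter_registry(
    sim$registry,
    included_ids(apply_inclusion_criteria(sim$registry, "base")))
  lm <- build_landmark_dataset(reg, "clinical")
  for (s in 1:20) {
    sp <- split_by_patient(lm, 0.8, seed = s)
    expect_length(intersect(unique(sp$train$patient_id),
                            unique(sp$test$patient_id)), 0L)
  }
  sp <- split_by_patient(lm, 0.8, seed = 1)
  fit <- fit_elie(sp$train, seed = 1)
  # fold membership is defined per patient, so rows of one patient can
  # never land in different folds
  expect_true(all(names(fit$foldid_by_patient) ==
                    unique(sp$train$patient_id)))
  # determinism
  fit2 <- fit_elie(sp$train, seed = 1)
  expect_identical(fit$coefficients, fit2$coefficients)
  # same split fractions as specified
  ids <- unique(lm$patient_id)
  expect_identical(length(unique(sp$train$patient_id)),
                   as.integer(round(0.8 * length(ids))))
})

test_that("prediction equals a by-hand linear-predictor computation and
           responds monotonically to EDSS", {
  sim <- shared_sim()
  reg <- filter_registry(
    sim$registry,
    included_ids(apply_inclusion_criteria(sim$registry, "base")))
  lm <- build_landmark_dataset(reg, "clinical")
  sp <- split_by_patient(lm, 0.8, seed = 1)
  fit <- fit_elie(sp$train, seed = 1)
  rows <- utils::head(sp$test, 10)
  p <- predict_risk(fit, rows)
  # by hand: recipe then dot product
  rc <- fit$recipe
  eta <- rep(fit$coefficients[["(Intercept)"]], nrow(rows))
  for (v in c("age", "disease_duration", "edss", "age_at_onset",
              "time_since_baseline")) {
    x <- rows[[v]]; x[is.na(x)] <- rc$medians[[v]]
    eta <- eta + fit$coefficients[[v]] *
      (x - rc$centers[[v]]) / rc$scales[[v]]
  }
  for (lev in rc$category_levels[-1]) {
    eta <- eta + fit$coefficients[[paste0("cat_", lev)]] *
      (rows$dmt_history_category == lev)
  }
  expect_equal(p, plogis(eta), tolerance = 1e-12, ignore_attr = TRUE)

  if (fit$coefficients[["edss"]] > 0) {
    up <- rows; up$edss <- up$edss + 1
    expect_true(all(predict_risk(fit, up) >= p))
  }

  bad <- rows; bad$dmt_history_category[1] <- "mystery"
  expect_error(predict_risk(fit, bad), "unknown treatment-history")
})

test_that("an all-zero coefficient model predicts the constant intercept
           probability", {
  sim <- shared_sim()
  reg <- filter_registry(
    sim$registry,
    included_ids(apply_inclusion_criteria(sim$registry, "base")))
  lm <- build_landmark_dataset(reg, "clinical")
  fit <- fit_elie(lm, seed = 1)
  fit$coefficients[-1] <- 0
  fit$coefficients[1] <- qlogis(0.25)
  expect_equal(unique(predict_risk(fit, lm)), 0.25, tolerance = 1e-12)
})

test_that("the model card survives a JSON round trip", {
  sim <- shared_sim()
  reg <- filter_registry(
    sim$registry,
    included_ids(apply_inclusion_criteria(sim$registry, "base")))
  lm <- build_landmark_dataset(reg, "clinical")
  fit <- fit_elie(lm, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_elie_model(fit, f)
  back <- read_elie_model(f)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(predict_risk(back, utils::head(lm, 20)),
               predict_risk(fit, utils::head(lm, 20)))
})

test_that("decile boundaries come from training quantiles and test rows
           clamp into 1..10", {
  set.seed(10)
  tr <- runif(1000)
  te <- c(-1, 2, runif(98))
  d <- stratify_deciles(tr, te)
  expect_identical(d$test[1], 1L)
  expect_identical(d$test[2], 10L)
  expect_true(all(table(d$train) %in% 99:101))
  expect_equal(d$boundaries,
               unname(quantile(tr, seq(0.1, 0.9, 0.1))))
  expect_warning(stratify_deciles(rep(0.5, 50), runif(10)), "merged")
})
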