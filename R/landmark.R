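#' @title ELIE: dynamic landmark-based individualized risk estimation
#' @description Every eligible clinical visit becomes a landmark: the
#'   model predicts the 5-year progression risk from covariates frozen at
#'   that visit (age, disease duration, EDSS, age at onset, time since
#'   baseline) plus a ten-level summary of the treatment history from
#'   baseline to the landmark. Visits on/after the outcome are excluded
#'   and event-free landmarks with less than 5 years of subsequent
#'   follow-up are censored, so neither predictors nor labels use
#'   information they could not have had -- the landmark construction is
#'   what removes immortal-time bias.
#' @name elie_landmark
NULL

.elie_cont <- c("age", "disease_duration", "edss", "age_at_onset",
                "time_since_baseline")

#' Build the visit-level landmark dataset
#'
#' @param registry An `ms_registry`, already restricted to included
#'   patients.
#' @param outcome_source `"clinical"` (clinician SPMS label) or
#'   `"objective"` (confirmed progression detector).
#' @param horizon_years Fixed prediction horizon (5 years = 1826 days);
#'   the label interval is half-open `(landmark, landmark + horizon]`.
#' @param criteria [progression_criteria()] for the objective outcome.
#' @param gap_tolerance_days Passed to [elie_history_category()].
#' @return data.frame with one row per eligible landmark: `patient_id`,
#'   `landmark_date`, the five continuous covariates,
#'   `dmt_history_category`, `outcome_label`, `outcome_source`. A
#'   `dropped` attribute counts censored landmarks.
#' @export
build_landmark_dataset <- function(registry,
                                   outcome_source = c("clinical",
                                                      "objective"),
                                   horizon_years = 5,
                                   criteria = progression_criteria(),
                                   gap_tolerance_days = 0) {
  outcome_source <- match.arg(outcome_source)
  horizon_days <- round(horizon_years * 365.25)
  recs <- .split_registry(registry)
  rows <- vector("list", length(recs))
  dropped <- 0L
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    outcome_date <- if (outcome_source == "clinical") {
      d <- rec$spms_transition_date
      if (is.null(d) || length(d) == 0L) as.Date(NA) else d
    } else {
      ev <- detect_objective_progression(rec, criteria)
      if (is.null(ev)) as.Date(NA) else ev$event_date
    }
    v <- rec$visits
    v <- v[v$date >= rec$baseline_date & !is.na(v$edss), , drop = FALSE]
    if (nrow(v) == 0L) next
    last_fu <- max(v$date)
    if (!is.na(outcome_date)) {
      v <- v[v$date < outcome_date, , drop = FALSE]   # strictly prior
    }
    if (nrow(v) == 0L) next
    has_event <- !is.na(outcome_date)
    lab <- if (has_event) {
      as.integer(outcome_date <= v$date + horizon_days)
    } else {
      ok <- as.numeric(last_fu - v$date) >= horizon_days
      dropped <- dropped + sum(!ok)
      v <- v[ok, , drop = FALSE]
      if (nrow(v) == 0L) next
      rep(0L, nrow(v))
    }
    cat_k <- vapply(v$date, function(lm) {
      elie_history_category(rec$treatments, rec$baseline_date,
                            max(lm, rec$baseline_date + 1),
                            gap_tolerance_days = gap_tolerance_days)$category
    }, "")
    age <- as.numeric(v$date - rec$birth_date) / 365.25
    dur <- as.numeric(v$date - rec$onset_date) / 365.25
    rows[[i]] <- data.frame(
      patient_id = rec$patient_id, landmark_date = v$date,
      age = age, disease_duration = dur, edss = v$edss,
      age_at_onset = age - dur,
      time_since_baseline =
        as.numeric(v$date - rec$baseline_date) / 365.25,
      dmt_history_category = cat_k,
      outcome_label = lab, outcome_source = outcome_source,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Patient-level train/test split
#'
#' Splits at the patient level so all of a patient's landmark rows fall on
#' one side; no patient contributes to both sets.
#'
#' @param rows Landmark data.frame with `patient_id`.
#' @param train_fraction Fraction of patients assigned to training (0.8).
#' @param seed Integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_by_patient <- function(rows, train_fraction = 0.8, seed = 1) {
  stopifnot(nrow(rows) > 0)
  ids <- unique(rows$patient_id)
  set.seed(seed)
  n_train <- round(train_fraction * length(ids))
  train_ids <- sample(ids, n_train)
  list(train = rows[rows$patient_id %in% train_ids, , drop = FALSE],
       test = rows[!rows$patient_id %in% train_ids, , drop = FALSE])
}

## apply the learned preprocessing recipe; errors on unseen categories
.elie_design <- function(recipe, rows) {
  X <- matrix(0, nrow(rows), length(recipe$feature_names),
              dimnames = list(NULL, recipe$feature_names))
  for (v in .elie_cont) {
    x <- rows[[v]]
    x[is.na(x)] <- recipe$medians[[v]]
    X[, v] <- (x - recipe$centers[[v]]) / recipe$scales[[v]]
  }
  cats <- as.character(rows$dmt_history_category)
  unknown <- setdiff(unique(cats), recipe$category_levels)
  if (length(unknown)) {
    stop("unknown treatment-history category level(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (lev in recipe$category_levels[-1L]) {   # first level is reference
    X[, paste0("cat_", lev)] <- as.numeric(cats == lev)
  }
  X
}

#' Fit the ELIE model
#'
#' Class-weighted L1-penalized logistic regression on the landmark rows.
#' The preprocessing recipe (median imputation, one-hot encoding of the
#' ten-level treatment-history category against the never-treated
#' reference, standardization of continuous predictors) is learned on the
#' training data only. The penalty is selected at minimum cross-validated
#' class-weighted deviance over patient-grouped folds (folds never split
#' a patient). Class weights are `n_total / (2 * n_class)`.
#'
#' @param train_rows Landmark data.frame from [build_landmark_dataset()].
#' @param seed Integer seed (fold assignment).
#' @param n_folds Grouped CV folds (default 5).
#' @param nlambda Penalty grid size (default 100).
#' @return list of class `elie_model`: `recipe`, `coefficients`
#'   (including `(Intercept)`), `lambda`, `class_weights`, `seed`,
#'   `n_folds`, `foldid_by_patient`.
#' @export
fit_elie <- function(train_rows, seed = 1, n_folds = 5, nlambda = 100) {
  y <- train_rows$outcome_label
  if (length(unique(y)) < 2L) {
    stop("training outcome has a single class", call. = FALSE)
  }
  ids <- unique(train_rows$patient_id)
  if (length(ids) < n_folds) {
    stop("need at least n_folds patients", call. = FALSE)
  }
  recipe <- list(
    medians = lapply(train_rows[.elie_cont], stats::median, na.rm = TRUE),
    centers = lapply(train_rows[.elie_cont], mean, na.rm = TRUE),
    scales = lapply(train_rows[.elie_cont], function(x) {
      s <- stats::sd(x, na.rm = TRUE); if (is.na(s) || s == 0) 1 else s
    }),
    category_levels = elie_categories())
  recipe$feature_names <- c(.elie_cont,
                            paste0("cat_", recipe$category_levels[-1L]))

  X <- .elie_design(recipe, train_rows)
  w <- length(y) / (2 * ifelse(y == 1, sum(y == 1), sum(y == 0)))
  set.seed(seed)
  fold_of_patient <- stats::setNames(
    sample(rep_len(seq_len(n_folds), length(ids))), ids)
  foldid <- fold_of_patient[train_rows$patient_id]

  cv <- glmnet::cv.glmnet(X, y, family = "binomial", weights = w,
                          foldid = as.integer(foldid), alpha = 1,
                          nlambda = nlambda, standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(X))
  structure(list(recipe = recipe, coefficients = beta,
                 lambda = cv$lambda.min,
                 class_weights = c(`0` = length(y) / (2 * sum(y == 0)),
                                   `1` = length(y) / (2 * sum(y == 1))),
                 seed = seed, n_folds = n_folds,
                 foldid_by_patient = fold_of_patient),
            class = "elie_model")
}

#' @export
print.elie_model <- function(x, ...) {
  nz <- sum(x$coefficients[-1L] != 0)
  cat("ELIE model: ", nz, " of ", length(x$coefficients) - 1L,
      " predictors retained (lambda = ", signif(x$lambda, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Predict 5-year progression risk for landmark rows
#'
#' @param model An `elie_model`.
#' @param rows Landmark data.frame carrying the predictor columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, rows) {
  stopifnot(inherits(model, "elie_model"))
  X <- .elie_design(model$recipe, rows)
  eta <- drop(X %*% model$coefficients[-1L]) + model$coefficients[1L]
  stats::plogis(eta)
}

#' Decile stratification by training-prediction quantiles
#'
#' Decile boundaries are the training-set prediction quantiles (10
#' equal-count bins); test rows are assigned by those same boundaries and
#' clamped into deciles 1-10.
#'
#' @param train_predictions,test_predictions Numeric prediction vectors.
#' @return list with integer `train` and `test` decile assignments and
#'   the 9 `boundaries`.
#' @export
stratify_deciles <- function(train_predictions, test_predictions) {
  boundaries <- stats::quantile(train_predictions, probs = seq(0.1, 0.9, 0.1),
                                names = FALSE)
  if (length(unique(boundaries)) < 9L) {
    warning("fewer than 10 distinct prediction levels; ",
            "adjacent deciles merged")
  }
  assign <- function(p) {
    pmin(pmax(findInterval(p, boundaries) + 1L, 1L), 10L)
  }
  list(train = assign(train_predictions),
       test = assign(test_predictions), boundaries = boundaries)
}

#' Serialize / restore an ELIE model card
#'
#' Writes the recipe constants and coefficients as portable JSON so a fit
#' can be stored and reapplied without refitting.
#'
#' @param model An `elie_model`.
#' @param path Output (input) JSON path.
#' @return `path` (for write) or the restored `elie_model` (for read).
#' @export
write_elie_model <- function(model, path) {
  obj <- model
  obj$foldid_by_patient <- as.list(obj$foldid_by_patient)
  obj$coefficients <- as.list(obj$coefficients)   # keep the names in JSON
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_elie_model
#' @export
read_elie_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$recipe$category_levels <- unlist(obj$recipe$category_levels)
  obj$recipe$feature_names <- unlist(obj$recipe$feature_names)
  structure(obj, class = "elie_model")
}
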