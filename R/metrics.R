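#' @title Calibration and discrimination validation metrics
#' @name validation_metrics
NULL

#' Observed event proportion with Wilson confidence interval
#'
#' Wilson's score interval is used for observed proportions: it has
#' better small-count coverage than the Wald interval and never leaves
#' `[0, 1]`.
#'
#' @param events,n Event count and stratum size (`0 <= events <= n`,
#'   `n > 0`).
#' @param level Confidence level (default 0.95).
#' @return list with `proportion`, `ci` (length 2).
#' @export
observed_proportion_ci <- function(events, n, level = 0.95) {
  stopifnot(n > 0, events >= 0, events <= n)
  p <- events / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(proportion = p, ci = c(max(0, centre - half), min(1, centre + half)))
}

#' Two-sided pooled two-proportion z-test
#'
#' @param x1,n1,x2,n2 Event counts and totals of the two groups.
#' @return list with `z` and two-sided `p`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better calibrated.
#'
#' @param predictions Probabilities in `[0, 1]`.
#' @param labels Binary outcomes aligned with `predictions`.
#' @return Value in `[0, 1]`.
#' @export
brier_score <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels),
            length(predictions) > 0,
            all(predictions >= 0 & predictions <= 1),
            all(labels %in% c(0, 1)))
  mean((predictions - labels)^2)
}

#' SMOTE oversampling with Tomek-link cleaning
#'
#' The minority class is synthetically oversampled by convex
#' interpolation between each seed minority point and one of its `k`
#' minority nearest neighbours until the classes are equal in size; then
#' Tomek links (cross-class mutual nearest neighbours) are removed from
#' the majority class. Original minority points are never removed.
#'
#' @param features Numeric matrix (rows = samples).
#' @param labels Binary vector (0/1) aligned with rows.
#' @param k Number of minority nearest neighbours (default 10); the
#'   minority class must have more than `k` members.
#' @param seed RNG seed.
#' @return list with balanced `features`, `labels` and a logical
#'   `synthetic` marker per row.
#' @export
smote_tomek_balance <- function(features, labels, k = 10, seed = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(0, 1)))
  tab <- table(factor(labels, levels = c(0, 1)))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min <= k) {
    stop("minority class has ", n_min, " members; choose k < ", n_min,
         call. = FALSE)
  }
  set.seed(seed)
  synth <- NULL
  need <- n_maj - n_min
  if (need > 0) {
    idx_min <- which(labels == minority)
    Xm <- features[idx_min, , drop = FALSE]
    dm <- as.matrix(stats::dist(Xm))
    diag(dm) <- Inf
    nn <- t(apply(dm, 1L, function(d) order(d)[seq_len(k)]))
    seeds <- sample(seq_len(n_min), need, replace = TRUE)
    mates <- nn[cbind(seeds, sample(seq_len(k), need, replace = TRUE))]
    t_ <- stats::runif(need)
    synth <- Xm[seeds, , drop = FALSE] +
      t_ * (Xm[mates, , drop = FALSE] - Xm[seeds, , drop = FALSE])
  }
  X <- rbind(features, synth)
  y <- c(labels, rep(minority, NROW(synth)))
  synthetic <- c(rep(FALSE, length(labels)), rep(TRUE, NROW(synth)))

  ## Tomek links: mutual nearest neighbours with opposite labels; drop the
  ## majority member of each link
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nn1 <- apply(d, 1L, which.min)
  drop <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    j <- nn1[i]
    if (nn1[j] == i && y[i] != y[j]) {
      maj <- if (y[i] == minority) j else i
      drop[maj] <- TRUE
    }
  }
  list(features = X[!drop, , drop = FALSE], labels = y[!drop],
       synthetic = synthetic[!drop])
}

#' Rank-based AUROC and threshold accuracy with bootstrap CIs
#'
#' AUROC is computed as rank concordance (ties count one half);
#' accuracy classifies at 0.5. Percentile bootstrap CIs are taken over
#' `n_boot` class-stratified resamples.
#'
#' @param predictions Scores or probabilities.
#' @param labels Binary outcomes (both classes must be present).
#' @param n_boot Bootstrap resamples (default 2000); 0 skips the CIs.
#' @param seed RNG seed for the bootstrap.
#' @return list with `auroc`, `auroc_ci`, `accuracy`, `accuracy_ci`.
#' @export
auroc_accuracy <- function(predictions, labels, n_boot = 2000, seed = 1) {
  stopifnot(length(unique(labels)) == 2L)
  auc <- function(p, y) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    r <- rank(p, ties.method = "average")
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  acc <- function(p, y) mean((p >= 0.5) == (y == 1))
  est_auc <- auc(predictions, labels)
  est_acc <- acc(predictions, labels)
  auc_ci <- acc_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    i1 <- which(labels == 1); i0 <- which(labels == 0)
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      c(auc(predictions[idx], labels[idx]),
        acc(predictions[idx], labels[idx]))
    }, numeric(2))
    auc_ci <- unname(stats::quantile(bs[1, ], c(0.025, 0.975)))
    acc_ci <- unname(stats::quantile(bs[2, ], c(0.025, 0.975)))
  }
  list(auroc = est_auc, auroc_ci = auc_ci,
       accuracy = est_acc, accuracy_ci = acc_ci)
}

#' Multiple imputation by chained equations
#'
#' A compact chained-equations imputer: numeric columns are imputed by
#' predictive mean matching (donor pool of 5) on a linear regression of
#' the other columns; binary columns by logistic draws. Columns are
#' swept in order of missingness for a fixed number of sweeps, and `m`
#' completed copies are returned. Pooling across copies follows Rubin's
#' rules (mean of estimates, within + between variance).
#'
#' @param table data.frame of numeric and binary columns with missing
#'   values; at least one column must be complete.
#' @param m Number of completed copies (default 5).
#' @param seed RNG seed.
#' @param sweeps Chained-equation sweeps per copy (default 10).
#' @return list with `completed` (list of `m` data.frames) and
#'   `pooled` (per-column mean estimate with Rubin total variance).
#' @export
mice_impute <- function(table, m = 5, seed = 1, sweeps = 10) {
  stopifnot(is.data.frame(table), m >= 1)
  miss <- vapply(table, function(col) sum(is.na(col)), 0L)
  if (any(miss == nrow(table))) stop("all-missing column", call. = FALSE)
  set.seed(seed)
  cols <- names(sort(miss[miss > 0]))
  is_bin <- vapply(table, function(col) {
    all(stats::na.omit(col) %in% c(0, 1))
  }, TRUE)

  complete_once <- function() {
    imp <- table
    for (cn in cols) {   # initialize from observed marginals
      nas <- is.na(imp[[cn]])
      imp[[cn]][nas] <- sample(stats::na.omit(table[[cn]]), sum(nas),
                               replace = TRUE)
    }
    if (length(cols) == 0L) return(imp)
    for (s in seq_len(sweeps)) {
      for (cn in cols) {
        nas <- is.na(table[[cn]])
        others <- setdiff(names(imp), cn)
        dtrain <- imp[!nas, , drop = FALSE]
        dmiss <- imp[nas, , drop = FALSE]
        fml <- stats::reformulate(others, response = cn)
        if (is_bin[[cn]]) {
          fit <- suppressWarnings(
            stats::glm(fml, data = dtrain, family = stats::binomial()))
          p <- stats::predict(fit, newdata = dmiss, type = "response")
          imp[[cn]][nas] <- as.numeric(stats::runif(sum(nas)) < p)
        } else {
          fit <- stats::lm(fml, data = dtrain)
          pred_obs <- stats::fitted(fit)
          pred_mis <- stats::predict(fit, newdata = dmiss)
          ## predictive mean matching: draw among the 5 closest donors
          imp[[cn]][nas] <- vapply(pred_mis, function(pm) {
            donors <- order(abs(pred_obs - pm))[seq_len(min(5,
                                                            length(pred_obs)))]
            sample(dtrain[[cn]][donors], 1L)
          }, 0)
        }
      }
    }
    imp
  }

  completed <- lapply(seq_len(m), function(i) complete_once())
  pooled <- lapply(names(table), function(cn) {
    est <- vapply(completed, function(d) mean(d[[cn]]), 0)
    wvar <- vapply(completed, function(d) stats::var(d[[cn]]) / nrow(d), 0)
    bvar <- if (m > 1) stats::var(est) else 0
    c(estimate = mean(est),
      total_var = mean(wvar) + (1 + 1 / m) * bvar)
  })
  names(pooled) <- names(table)
  list(completed = completed, pooled = pooled)
}

#' Calibration table across ordered risk strata
#'
#' Compares observed event proportions with predicted risk per stratum
#' using a one-sample z-test against the predicted proportion, with
#' Bonferroni adjustment over the strata.
#'
#' @param strata Stratum labels (ordered by increasing predicted risk).
#' @param predicted Predicted risk (proportion in `[0, 1]`) per stratum.
#' @param observed_events,n Event counts and sizes per stratum.
#' @param bonferroni_m Number of comparisons (default: number of strata).
#' @return data.frame of class `calibration_table`: per-stratum `n`,
#'   `events`, `observed`, `ci_low`, `ci_high`, `predicted`, `z`, `p`,
#'   `p_adjusted`, plus a `monotone` attribute (observed proportions
#'   non-decreasing across the given stratum order).
#' @export
calibration_report <- function(strata, predicted, observed_events, n,
                               bonferroni_m = length(strata)) {
  stopifnot(length(strata) == length(predicted),
            length(strata) == length(observed_events),
            length(strata) == length(n))
  obs <- observed_events / n
  ci <- t(mapply(function(e, nn) observed_proportion_ci(e, nn)$ci,
                 observed_events, n))
  se <- sqrt(predicted * (1 - predicted) / n)
  z <- ifelse(se == 0, 0, (obs - predicted) / se)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(stratum = as.character(strata), n = n,
                    events = observed_events, observed = obs,
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    predicted = predicted, z = z, p = p,
                    p_adjusted = pmin(1, bonferroni_m * p))
  attr(out, "monotone") <- !is.unsorted(obs)
  class(out) <- c("calibration_table", "data.frame")
  out
}
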