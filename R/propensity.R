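#' @title Propensity-score matching for indication bias
#' @description Sicker patients preferentially receive high-efficacy
#'   therapy, so naive treated-group comparisons are confounded. Treatment
#'   groups are compared after nearest-neighbour 1:1 propensity-score
#'   matching without replacement, with the propensity modelled by
#'   logistic regression on the four baseline covariates: age, sex,
#'   disease duration and EDSS.
#' @name propensity_match
NULL

#' Estimate propensity scores
#'
#' @param data data.frame with columns `age`, `sex`, `disease_duration`,
#'   `edss` and a logical/0-1 `treated` column.
#' @return Numeric vector of fitted treatment probabilities in (0, 1).
#'   Perfect or quasi-perfect separation triggers a warning and a
#'   ridge-penalized refit so scores stay inside (0, 1).
#' @export
estimate_propensity <- function(data) {
  stopifnot(all(c("age", "sex", "disease_duration", "edss", "treated")
                %in% names(data)))
  if (length(unique(data$treated)) < 2L) {
    stop("both treatment labels must be present", call. = FALSE)
  }
  fit <- stats::glm(treated ~ age + sex + disease_duration + edss,
                    family = stats::binomial(), data = data)
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p < eps | p > 1 - eps)) {
    warning("(quasi-)separation in the propensity model; ",
            "falling back to a ridge-penalized fit")
    x <- stats::model.matrix(~ age + sex + disease_duration + edss,
                             data = data)[, -1, drop = FALSE]
    rf <- glmnet::glmnet(x, as.numeric(data$treated), family = "binomial",
                         alpha = 0, lambda = 1e-3)
    p <- as.numeric(stats::predict(rf, newx = x, type = "response"))
  }
  unname(p)
}

#' Greedy nearest-neighbour 1:1 matching without replacement
#'
#' Treated units are processed in a seeded random order; each takes the
#' unmatched control nearest in |logit propensity difference|, ties broken
#' by the lowest control id. No caliper is applied.
#'
#' @param treated_scores,control_scores Named numeric vectors of
#'   propensity scores (names = patient ids).
#' @param seed Integer seed for the processing order.
#' @return list of class `matched_cohort`: `pairs` (data.frame
#'   `treated_id`, `control_id`, `distance`), `unmatched_ids`.
#' @export
match_nearest_neighbor <- function(treated_scores, control_scores,
                                   seed = 1) {
  stopifnot(length(treated_scores) > 0, length(control_scores) > 0,
            !is.null(names(treated_scores)), !is.null(names(control_scores)))
  lt <- stats::qlogis(pmin(pmax(treated_scores, 1e-12), 1 - 1e-12))
  lc <- stats::qlogis(pmin(pmax(control_scores, 1e-12), 1 - 1e-12))
  lc <- lc[order(names(lc))]          # ties break toward lowest control id
  set.seed(seed)
  order_t <- sample(seq_along(lt))
  avail <- rep(TRUE, length(lc))
  pairs <- vector("list", min(length(lt), length(lc)))
  np <- 0L
  for (ti in order_t) {
    if (!any(avail)) break
    d <- abs(lc - lt[ti])
    d[!avail] <- Inf
    j <- which.min(d)
    np <- np + 1L
    pairs[[np]] <- data.frame(treated_id = names(lt)[ti],
                              control_id = names(lc)[j],
                              distance = d[j])
    avail[j] <- FALSE
  }
  out <- list(pairs = do.call(rbind, pairs[seq_len(np)]),
              unmatched_ids = c(
                setdiff(names(lt), vapply(pairs[seq_len(np)],
                                          function(p) p$treated_id, "")),
                names(lc)[avail]))
  rownames(out$pairs) <- NULL
  class(out) <- "matched_cohort"
  out
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("Matched cohort:", nrow(x$pairs), "pairs;",
      length(x$unmatched_ids), "unmatched\n")
  invisible(x)
}

#' Standardized mean difference of a covariate between two groups
#'
#' Absolute difference in means divided by the pooled standard deviation
#' (the usual balance diagnostic; binary covariates enter as 0/1).
#'
#' @param x Numeric covariate.
#' @param treated Logical group indicator aligned with `x`.
#' @return Non-negative SMD (0 when both groups are constant).
#' @export
standardized_mean_diff <- function(x, treated) {
  m1 <- mean(x[treated]); m0 <- mean(x[!treated])
  s <- sqrt((stats::var(x[treated]) + stats::var(x[!treated])) / 2)
  if (!is.finite(s) || s == 0) return(0)
  abs(m1 - m0) / s
}

#' Covariate balance before and after matching
#'
#' @param data data.frame with `patient_id`, `age`, `sex`,
#'   `disease_duration`, `edss`, `treated`.
#' @param matched A `matched_cohort` from [match_nearest_neighbor()].
#' @return data.frame with per-covariate SMD `before` and `after`.
#' @export
match_balance <- function(data, matched) {
  covs <- c("age", "sex_male", "disease_duration", "edss")
  data$sex_male <- as.numeric(data$sex == "male")
  after_ids <- c(matched$pairs$treated_id, matched$pairs$control_id)
  sub <- data[match(after_ids, data$patient_id), , drop = FALSE]
  data.frame(
    covariate = covs,
    before = vapply(covs, function(cv) {
      standardized_mean_diff(data[[cv]], as.logical(data$treated))
    }, 0),
    after = vapply(covs, function(cv) {
      standardized_mean_diff(sub[[cv]], as.logical(sub$treated))
    }, 0),
    row.names = NULL)
}
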