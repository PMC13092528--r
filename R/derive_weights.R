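#' Re-derive integer score weights from training data
#'
#' A simplified re-derivation of the score's development pipeline: (1) a
#' smooth additive logistic fit per feature (GAM) captures each feature's
#' marginal effect on the binary 5-year outcome; (2) the smooth effect is
#' cut into ordinal bins at quantile knots and made monotone
#' non-decreasing by isotonic regression (risk is assumed non-decreasing
#' in each feature); (3) the per-feature ordinal effects are entered into
#' an L1-penalized logistic regression which selects features; (4) the
#' retained effects are rescaled to non-negative integer points whose
#' maximum achievable total is 12.
#'
#' @param rows data.frame with columns `disease_duration`, `age`,
#'   `age_at_onset`, `edss` and a binary `label`.
#' @param n_bins Number of quantile bins per feature (default 4).
#' @param seed Seed for the cross-validated penalty selection.
#' @return list with `weights` (a [weight_table()]; all-zero and flagged
#'   when the penalty removes every feature), `coefficients` (the selected
#'   per-feature multipliers) and `degenerate` (logical).
#' @export
derive_score_weights <- function(rows, n_bins = 4, seed = 1) {
  feats <- c("disease_duration", "age", "age_at_onset", "edss")
  stopifnot(all(c(feats, "label") %in% names(rows)))
  y <- rows$label
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: all labels identical", call. = FALSE)
  }

  edges <- raw <- list()
  for (f in feats) {
    x <- rows[[f]]
    fit <- mgcv::gam(y ~ s(x, k = 5), family = stats::binomial(),
                     data = data.frame(x = x, y = y))
    lp <- as.numeric(stats::predict(fit, type = "link"))
    cuts <- unique(stats::quantile(x, probs = seq(0, 1,
                                                  length.out = n_bins + 1),
                                   names = FALSE))
    inner <- cuts[-c(1, length(cuts))]
    lower <- c(-Inf, inner); upper <- c(inner, Inf)
    bin_of <- findInterval(x, lower)
    eff <- tapply(lp, factor(bin_of, levels = seq_along(lower)), mean)
    eff[is.na(eff)] <- min(eff, na.rm = TRUE)
    eff <- stats::isoreg(seq_along(eff), eff)$yf   # monotone in the feature
    eff <- eff - eff[1L]
    edges[[f]] <- data.frame(lower = lower, upper = upper)
    raw[[f]] <- as.numeric(eff)
  }

  X <- vapply(feats, function(f) {
    raw[[f]][findInterval(rows[[f]], edges[[f]]$lower)]
  }, numeric(nrow(rows)))
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  beta <- stats::setNames(numeric(length(feats)), feats)
  if (any(keep)) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(cbind(X[, keep, drop = FALSE], jitter_ = 0),
                            y, family = "binomial", alpha = 1, nfolds = 5)
    co <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]
    beta[feats[keep]] <- pmax(utils::head(co, sum(keep)), 0)
  }

  degenerate <- all(beta * vapply(raw, max, 0) == 0)
  bins <- list()
  if (degenerate) {
    for (f in feats) {
      bins[[f]] <- data.frame(lower = -Inf, upper = Inf, points = 0L)
    }
  } else {
    scaled_max <- beta * vapply(raw, max, 0)
    scale <- 12 / sum(scaled_max)
    for (f in feats) {
      pts <- as.integer(round(beta[[f]] * raw[[f]] * scale))
      bins[[f]] <- data.frame(lower = edges[[f]]$lower,
                              upper = edges[[f]]$upper, points = pts)
    }
    ## rounding can push the achievable total above 12; shave the largest
    repeat {
      tot <- sum(vapply(bins, function(b) max(b$points), 0L))
      if (tot <= 12L) break
      big <- which.max(vapply(bins, function(b) max(b$points), 0L))
      b <- bins[[big]]
      b$points[which.max(b$points)] <- max(b$points) - 1L
      bins[[big]] <- b
    }
  }
  wt <- weight_table(bins, label = "derived from training data")
  attr(wt, "degenerate") <- degenerate
  list(weights = wt, coefficients = beta, degenerate = degenerate)
}
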