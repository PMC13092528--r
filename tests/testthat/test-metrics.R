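test_that("Wilson intervals behave at the boundaries and track the exact
           binomial interval", {
  r0 <- observed_proportion_ci(0, 100)
  expect_equal(r0$proportion, 0)
  expect_equal(r0$ci[1], 0)
  r50 <- observed_proportion_ci(50, 100)
  expect_equal(r50$proportion, 0.5)
  expect_equal(r50$ci[1] + r50$ci[2], 1, tolerance = 1e-12)  # symmetric

  r <- observed_proportion_ci(66, 1000)
  exact <- binom.test(66, 1000)$conf.int   # Clopper-Pearson oracle
  expect_lt(max(abs(r$ci - exact)), 0.003)
  expect_error(observed_proportion_ci(1, 0))
})

test_that("the pooled z-test matches the chi-square identity and flags the
           cohort-level outcome difference", {
  z0 <- two_proportion_ztest(30, 100, 60, 200)
  expect_equal(z0$z, 0); expect_equal(z0$p, 1)

  # objective vs clinical progression counts from the study cohort
  zt <- two_proportion_ztest(4856, 23102, 3391, 34510)
  expect_lt(zt$p, 0.001)

  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    x1 <- rbinom(1, n1, runif(1, 0.1, 0.9))
    x2 <- rbinom(1, n2, runif(1, 0.1, 0.9))
    z <- two_proportion_ztest(x1, n1, x2, n2)
    cs <- suppressWarnings(stats::chisq.test(
      matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE),
      correct = FALSE))
    expect_equal(z$z^2, unname(cs$statistic), tolerance = 1e-9)
  }
})

test_that("the Brier score matches its closed forms and a direct oracle", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), rbinom(7, 1, 0.5)), 0.25)
  set.seed(3)
  p <- runif(500); y <- rbinom(500, 1, p)
  expect_equal(brier_score(p, y), sum((p - y)^2) / 500, tolerance = 1e-15)
  expect_error(brier_score(numeric(), numeric()))
})

test_that("SMOTE+Tomek balances a 10:1 set with synthetic points on
           minority segments and never deletes original minority points", {
  set.seed(41)
  X <- rbind(matrix(rnorm(1000 * 2, 0), ncol = 2),
             matrix(rnorm(100 * 2, 3.0), ncol = 2))
  y <- c(rep(0, 1000), rep(1, 100))
  out <- smote_tomek_balance(X, y, k = 10, seed = 9)
  ratio <- sum(out$labels == 1) / sum(out$labels == 0)
  expect_gte(ratio, 0.9); expect_lte(ratio, 1.1)
  expect_true(all(out$labels[out$synthetic] == 1))
  # original minority points survive
  orig_min <- X[y == 1, ]
  kept <- out$features[out$labels == 1 & !out$synthetic, , drop = FALSE]
  expect_gt(nrow(kept), 0)
  # every synthetic point lies on a segment between two original minority
  # points
  syn <- out$features[out$synthetic, , drop = FALSE]
  on_segment <- function(s) {
    for (i in seq_len(nrow(orig_min) - 1)) {
      a <- orig_min[i, ]
      for (j in seq(i + 1, nrow(orig_min))) {
        b <- orig_min[j, ]
        ab <- b - a; as_ <- s - a
        denom <- sum(ab^2)
        if (denom == 0) next
        t_ <- sum(as_ * ab) / denom
        if (t_ >= -1e-9 && t_ <= 1 + 1e-9 &&
            sqrt(sum((a + t_ * ab - s)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(syn[seq_len(min(40, nrow(syn))), , drop = FALSE],
                        1, on_segment)))

  # already balanced, well separated: nothing changes
  Xb <- rbind(matrix(rnorm(60, 0), ncol = 2),
              matrix(rnorm(60, 8), ncol = 2))
  yb <- rep(c(0, 1), each = 30)
  outb <- smote_tomek_balance(Xb, yb, k = 10, seed = 1)
  expect_identical(length(outb$labels), 60L)

  expect_error(smote_tomek_balance(X[1:1005, ], y[1:1005], k = 10),
               "choose k")
})

test_that("AUROC equals all-pairs concordance, is monotone-invariant, and
           is near 0.5 under the null", {
  set.seed(5)
  p <- runif(200); y <- rbinom(200, 1, 0.4)
  a <- auroc_accuracy(p, y, n_boot = 0)$auroc
  # O(n^2) concordance oracle with ties counted one half
  pos <- p[y == 1]; neg <- p[y == 0]
  conc <- outer(pos, neg, function(a_, b_) (a_ > b_) + 0.5 * (a_ == b_))
  expect_equal(a, mean(conc), tolerance = 1e-12)
  expect_equal(auroc_accuracy(qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)), y,
                              n_boot = 0)$auroc, a, tolerance = 1e-12)

  sep <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  expect_equal(auroc_accuracy(sep, rep(c(0, 1), each = 50),
                              n_boot = 0)$auroc, 1)

  n <- 10000
  pn <- runif(n); yn <- rbinom(n, 1, 0.5)
  an <- auroc_accuracy(pn, yn, n_boot = 0)$auroc
  n1 <- sum(yn); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(an - 0.5), 3 * se)
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  p <- runif(300); y <- rbinom(300, 1, plogis(3 * (p - 0.5)))
  ours <- auroc_accuracy(p, y, n_boot = 0)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("chained-equation imputation is deterministic, exact on complete
           data, and unbiased under MCAR", {
  set.seed(7)
  full <- data.frame(a = rnorm(300, 10, 2), b = rnorm(300),
                     c = rbinom(300, 1, 0.4))
  full$b <- full$b + 0.5 * full$a
  out0 <- mice_impute(full, m = 3, seed = 1)
  for (d in out0$completed) expect_equal(d, full)

  holey <- full
  holey$a[sample(300, 30)] <- NA
  r1 <- mice_impute(holey, m = 5, seed = 2, sweeps = 5)
  r2 <- mice_impute(holey, m = 5, seed = 2, sweeps = 5)
  expect_equal(r1$completed, r2$completed)
  pooled_mean <- r1$pooled$a[["estimate"]]
  se <- sd(full$a) / sqrt(300)
  expect_lt(abs(pooled_mean - mean(full$a)), 3 * se)
  # imputed values are observed donor values (predictive mean matching)
  expect_true(all(r1$completed[[1]]$a %in% full$a |
                    !is.na(holey$a)))

  allna <- holey; allna$b <- NA_real_
  expect_error(mice_impute(allna), "all-missing")
})

test_that("the calibration table applies the Bonferroni rule and flags
           monotone observed risk", {
  tab <- calibration_report(1:10, seq(0.05, 0.5, 0.05),
                            round(seq(0.05, 0.5, 0.05) * 200),
                            rep(200, 10))
  expect_true(all(tab$p_adjusted >= tab$p))
  expect_equal(tab$p_adjusted, pmin(1, 10 * tab$p))
  expect_true(attr(tab, "monotone"))
  expect_true(all(tab$observed >= tab$ci_low & tab$observed <= tab$ci_high))

  same <- calibration_report(1:4, c(0.1, 0.2, 0.3, 0.4),
                             c(10, 20, 30, 40), rep(100, 4))
  expect_true(all(same$p_adjusted == 1))
  expect_true(all(abs(same$z) < 1e-12))
})
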