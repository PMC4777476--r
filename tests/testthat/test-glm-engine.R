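test_that("intercept-only fit has the closed-form solution", {
  y <- c(rep(1, 5), rep(0, 15))
  m <- fit_logistic(NULL, y)
  expect_equal(unname(stats::plogis(m$beta[1])), 0.25, tolerance = 1e-8)
  expect_equal(m$log_lik, 5 * log(0.25) + 15 * log(0.75), tolerance = 1e-8)
  expect_equal(m$log_lik, m$null_log_lik)
  expect_equal(m$n1, 5); expect_equal(m$n0, 15)
  expect_equal(model_aic(m), 2 - 2 * (5 * log(0.25) + 15 * log(0.75)),
               tolerance = 1e-8)
})

test_that("IRLS matches glm() and direct likelihood maximisation", {
  d <- make_logit_data(n = 300, seed = 5)
  m <- fit_logistic(d$x, d$y)
  ref <- stats::glm(d$y ~ d$x, family = stats::binomial())
  expect_equal(unname(m$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(m$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-3)
  expect_equal(m$log_lik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_true(m$converged)
  expect_false(m$separation)

  # brute-force oracle on tiny instances (n <= 8)
  tiny <- list(
    list(x = c(-1.5, -1, -0.5, -0.1, 0.1, 0.5, 1, 1.5),
         y = c(0, 1, 0, 0, 1, 0, 1, 1)),
    list(x = c(-2, -1, 0, 1, 2, 0.5), y = c(0, 0, 1, 0, 1, 1)))
  for (tc in tiny) {
    x <- matrix(tc$x, ncol = 1, dimnames = list(NULL, "x1"))
    m2 <- fit_logistic(x, tc$y)
    bf <- oracle_logit_ml(x, tc$y)
    expect_lt(max(abs(unname(m2$beta) - bf)), 1e-4)
  }
})

test_that("degenerate designs and responses are rejected or flagged", {
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(NULL, rep(1, 10)), "single class")
  x <- cbind(a = rnorm(20), b = 0)
  x[, "b"] <- x[, "a"]  # duplicate column
  expect_error(fit_logistic(x, y), "aliased.*b")
  # perfect separation: response equals an indicator predictor
  sep <- cbind(ind = rep(c(0, 1), each = 10))
  m <- fit_logistic(sep, rep(c(0, 1), each = 10))
  expect_true(m$separation)
})

test_that("likelihood-ratio test behaves at its analytic anchors", {
  d <- make_logit_data(n = 200, seed = 8)
  m1 <- fit_logistic(d$x, d$y)
  m0 <- fit_logistic(NULL, d$y)
  lt <- lr_test(m1, m0)
  expect_equal(lt$df, 1)
  expect_equal(lt$p_value,
               stats::pchisq(2 * (m1$log_lik - m0$log_lik), 1,
                             lower.tail = FALSE))
  # identical models: statistic 0, p = 1
  self <- lr_test(m1, m1)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # chi-square(1) anchor: deviance 3.841 <-> p ~ 0.050
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  # non-nested rejected
  x2 <- cbind(z = rnorm(200))
  m2 <- fit_logistic(x2, d$y)
  expect_error(lr_test(m1, m2), "nested")
})

test_that("lr p-values are approximately uniform under the null", {
  reps <- 300
  pv <- withr::with_seed(21, {
    vapply(seq_len(reps), function(i) {
      y <- stats::rbinom(120, 1, 0.3)
      if (length(unique(y)) < 2) return(NA_real_)
      x <- matrix(stats::rnorm(120), ncol = 1, dimnames = list(NULL, "noise"))
      lr_test(fit_logistic(x, y), fit_logistic(NULL, y))$p_value
    }, numeric(1))
  })
  pv <- pv[!is.na(pv)]
  rej <- mean(pv < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / length(pv)) + 0.01)
})

test_that("Benjamini-Hochberg step-up matches hand-derived cases", {
  expect_identical(bh_fdr(c(0.001, 0.04, 0.2), 0.05), c(TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_identical(bh_fdr(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("Benjamini-Hochberg matches the adjusted-p oracle on a full grid", {
  grid <- c(0.001, 0.012, 0.03, 0.2, 0.9)
  for (len in 1:5) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    for (i in seq_len(nrow(combos))) {
      p <- unname(combos[i, ])
      expect_identical(bh_fdr(p, 0.05), oracle_bh(p, 0.05))
    }
  }
})

test_that("VIF has its closed-form values", {
  withr::with_seed(2, {
    n <- 5000
    # near-orthogonal columns -> VIF close to 1
    x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    expect_true(all(vif(x) < 1.01))
    # two columns with correlation r: VIF = 1/(1-r^2)
    r <- 0.8
    z <- rnorm(n)
    x2 <- cbind(a = z, b = r * z + sqrt(1 - r^2) * rnorm(n))
    v <- vif(x2)
    r_obs <- stats::cor(x2[, 1], x2[, 2])
    expect_equal(unname(v[1]), 1 / (1 - r_obs^2), tolerance = 1e-8)
    expect_equal(unname(v), unname(rev(v)), tolerance = 1e-8)
    # near-duplicate -> huge VIF
    x3 <- cbind(a = z, b = z + 0.01 * rnorm(n))
    expect_gt(min(vif(x3)), 100)
  })
  expect_error(vif(cbind(a = rnorm(10))), "two columns")
  expect_error(vif(cbind(a = rnorm(10), b = 1)), "constant")
})

test_that("Nagelkerke R2 follows its formula and its limits", {
  d <- make_logit_data(n = 150, seed = 13)
  m0 <- fit_logistic(NULL, d$y)
  expect_equal(nagelkerke_r2(m0), 0)
  # plug-in anchor: n=100, prevalence 1/2, log_lik = -50
  m <- m0
  m$n <- 100; m$null_log_lik <- 100 * log(0.5); m$log_lik <- -50
  expect_equal(nagelkerke_r2(m),
               (1 - exp(2 * (m$null_log_lik - m$log_lik) / 100)) /
                 (1 - exp(2 * m$null_log_lik / 100)),
               tolerance = 1e-12)
  expect_equal(nagelkerke_r2(m), 0.427239, tolerance = 1e-5)
  # perfectly predictive limit
  m$log_lik <- 0
  expect_equal(nagelkerke_r2(m), 1)
  # row-duplication invariance: 2/n scaling cancels
  m1 <- fit_logistic(d$x, d$y)
  m2 <- fit_logistic(rbind(d$x, d$x), c(d$y, d$y))
  expect_equal(nagelkerke_r2(m1), nagelkerke_r2(m2), tolerance = 1e-6)
})

test_that("AIC is 2k - 2 logLik and grows by 2 per useless parameter", {
  d <- make_logit_data(n = 120, seed = 4)
  m <- fit_logistic(d$x, d$y)
  expect_equal(model_aic(m), 2 * 2 - 2 * m$log_lik)
  fake <- m; fake$df <- 3L
  expect_equal(model_aic(fake) - model_aic(m), 2)
})

test_that("AUC agrees with enumeration and with the trapezoidal ROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      y <- c(1, 0, stats::rbinom(n - 2, 1, 0.4))
      s <- round(stats::runif(n), 2)  # force ties
      expect_equal(roc_auc(s, y), oracle_auc_trapezoid(s, y),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC matches pROC on a random instance", {
  skip_if_not_installed("pROC")
  withr::with_seed(6, {
    y <- stats::rbinom(100, 1, 0.3)
    s <- stats::runif(100)
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("confusion metrics count the table correctly", {
  cm <- confusion_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$ccr, 0.5)
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1, ccr = 1))
  all_pos <- confusion_metrics(runif(10), rep(c(0, 1), 5), 0)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  # threshold is inclusive: score exactly at the cut is a predicted presence
  at_cut <- confusion_metrics(c(0.5, 0.5), c(1, 0), 0.5)
  expect_equal(at_cut$sensitivity, 1)
  expect_equal(at_cut$specificity, 0)
  # ccr lies between sensitivity and specificity
  withr::with_seed(14, {
    y <- stats::rbinom(50, 1, 0.3)
    s <- stats::runif(50)
    cm <- confusion_metrics(s, y, 0.5)
    expect_gte(cm$ccr, min(cm$sensitivity, cm$specificity))
    expect_lte(cm$ccr, max(cm$sensitivity, cm$specificity))
  })
})
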