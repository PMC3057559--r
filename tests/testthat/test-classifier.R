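# Logistic fits, the c statistic, BIC model averaging, cross-validation
# and the published predictive equations.

test_that("fit_logistic recovers known coefficients and computes BIC", {
  set.seed(61)
  n <- 1e4
  x <- rnorm(n, 23, 3)
  eta <- -10 + 0.45 * x
  y <- rbinom(n, 1, plogis(eta))
  f <- fit_logistic(y, cbind(x = x))
  expect_false(f$separation)
  expect_lt(abs(f$coefficients[["x"]] - 0.45), 3 * f$standard_errors[["x"]])
  # agreement with stats::glm
  ref <- glm(y ~ x, family = binomial)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(f$bic, BIC(ref), tolerance = 1e-6)

  # closed-form intercept-only BIC
  f0 <- fit_logistic(y)
  phat <- mean(y)
  ll0 <- sum(y) * log(phat) + sum(1 - y) * log(1 - phat)
  expect_equal(f0$bic, -2 * ll0 + log(n), tolerance = 1e-9)

  expect_error(fit_logistic(rep(1, 20), cbind(rnorm(20))), "no variation")
  expect_error(fit_logistic(rbinom(20, 1, 0.5), cbind(rep(2, 20))),
               "constant predictor")
  xx <- rnorm(20)
  expect_error(fit_logistic(rbinom(20, 1, 0.5), cbind(xx, 2 * xx)),
               "singular")
})

test_that("perfect separation is flagged", {
  x <- c(rnorm(20, -5), rnorm(20, 5))
  y <- rep(0:1, each = 20)
  f <- fit_logistic(y, cbind(x = x))
  expect_true(f$separation)
})

test_that("c statistic is the Mann-Whitney probability with tie correction", {
  set.seed(62)
  # brute-force pairwise oracle on random instances, with ties
  for (i in 1:60) {
    n <- sample(20:80, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(c_statistic(scores, labels),
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
  # perfectly ordered scores
  expect_equal(c_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # independent library cross-check
  skip_if_not_installed("pROC")
  set.seed(620)
  sc <- rnorm(200)
  lb <- rbinom(200, 1, plogis(sc))
  expect_equal(c_statistic(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-12)
  # labels independent of scores: near 1/2
  set.seed(63)
  cs <- replicate(200, c_statistic(rnorm(100), rbinom(100, 1, 0.5)))
  expect_lt(abs(mean(cs) - 0.5), 0.02)
  expect_error(c_statistic(rnorm(5), rep(1, 5)), "both classes")
})

test_that("in-sample c of a joint fit dominates its single predictors", {
  set.seed(64)
  d <- m20s_records()
  y <- as.numeric(d$type == "TE")
  f2 <- fit_logistic(y, cbind(bmi = d$bmi, cjwr = d$CJWR))
  f_bmi <- fit_logistic(y, cbind(bmi = d$bmi))
  f_cj <- fit_logistic(y, cbind(cjwr = d$CJWR))
  expect_gte(f2$c_statistic + 1e-9, f_bmi$c_statistic)
  expect_gte(f2$c_statistic + 1e-9, f_cj$c_statistic)
})

test_that("BMA enumerates subsets, normalizes weights and ranks by BIC", {
  set.seed(65)
  n <- 300
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 1.2 * x1))
  # single candidate: two models, higher weight on the true predictor
  b1 <- bma_logistic(y, cbind(x1 = x1))
  expect_equal(nrow(b1$models), 2)
  expect_equal(sum(b1$models$weight), 1, tolerance = 1e-12)
  expect_equal(b1$parsimonious, "x1")
  expect_gt(b1$inclusion_probs[["x1"]], 0.9)

  # three candidates: 8 models, parsimonious has minimal BIC
  X <- cbind(x1 = x1, x2 = rnorm(n), x3 = rnorm(n))
  b3 <- bma_logistic(y, X)
  expect_equal(nrow(b3$models), 8)
  expect_equal(sum(b3$models$weight), 1, tolerance = 1e-12)
  best <- b3$models$model[which.min(b3$models$bic)]
  expect_equal(sort(strsplit(best, "\\+")[[1]]), sort(b3$parsimonious))
  # inclusion probabilities from an independent recomputation
  w <- exp(-(b3$models$bic - min(b3$models$bic)) / 2)
  w <- w / sum(w)
  incl_x2 <- sum(w[grepl("x2", b3$models$model)])
  expect_equal(b3$inclusion_probs[["x2"]], incl_x2, tolerance = 1e-12)
})

test_that("BMA prefers the generating predictors over noise", {
  # strong two-predictor signal plus noise candidates: the minimum-BIC
  # model should usually be exactly the generating pair
  set.seed(66)
  hits <- 0
  nseed <- 30
  for (s in 1:nseed) {
    n <- 230
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 1.2 * x1 + 0.9 * x2))
    X <- cbind(a = x1, b = x2, n1 = rnorm(n), n2 = rnorm(n))
    fit <- suppressWarnings(bma_logistic(y, X))
    if (setequal(fit$parsimonious, c("a", "b"))) hits <- hits + 1
  }
  expect_gte(hits, nseed * 0.7)
})

test_that("LOOCV correct rate hits the expected benchmarks", {
  # well-separated toy data: every held-out case classified correctly
  set.seed(67)
  x <- c(rnorm(25, -4), rnorm(25, 4))
  y <- rep(0:1, each = 25)
  expect_equal(loocv_correct_rate(y, cbind(x = x)), 100)

  # shuffled labels: about max(prevalence, 1 - prevalence)
  set.seed(68)
  rates <- replicate(20, {
    n <- 120
    y2 <- rbinom(n, 1, 0.42)
    loocv_correct_rate(y2, cbind(x = rnorm(n)))
  })
  expect_lt(abs(mean(rates) - 58), 8)
})

test_that("published equations evaluate exactly and match fold changes", {
  # at the printed TE group means for M20s
  p <- predict_te("M20s", bmi = 25.1, cjwr = 1.13)
  x <- 0.236 - 0.454 * 25.1 + 9.237 * 1.13
  expect_equal(x, -0.72159, tolerance = 1e-10)
  expect_equal(p, 1 / (1 + exp(x)), tolerance = 1e-15)
  expect_equal(round(p, 3), 0.673)

  # coefficient sign: large CJWR drives the TE probability to zero
  expect_lt(predict_te("M20s", 25.1, 10), 1e-10)
  # heavier subjects are more probably TE
  expect_gt(predict_te("M20s", 30, 1.13), p)

  # per-unit-BMI fold changes, all four strata, two-decimal agreement
  eq <- te_equations()
  folds <- c(M20s = 1.57, M60s = 1.45, F20s = 1.58, F60s = 1.72)
  for (s in names(folds))
    expect_lt(abs(exp(abs(eq$b_bmi[eq$stratum == s])) - folds[[s]]), 0.01)

  expect_error(predict_te("M40s", 23, 1.1), "unknown stratum")
})

test_that("interaction Wald p is null-uniform and powered when present", {
  # no interaction in the generator: p approximately uniform over seeds
  set.seed(69)
  ps <- replicate(150, {
    n <- 230
    z1 <- rnorm(n); z2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.4 * z1 + 0.4 * z2))
    interaction_check(y, z1, z2)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # strong interaction: detected at the 5% level in most seeds
  set.seed(70)
  hits <- mean(replicate(60, {
    n <- 230
    z1 <- rnorm(n); z2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 * z1 + 0.3 * z2 + 0.8 * z1 * z2))
    interaction_check(y, z1, z2)$p < 0.05
  }))
  expect_gte(hits, 0.9)
})
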