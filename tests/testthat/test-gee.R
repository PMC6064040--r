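test_that("linear GEE with one record per cluster equals closed-form OLS", {
  set.seed(101)
  n <- 60
  x <- rnorm(n); y <- 2 + 0.7 * x + rnorm(n)
  d <- data.frame(y = y, x = x, id = seq_len(n))
  # closed-form OLS oracle
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  for (wc in c("independence", "exchangeable")) {
    fit <- fit_linear_gee(d, "y", "x", "id", working_correlation = wc)
    expect_equal(fit$estimate, slope, tolerance = 1e-8)
    expect_equal(fit$coefficients[["(Intercept)"]],
                 mean(y) - slope * mean(x), tolerance = 1e-8)
  }
})

test_that("logistic GEE with one record per cluster equals Newton-Raphson ML", {
  set.seed(102)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 1.1 * x))
  d <- data.frame(y = y, x = x, id = seq_len(n))
  oracle <- logistic_ml_oracle(y, cbind(1, x))
  fit <- fit_logistic_gee(d, "y", "x", "id", working_correlation = "independence")
  expect_equal(fit$coefficients[["(Intercept)"]], unname(oracle[1]),
               tolerance = 1e-6)
  expect_equal(fit$estimate, unname(oracle[2]), tolerance = 1e-6)
})

test_that("sandwich SEs are non-negative and CIs bracket the estimate", {
  set.seed(103)
  for (i in 1:10) {
    n <- 40; m <- 3
    u <- rep(rnorm(n), each = m)
    x <- rnorm(n * m)
    d <- data.frame(x = x, id = rep(seq_len(n), each = m))
    d$y <- 1 + 0.5 * x + u + rnorm(n * m)
    fit <- fit_linear_gee(d, "y", "x", "id")
    expect_gte(fit$robust_se, 0)
    expect_lte(fit$ci95_low, fit$estimate)
    expect_gte(fit$ci95_high, fit$estimate)
    d$yb <- rbinom(n * m, 1, plogis(0.3 * x + u / 2))
    fitb <- fit_logistic_gee(d, "yb", "x", "id")
    expect_gt(fitb$or_value, 0)
    expect_lte(fitb$or_ci95[1], fitb$or_value)
    expect_gte(fitb$or_ci95[2], fitb$or_value)
  }
})

test_that("per-1-SD estimates are invariant to rescaling the raw predictor", {
  set.seed(104)
  n <- 80; m <- 3
  raw <- rnorm(n * m, 70, 11)
  d <- data.frame(id = rep(seq_len(n), each = m))
  d$y <- 1.5 + 0.04 * raw + rep(rnorm(n), each = m) + rnorm(n * m)
  for (k in c(1, 3.7, 250)) {
    sc <- standardize(raw * k)
    d$z <- sc$z
    fit <- fit_linear_gee(d, "y", "z", "id")
    if (k == 1) ref <- fit$estimate else
      expect_equal(fit$estimate, ref, tolerance = 1e-8)
  }
})

test_that("estimate bias shrinks as the number of clusters grows", {
  true_beta <- 0.8
  mae <- sapply(c(50, 200, 500), function(n) {
    errs <- sapply(1:8, function(s) {
      set.seed(7000 + 13 * s + n)
      m <- 3
      u <- rep(rnorm(n, 0, 1.5), each = m)
      x <- rnorm(n * m)
      d <- data.frame(x = x, id = rep(seq_len(n), each = m))
      d$y <- true_beta * x + u + rnorm(n * m)
      abs(fit_linear_gee(d, "y", "x", "id")$estimate - true_beta)
    })
    mean(errs)
  })
  expect_lt(mae[3], mae[1])
})

test_that("null effects are covered by the 95% CI at close to nominal rate", {
  covered <- sapply(1:200, function(s) {
    set.seed(3000 + s)
    n <- 50; m <- 3
    u <- rep(rnorm(n), each = m)
    x <- rnorm(n * m)
    d <- data.frame(x = x, id = rep(seq_len(n), each = m))
    d$y <- 1 + u + rnorm(n * m)          # true slope 0
    fit <- fit_linear_gee(d, "y", "x", "id")
    fit$ci95_low <= 0 && fit$ci95_high >= 0
  })
  expect_gt(mean(covered), 0.88)
  expect_lt(mean(covered), 0.995)
})

test_that("exchangeable alpha tracks the induced within-cluster correlation", {
  set.seed(106)
  n <- 400; m <- 3
  u <- rep(rnorm(n, 0, 1), each = m)      # ICC = 0.5 against unit noise
  x <- rnorm(n * m)
  d <- data.frame(x = x, id = rep(seq_len(n), each = m))
  d$y <- 0.3 * x + u + rnorm(n * m)
  fit <- fit_linear_gee(d, "y", "x", "id")
  expect_gt(fit$alpha_hat, 0.35)
  expect_lt(fit$alpha_hat, 0.65)
})

test_that("degenerate inputs raise informative errors", {
  d <- data.frame(y = c(1, 1, 1, 1), x = c(0, 1, 0, 1), id = c(1, 1, 2, 2))
  expect_error(fit_logistic_gee(d, "y", "x", "id"), "single class")
  d2 <- data.frame(y = rnorm(6), x = rep(2, 6), id = rep(1:3, each = 2))
  expect_error(fit_linear_gee(d2, "y", "x", "id"), "singular")
  d3 <- data.frame(y = rnorm(3), x = rnorm(3), id = rep(1, 3))
  expect_error(fit_linear_gee(d3, "y", "x", "id"), "2 clusters")
})
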