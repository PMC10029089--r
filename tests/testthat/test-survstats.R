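test_that("Kaplan-Meier matches closed-form product limits", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  expect_equal(km$at_risk, c(3, 2, 1))

  # hand product-limit: S(1) = 2/3, time 2 censored, S(3) = 2/3 * 0 = 0
  km2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km2$event_times, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_equal(km2$median, 3)

  km3 <- km_estimate(c(5, 8, 2), c(FALSE, FALSE, FALSE))
  expect_equal(length(km3$event_times), 0L)
  expect_true(is.na(km3$median))
  expect_true(all(is.na(km3$event_time_iqr)))

  expect_error(km_estimate(numeric(), logical()))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(31)
  for (rep in 1:20) {
    t <- sample(1:30, 40, replace = TRUE)
    km <- km_estimate(t, rep(TRUE, 40))
    emp <- vapply(km$event_times, function(u) mean(t > u), numeric(1))
    expect_equal(km$survival, emp)
  }
})

test_that("log-rank statistic is zero for identical groups", {
  t <- c(3, 5, 7, 9, 11)
  e <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  lr <- logrank_test(c(t, t), c(e, e), rep(1:2, each = 5))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, 1)
})

test_that("log-rank agrees with survival::survdiff to 1e-8", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(30:120, 1)
    k <- sample(2:4, 1)
    d <- random_survival_data(n, tie_times = rep %% 2 == 0)
    g <- sample(k, n, replace = TRUE)
    while (length(unique(g)) < k) g <- sample(k, n, replace = TRUE)
    ours <- logrank_test(d$times, d$events, g)
    ref <- survival::survdiff(survival::Surv(d$times, d$events) ~ factor(g))
    expect_equal(ours$statistic, unname(ref$chisq), tolerance = 1e-8)
  }
})

test_that("log-rank detects a hazard ratio of 3 with high power", {
  set.seed(7)
  reject <- 0L
  for (rep in 1:100) {
    t1 <- rexp(200, 0.03)
    t2 <- rexp(200, 0.09)
    lr <- logrank_test(c(t1, t2), rep(TRUE, 400), rep(1:2, each = 200))
    if (lr$p_value < 0.01) reject <- reject + 1L
  }
  expect_gte(reject, 95L)
})

test_that("log-rank is invariant under group relabeling and monotone time transforms", {
  set.seed(8)
  d <- random_survival_data(60)
  g <- sample(1:3, 60, replace = TRUE)
  a <- logrank_test(d$times, d$events, g)
  b <- logrank_test(d$times, d$events, c("x", "z", "y")[g])
  expect_equal(a$statistic, b$statistic)
  cc <- logrank_test(d$times^3, d$events, g)
  expect_equal(a$statistic, cc$statistic, tolerance = 1e-10)
  expect_error(logrank_test(d$times, d$events, rep(1, 60)), "2 groups")
})

test_that("Harrell's C handles perfect, tied and mixed orderings", {
  t <- c(1, 2, 3, 4, 5)
  e <- rep(TRUE, 5)
  expect_equal(harrell_c(t, e, c(5, 4, 3, 2, 1)), 1.0)
  expect_equal(harrell_c(t, e, c(1, 2, 3, 4, 5)), 0.0)
  expect_equal(harrell_c(t, e, rep(2, 5)), 0.5)
  expect_error(harrell_c(c(3, 3), c(FALSE, FALSE), c(1, 2)), "comparable")
})

test_that("Harrell's C equals the pair-enumeration oracle and the complement identity", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(10:50, 1)
    d <- random_survival_data(n, tie_times = rep %% 3 == 0)
    s <- if (rep %% 2 == 0) sample(1:4, n, replace = TRUE) else rnorm(n)
    expect_identical(harrell_c(d$times, d$events, s),
                     oracle_harrell(d$times, d$events, s))
    if (!anyDuplicated(s)) {
      expect_equal(harrell_c(d$times, d$events, s) +
                     harrell_c(d$times, d$events, -s), 1)
    }
  }
})

test_that("univariate Cox agrees with coxph (Breslow ties) to 1e-6", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(40:150, 1)
    d <- random_survival_data(n, tie_times = rep %% 2 == 0)
    x <- if (rep %% 3 == 0) rbinom(n, 1, 0.4) else d$x
    if (length(unique(x)) < 2 || sum(d$events) < 3) next
    ours <- cox_univariate(d$times, d$events, x)
    ref <- survival::coxph(survival::Surv(d$times, d$events) ~ x,
                           ties = "breslow")
    expect_equal(ours$coef, unname(ref$coefficients), tolerance = 1e-6)
    expect_equal(ours$se, sqrt(unname(ref$var[1, 1])), tolerance = 1e-6)
  }
})

test_that("Cox recovers a known hazard ratio and rejects degenerate input", {
  set.seed(123)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.02 * exp(log(2) * x))
  fit <- cox_univariate(t, rep(TRUE, n), x)
  expect_gt(fit$hr, 1.8)
  expect_lt(fit$hr, 2.2)
  expect_true(fit$ci[1] < 2 && fit$ci[2] > 2)
  expect_error(cox_univariate(t, rep(TRUE, n), rep(1, n)), "degenerate")
})

test_that("Cox direction is concordant with the log-rank on binary groups", {
  set.seed(5)
  for (rep in 1:10) {
    g <- rep(0:1, each = 40)
    t <- rexp(80, 0.02 * exp(0.8 * g)) + rep * 1e-4
    fit <- cox_univariate(t, rep(TRUE, 80), g)
    lr <- logrank_test(t, rep(TRUE, 80), g)
    o_minus_e <- lr$observed[2] - lr$expected[2]
    expect_equal(sign(fit$coef), sign(o_minus_e))
  }
})

test_that("odds ratios use the cross-product with Haldane correction on zeros", {
  expect_equal(odds_ratio(matrix(c(10, 10, 10, 10), 2))$or, 1)
  expect_equal(odds_ratio(matrix(c(20, 5, 5, 20), 2))$or, 16)
  z <- odds_ratio(matrix(c(12, 0, 7, 9), 2, byrow = TRUE))
  expect_true(z$corrected)
  expect_equal(z$log_or, log(12.5) + log(9.5) - log(0.5) - log(7.5))
  unst <- odds_ratio(matrix(c(0, 0, 5, 9), 2, byrow = TRUE))
  expect_true(unst$unstable)

  set.seed(77)
  for (rep in 1:25) {
    m <- matrix(rpois(4, 8), 2)
    ref_lor <- log(m[1, 1]) + log(m[2, 2]) - log(m[1, 2]) - log(m[2, 1])
    if (!is.finite(ref_lor)) next
    expect_equal(odds_ratio(m)$log_or, ref_lor, tolerance = 1e-10)
  }
})
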