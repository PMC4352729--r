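surv_tb <- function(time, event, covariate = seq_along(time)) {
  tibble::tibble(sample_id = sprintf("s%03d", seq_along(time)),
                 time = time, event = as.integer(event),
                 covariate = covariate)
}

test_that("median dichotomization applies the declared tie rule", {
  tb <- surv_tb(1:4, rep(1, 4), covariate = c(1, 2, 3, 4))
  g <- median_split(tb)$group
  expect_identical(as.character(g), c("low", "low", "high", "high"))

  tb2 <- surv_tb(1:4, rep(1, 4), covariate = c(1, 2, 2, 3))
  g2 <- median_split(tb2)$group       # median 2; ties go low
  expect_identical(as.character(g2), c("low", "low", "low", "high"))

  expect_error(median_split(surv_tb(1:4, rep(1, 4), covariate = rep(5, 4))),
               "degenerate")
  expect_error(median_split(surv_tb(1:3, rep(1, 3), covariate = 1:3)),
               ">= 4")
})

test_that("the product-limit curve matches hand computation", {
  # subjects: event at 1, censored at 2, event at 3
  km <- kaplan_meier(surv_tb(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))
  expect_equal(km$n_event, c(1L, 0L, 1L))

  flat <- kaplan_meier(surv_tb(c(2, 5, 9), c(0, 0, 0)))
  expect_true(all(flat$survival == 1))

  single <- kaplan_meier(surv_tb(5, 1))
  expect_equal(single$survival, 0)
  expect_error(kaplan_meier(surv_tb(-1, 1)), "negative")
})

test_that("the survival curve is a proper nonincreasing step function", {
  set.seed(8)
  for (r in 1:5) {
    tb <- toy_surv(50, seed = r)
    km <- kaplan_meier(tb)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_lte(km$survival[1], 1)
    # without censoring the estimator is the empirical survival function
    tb$event <- 1L
    km2 <- kaplan_meier(tb)
    emp <- vapply(km2$time, function(tt) mean(tb$time > tt), 0)
    expect_equal(km2$survival, emp, tolerance = 1e-12)
  }
})

test_that("log-rank O/E/V sums match independent hand arithmetic", {
  # group a events at 1,2,3; group b events at 4,5,6; no censoring
  tb <- surv_tb(1:6, rep(1, 6))
  g <- rep(c("a", "b"), each = 3)
  res <- logrank_test(tb, g)
  # direct evaluation: at t=1..3 group a has events; risk sets shrink 6,5,4,3,2,1
  n1 <- c(3, 2, 1, 0, 0, 0)
  nn <- c(6, 5, 4, 3, 2, 1)
  E <- sum(n1 / nn)
  V <- sum((n1 / nn) * (1 - n1 / nn) * (nn - 1) / pmax(nn - 1, 1))
  stat <- (3 - E)^2 / V
  expect_equal(res$observed, 3)
  expect_equal(res$expected, E, tolerance = 1e-12)
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("log-rank degenerate cases behave as declared", {
  tb <- surv_tb(rep(c(1, 2, 3), 2), rep(1, 6))
  g <- rep(c("a", "b"), each = 3)
  res <- logrank_test(tb, g)       # identical time/event vectors per group
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  none <- logrank_test(surv_tb(1:6, rep(0, 6)), g)
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)

  expect_error(logrank_test(tb, rep("a", 6)), "two groups")
})

test_that("log-rank is invariant to label swap and monotone time relabeling", {
  set.seed(14)
  for (r in 1:5) {
    tb <- toy_surv(60, seed = 100 + r)
    g <- sample(c("a", "b"), 60, replace = TRUE)
    if (min(table(g)) == 0) next
    r1 <- logrank_test(tb, g)
    r2 <- logrank_test(tb, ifelse(g == "a", "b", "a"))
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
    tb2 <- dplyr::mutate(tb, time = log1p(time) * 7)
    r3 <- logrank_test(tb2, g)
    expect_equal(r1$statistic, r3$statistic, tolerance = 1e-12)
  }
})

test_that("statistic and p agree with the survival package on random tables", {
  skip_if_not_installed("survival")
  set.seed(23)
  for (r in 1:10) {
    n <- sample(30:90, 1)
    tb <- surv_tb(round(rexp(n, 0.2), 1), rbinom(n, 1, 0.7))
    g <- factor(sample(c("a", "b"), n, replace = TRUE))
    if (min(table(g)) == 0) next
    mine <- logrank_test(tb, g)
    ref <- survival::survdiff(survival::Surv(time, event) ~ g,
                              data = cbind(tb, g = g))
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
  }
})

test_that("median-split validation wires the three steps together", {
  st <- simulate_study(sim_config(n_genes = 6, n_samples = 100, n_mirna = 4,
                                  n_meth = 6, n_cnv = 6, log_hr = 1.2,
                                  seed = 55))
  v <- survival_validation(st$survival)
  expect_s3_class(v$km, "km_curve")
  expect_s3_class(v$logrank, "logrank_result")
  expect_identical(sum(v$logrank$n_per_group), 100L)
  expect_lt(v$logrank$p_value, 0.05)  # strong driver effect by construction
  td <- tidy(v$logrank)
  expect_named(td, c("statistic", "p_value", "observed", "expected",
                     "variance", "n_group1", "n_group2"))
})
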