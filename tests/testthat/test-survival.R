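test_that("the product-limit estimate matches hand computation", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # times (1, 2+, 3): S(1) = 2/3, S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)

  # duplicating every subject leaves the curve unchanged
  km2 <- km_estimate(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))
  expect_equal(km2$surv, km$surv, tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM curves are monotone, bounded and start at 1", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    times <- rexp(n, 0.01)
    events <- rbinom(n, 1, 0.7)
    km <- km_estimate(times, events)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    first_event <- min(c(km$time[km$n_event > 0], Inf))
    expect_true(all(km$surv[km$time < first_event] == 1))
  }
})

test_that("log-rank handles identical groups, k groups and label swaps", {
  t2 <- c(3, 6, 9, 12, 3, 6, 9, 12)
  e2 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g2 <- rep(c("a", "b"), each = 4)
  lr <- logrank(t2, e2, g2)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  set.seed(5)
  t4 <- rexp(40, 0.1); e4 <- rbinom(40, 1, 0.8)
  g4 <- rep(letters[1:4], each = 10)
  expect_equal(logrank(t4, e4, g4)$df, 3L)

  ga <- rep(c("x", "y"), each = 20)
  gb <- rep(c("y", "x"), each = 20)
  expect_equal(logrank(t4, e4, ga)$statistic,
               logrank(t4, e4, gb)$statistic, tolerance = 1e-12)

  expect_error(logrank(t2, e2, factor(rep("a", 8), levels = c("a", "b"))),
               "group")
})

test_that("log-rank p sits near a large permutation oracle on a small fixture", {
  times <- c(2, 3, 5, 6, 8, 9, 11, 12, 13, 15, 17, 20)
  events <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1)
  groups <- rep(c("a", "b"), 6)
  p_pkg <- logrank(times, events, groups)$p
  chisq <- oracle_logrank_perm(times, events, groups, B = 100000)
  expect_equal(chisq[1], logrank(times, events, groups)$statistic,
               tolerance = 1e-9)
  p_perm <- mean(chisq[-1] >= chisq[1] - 1e-12)
  # chi-square approximation vs exact permutation at n = 12
  expect_lt(abs(p_pkg - p_perm), 0.03)
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(77)
  n <- 40
  times <- rexp(n, 1 / 500)
  events <- rbinom(n, 1, 0.7)
  ps <- replicate(500, logrank(times, events, sample(rep(c("a", "b"), n / 2)))$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.07)
})

test_that("Cox log-HR matches a grid-search partial-likelihood maximum", {
  fx <- surv_fixture_n8()
  fit <- cox_fit(matrix(fx$x, ncol = 1, dimnames = list(NULL, "x")),
                 fx$times, fx$events)
  beta_grid <- oracle_cox_grid(fx$x, fx$times, fx$events)
  expect_equal(fit$loghr, beta_grid, tolerance = 5e-4)
  expect_equal(round(fit$loghr, 3), round(beta_grid, 3))
  # reported CI is exp(loghr +/- 1.96 se) and HR > 0
  expect_equal(fit$lower, exp(fit$loghr - 1.96 * fit$se), tolerance = 1e-12)
  expect_equal(fit$upper, exp(fit$loghr + 1.96 * fit$se), tolerance = 1e-12)
  expect_gt(fit$hr, 0)

  expect_error(cox_fit(matrix(1, 8, 1), fx$times, fx$events), "constant")
})

test_that("null-covariate Cox CIs cover HR = 1 at the nominal rate", {
  set.seed(15)
  covered <- replicate(200, {
    n <- 60
    times <- rexp(n, 1 / 300)
    cens <- runif(n, 0, 900)
    x <- rnorm(n)
    f <- cox_fit(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                 pmin(times, cens), as.numeric(times <= cens))
    f$lower <= 1 && f$upper >= 1
  })
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("median dichotomization puts ties in the low group", {
  expect_equal(as.character(median_dichotomize(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_dichotomize(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_error(median_dichotomize(rep(2, 5)), "identical")
  expect_error(median_dichotomize(3), "at least 2")
})

test_that("mutation-by-expression strata partition samples and run all tests", {
  set.seed(33)
  n <- 120
  mut <- rbinom(n, 1, 0.4)
  expr <- rnorm(n)
  haz <- exp(log(2) * mut + log(2) * (expr <= median(expr)))
  times <- rexp(n, haz / 500)
  cens <- runif(n, 0, 1500)
  st <- mutation_expression_strata(mut, expr, pmin(times, cens),
                                   as.numeric(times <= cens))
  expect_equal(sum(st$sizes), n)
  expect_equal(nlevels(st$groups), 4L)
  expect_equal(st$overall$df, 3L)
  expect_false(is.null(st$wt_logrank))
  expect_false(is.null(st$mut_logrank))
  expect_false(is.null(st$expr_ttest))

  # with no mutated samples only the wild-type stratum tests run
  w <- capture_warnings(
    st0 <- mutation_expression_strata(rep(0, n), expr, times, rep(1, n)))
  expect_true(any(grepl("skipped", w)))
  expect_null(st0$overall)
  expect_false(is.null(st0$wt_logrank))
  expect_null(st0$mut_logrank)
})

test_that("additive mutation and low-expression hazards rank the strata", {
  set.seed(44)
  worst_is_mut_low <- replicate(100, {
    n <- 200
    mut <- rbinom(n, 1, 0.4)
    expr <- rnorm(n)
    low <- expr <= median(expr)
    haz <- exp(log(2) * mut + log(2) * low)
    times <- pmin(rexp(n, haz / 500), 1000)
    events <- as.numeric(times < 1000)
    groups <- paste(ifelse(mut == 1, "mut", "wt"),
                    ifelse(low, "low", "high"), sep = "/")
    t_ref <- median(times)
    km_at <- vapply(unique(groups), function(g) {
      km <- km_estimate(times[groups == g], events[groups == g])
      s <- km$surv[km$time <= t_ref]
      if (length(s)) min(s) else 1
    }, numeric(1))
    names(which.min(km_at)) == "mut/low"
  })
  expect_gte(mean(worst_is_mut_low), 0.9)
})
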