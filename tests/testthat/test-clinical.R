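test_that("H-score arithmetic, bounds and validation", {
  expect_equal(combined_ihc_score(c(0, 0, 0, 100)), 300)
  expect_equal(combined_ihc_score(c(100, 0, 0, 0)), 0)
  expect_equal(combined_ihc_score(c(0, 50, 50, 0)), 150)
  m <- rbind(c(25, 25, 25, 25), c(10, 20, 30, 40))
  expect_equal(combined_ihc_score(m), c(150, 200))
  expect_error(combined_ihc_score(c(10, 10, 10, 10)), "sum to 100")
  # bounds hold for random valid panels; score 0 iff all cells negative
  set.seed(8)
  for (i in 1:20) {
    g <- rgamma(4, 1); p <- 100 * g / sum(g)
    s <- combined_ihc_score(p)
    expect_gte(s, 0); expect_lte(s, 300)
    expect_true(s > 0 || p[1] == 100)
  }
})

test_that("marker dichotomization boundaries", {
  expect_equal(as.character(dichotomize_marker(c(160, 159.9, 300), "MIF")),
               c("high", "low", "high"))
  expect_equal(as.character(dichotomize_marker(c(0, 0.5), "HMGA2")),
               c("absent", "present"))
  expect_error(dichotomize_marker(100, "XYZ"))
  # cutoff is configurable
  expect_equal(as.character(dichotomize_marker(150, "MIF", cutoff = 140)),
               "high")
})

test_that("transcript normalization scales to the reference denominator", {
  expect_equal(relative_transcript_level(0, 1000), 0)
  expect_equal(relative_transcript_level(50, 50), 1e5)
  expect_equal(relative_transcript_level(48, 1e5, per = 1e5), 48)
  expect_error(relative_transcript_level(1, 0), "positive")
})

test_that("signed-rank test matches exact sign-pattern enumeration", {
  a <- c(5, 7, 9, 11, 13); b <- c(1, 2, 3, 4, 5)   # all positive diffs
  res <- wilcoxon_signed_rank(a, b, alternative = "greater")
  expect_equal(res$p.value, 1 / 32)
  expect_equal(res$p.value, enumerate_signed_rank_p(a - b, "greater"))
  # two-sided agreement on asymmetric differences
  set.seed(14)
  for (i in 1:5) {
    d <- round(rnorm(7, 0.5, 2), 3)
    d <- d[d != 0]
    res2 <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(res2$p.value, enumerate_signed_rank_p(d, "two.sided"))
  }
  expect_equal(wilcoxon_signed_rank(1:4, 1:4)$p.value, 1)
})

test_that("rank-sum test matches exact rank-assignment enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p.value, 2 / 6)
  set.seed(19)
  for (i in 1:5) {
    a <- round(rnorm(4, 1), 3); b <- round(rnorm(4), 3)
    expect_equal(wilcoxon_rank_sum(a, b)$p.value, enumerate_rank_sum_p(a, b))
  }
  expect_equal(wilcoxon_rank_sum(3, 3)$p.value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("rank-sum power grows with the shift alternative", {
  set.seed(23)
  pow <- sapply(c(0, 1, 2), function(shift) {
    mean(replicate(200, {
      wilcoxon_rank_sum(rnorm(10, shift), rnorm(10))$p.value < 0.05
    }))
  })
  expect_true(all(diff(pow) > 0))
})

test_that("Kaplan-Meier estimate equals the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))$all
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring before the first event leaves S at 1 but reduces risk set
  km2 <- km_estimate(c(0.5, 1, 2), c(0, 1, 1))$all
  expect_equal(km2$surv[km2$n_event > 0], c(1 / 2, 0))
  # random instance against the naive oracle
  set.seed(29)
  t <- round(rexp(30, 0.1), 2); e <- rbinom(30, 1, 0.7)
  km3 <- km_estimate(t, e)$all
  oracle <- hand_km(t, e)
  expect_equal(km3$surv[km3$n_event > 0], oracle$surv, tolerance = 1e-12)
  # with no censoring KM equals the empirical survival function
  t2 <- 1:10; e2 <- rep(1, 10)
  km4 <- km_estimate(t2, e2)$all
  expect_equal(km4$surv, 1 - ecdf(t2)(sort(t2)), tolerance = 1e-12)
  # S non-increasing, S in [0,1]; no events -> S stays 1
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_equal(km_estimate(c(1, 2), c(0, 0))$all$surv, c(1, 1))
})

test_that("five-year survival is read from the step function", {
  km <- km_estimate(c(10, 50, 70), c(1, 1, 1), horizon = 60)$all
  expect_equal(km$surv_horizon, 1 / 3)
})

test_that("log-rank chi-square equals hand-computed hypergeometric terms", {
  t <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e <- c(1, 1, 0, 1, 1, 0, 1, 1)
  g <- rep(c("a", "b"), 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi2, hand_logrank_chi2(t, e, g), tolerance = 1e-10)
  # identical groups -> chi2 ~ 0
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                      rep(c("a", "b"), 3))
  expect_lt(lr0$chi2, 1e-10)
  expect_error(logrank_test(t, e, rep("a", 8)), "2 groups")
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  t <- c(2, 5, 7, 11); e <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_ph_fit(t, e, x)
  grid <- seq(-5, 5, by = 0.001)
  ll <- vapply(grid, hand_cox_loglik, numeric(1), times = t, events = e,
               x = x)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 2e-3)
  expect_error(cox_ph_fit(t, e, rep(1, 4)), "constant")
  expect_error(cox_ph_fit(t, c(0, 0, 0, 0), x), "event")
})

test_that("log-rank agrees with the Cox score test on tie-free data", {
  set.seed(37)
  t <- rexp(40); e <- rbinom(40, 1, 0.8)
  g <- rep(c(0, 1), 20)
  lr <- logrank_test(t, e, g)
  sc <- survival::coxph(survival::Surv(t, e) ~ g)
  expect_equal(lr$chi2, unname(sc$score), tolerance = 1e-8)
})
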