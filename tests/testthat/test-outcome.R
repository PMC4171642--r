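test_that("AUC matches brute-force pair counting on fixtures and random data", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc,
               pair_count_auc(c(1, 3, 2, 4), c(0, 0, 1, 1)))  # 0.75
  expect_equal(pair_count_auc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)

  withr::local_seed(30)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n), 1)           # induce ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, pair_count_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUC of scores independent of labels is near one half", {
  withr::local_seed(31)
  s <- rnorm(1000)
  y <- rbinom(1000, 1, 0.4)
  expect_equal(roc_auc(s, y)$auc, 0.5, tolerance = 0.06)
})

test_that("log-rank matches the hand-computed expected/observed table", {
  # group A events at 1, 2; group B events at 3, 4; no censoring.
  # By hand: O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36,
  # chi-square = (2 - 5/6)^2 / (17/36) = 2.88235, p = 0.0896.
  f <- km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(f$logrank_chisq, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-9)
  expect_equal(f$logrank_p, pchisq(2.882353, 1, lower.tail = FALSE),
               tolerance = 1e-5)
})

test_that("identical groups give a log-rank p near 1 and KM curves are monotone", {
  base_t <- c(5, 10, 15, 20, 30, 40, 55, 70)
  base_e <- c(1, 0, 1, 1, 0, 1, 0, 0)
  f <- km_logrank(rep(base_t, 2), rep(base_e, 2),
                  rep(c("A", "B"), each = 8))
  expect_gte(f$logrank_p, 0.99)
  d <- tidy(f)
  for (g in c("A", "B")) {
    s <- d$survival[d$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("five-year rates follow the product-limit estimate", {
  # events at 12 and 24 among four samples, no censoring before 60:
  # S(60) = (3/4) * (2/3) = 1/2
  f <- km_logrank(c(12, 24, 70, 80, 12, 24, 70, 80),
                  c(1, 1, 1, 1, 1, 1, 1, 1),
                  rep(c("A", "B"), each = 4))
  r <- five_year_rate(f)
  expect_equal(r$rate, c(0.5, 0.5))

  # no events by 60 months -> 1.0
  f2 <- km_logrank(c(70, 80, 90, 75, 85, 95), rep(c(0, 1), each = 3),
                   rep(c("A", "B"), each = 3))
  expect_equal(five_year_rate(f2)$rate, c(1, 1))

  # follow-up ending early triggers a warning and carries the last value
  f3 <- km_logrank(c(10, 20, 30, 10, 25, 40), c(1, 1, 0, 1, 1, 0),
                   rep(c("A", "B"), each = 3))
  expect_warning(r3 <- five_year_rate(f3), "before 60")
  expect_true(all(r3$rate >= 0 & r3$rate <= 1))
})

test_that("a planted hazard ratio near 3 is recovered between risk groups", {
  hits <- 0
  for (s in 1:12) {
    withr::local_seed(400 + s)
    n <- 300
    grp <- rep(c("low", "high"), each = n / 2)
    rate <- ifelse(grp == "high", 3, 1) / 40
    t <- rexp(n, rate)
    cens <- runif(n, 36, 96)
    time <- pmin(t, cens)
    ev <- as.integer(t <= cens)
    f <- km_logrank(time, ev, factor(grp, levels = c("low", "high")))
    hr <- f$hr$hr[1]
    if (hr >= 2 && hr <= 4.5) hits <- hits + 1
  }
  expect_gte(hits, 10)
})

test_that("Cox per-SD hazard ratios are invariant to affine rescaling of the score", {
  sim <- simulate_cohort(sim_params(n_samples = 200, seed = 33))
  prof <- score_cohort(sim$cohort)
  a <- cox_fit(sim$cohort, prof, score_form = "continuous_per_sd")
  prof2 <- prof
  prof2$score <- prof2$score * 7.3 + 2
  b <- cox_fit(sim$cohort, prof2, score_form = "continuous_per_sd")
  expect_equal(a$hr[1], b$hr[1], tolerance = 1e-8)

  # dichotomized and continuous forms agree in direction
  d <- cox_fit(sim$cohort, prof, score_form = "dichotomized")
  expect_true((a$hr[1] > 1) == (d$hr[1] > 1))
})

test_that("a shuffled score yields null Cox calibration", {
  covered <- 0
  sim <- simulate_cohort(sim_params(n_samples = 250, seed = 34))
  prof <- score_cohort(sim$cohort)
  for (s in 1:20) {
    withr::local_seed(500 + s)
    shuffled <- prof
    shuffled$score <- sample(shuffled$score)
    fit <- cox_fit(sim$cohort, shuffled, score_form = "continuous_per_sd")
    if (fit$ci_low[1] <= 1 && 1 <= fit$ci_high[1]) covered <- covered + 1
  }
  expect_gte(covered, 16)  # ~95% nominal coverage
})

test_that("multivariate Cox includes exactly the requested covariates", {
  sim <- simulate_cohort(sim_params(n_samples = 200, seed = 35))
  prof <- score_cohort(sim$cohort)
  fit <- cox_fit(sim$cohort, prof, covariates = c("stage", "grade"),
                 score_form = "dichotomized")
  expect_true(any(grepl("^score_", fit$term)))
  expect_true(any(grepl("stage", fit$term)))
  expect_true(any(grepl("grade", fit$term)))
  expect_error(cox_fit(sim$cohort, prof, covariates = "not_a_column"),
               "not_a_column")
})

test_that("collagen stratification splits evenly and the interaction model runs", {
  sim <- simulate_cohort(sim_params(n_samples = 240, seed = 36))
  prof <- score_cohort(sim$cohort)
  fits <- stratified_by_collagen(sim$cohort, prof, split = "median")
  expect_named(fits, c("low_collagen", "high_collagen"))
  ns <- vapply(fits, function(f) sum(f$n_per_group), numeric(1))
  expect_lte(abs(ns[1] - ns[2]), 1)
  fits3 <- stratified_by_collagen(sim$cohort, prof, split = "tertile")
  expect_length(fits3, 3)

  it <- collagen_interaction(sim$cohort, prof)
  expect_true(is.finite(it$estimate))
  expect_true(it$ci_low <= it$ci_high)
})

test_that("centring covariates leaves the interaction p-value unchanged", {
  sim <- simulate_cohort(sim_params(n_samples = 240, seed = 37))
  prof <- score_cohort(sim$cohort)
  p1 <- collagen_interaction(sim$cohort, prof)$p
  centred <- prof
  centred$score <- centred$score - mean(centred$score)
  centred$collagen_score <- centred$collagen_score - mean(centred$collagen_score)
  p2 <- collagen_interaction(sim$cohort, centred)$p
  expect_equal(p1, p2, tolerance = 1e-6)
})
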