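test_that("short-followup exclusion removes only non-recurrent early-censored samples", {
  expr <- tibble::tibble(sample_id = sprintf("s%d", 1:4), g = rnorm(4))
  clin <- tibble::tibble(
    sample_id = expr$sample_id,
    recurrence = c(0L, 1L, 0L, 0L),
    dfs_time = c(30, 6, 36, 50),
    dfs_event = c(0L, 1L, 0L, 0L),
    stage = rep("II", 4)
  )
  co <- cohort(expr, clin)
  out <- exclude_short_followup(co, 3)
  # 30-month non-recurrent sample removed; 6-month recurrent retained
  expect_setequal(out$clinical$sample_id, c("s2", "s3", "s4"))

  clin$dfs_time[1] <- NA
  clin$dfs_event[1] <- 0L
  expect_error(exclude_short_followup(cohort(expr, clin)), "s1")
})

test_that("a 160-sample cohort with 25 early-censored non-recurrent drops to 135", {
  withr::local_seed(20)
  n <- 160
  expr <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), g = rnorm(n))
  rec <- c(rep(1L, 48), rep(0L, n - 48))
  dfs <- c(runif(48, 5, 30), runif(25, 6, 35.9), runif(n - 73, 36, 96))
  clin <- tibble::tibble(sample_id = expr$sample_id, recurrence = rec,
                         dfs_time = dfs, dfs_event = rec, stage = "II")
  out <- exclude_short_followup(cohort(expr, clin))
  expect_equal(n_samples(out), 135)
  expect_equal(sum(out$clinical$recurrence), 48)
})

test_that("stratified resampling keeps stage proportions and is exhaustive", {
  clin <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:135),
    stage = c(rep("II", 64), rep("III", 71))
  )
  withr::local_seed(21)
  sp <- stratified_resample(clin, 2 / 3, "stage")
  expect_length(sp$train, 43 + 47)  # round(2/3 * 64), round(2/3 * 71)
  tr_stage <- clin$stage[match(sp$train, clin$sample_id)]
  expect_equal(sum(tr_stage == "II"), 43)
  expect_equal(sum(tr_stage == "III"), 47)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), clin$sample_id)

  small <- tibble::tibble(sample_id = c("a", "b", "c"), stage = "II")
  withr::local_seed(22)
  sp2 <- stratified_resample(small)
  expect_length(sp2$train, 2)
  expect_length(sp2$test, 1)
  expect_error(stratified_resample(tibble::tibble(sample_id = "a", stage = "II")),
               "too small")

  set.seed(99); a <- stratified_resample(clin)
  set.seed(99); b <- stratified_resample(clin)
  expect_identical(a, b)
})

test_that("the univariate screen matches glm on random data and a closed-form fixture", {
  withr::local_seed(23)
  n <- 80
  ex <- tibble::tibble(sample_id = sprintf("s%d", 1:n))
  for (g in sprintf("g%d", 1:6)) ex[[g]] <- rnorm(n, 8, 1)
  y <- rbinom(n, 1, plogis(ex$g1 - 8))
  res <- univariate_screen(ex, outcome = y)
  for (g in res$gene) {
    fit <- summary(glm(y ~ x, family = binomial,
                       data = data.frame(x = ex[[g]])))$coefficients
    expect_equal(res$p_value[res$gene == g], fit[2, 4], tolerance = 2e-3)
    expect_equal(res$estimate[res$gene == g], fit[2, 1], tolerance = 2e-2)
  }

  # 2x2 fixture: cells (x=0,y=0)=20, (0,1)=10, (1,0)=10, (1,1)=20.
  # beta = log OR = log 4; se = sqrt(1/20+1/10+1/10+1/20); Wald p hand-computed.
  x <- rep(c(0, 0, 1, 1), c(20, 10, 10, 20))
  y2 <- rep(c(0, 1, 0, 1), c(20, 10, 10, 20))
  ex2 <- tibble::tibble(sample_id = as.character(seq_along(x)), g = x)
  res2 <- univariate_screen(ex2, outcome = y2)
  z_hand <- log(4) / sqrt(0.3)
  expect_equal(res2$p_value, 2 * pnorm(-abs(z_hand)), tolerance = 5e-4)
})

test_that("the screen handles perfect separation and constant genes", {
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  ex <- tibble::tibble(sample_id = as.character(1:n),
                       sep = y + rnorm(n, 0, 0.01),
                       flat = rep(7, n))
  expect_warning(res <- univariate_screen(ex, outcome = y), "constant")
  expect_lt(res$p_value[res$gene == "sep"], 1e-6)
  expect_true(res$screened[res$gene == "sep"])
  expect_false(res$screened[res$gene == "flat"])
})

test_that("the screen's null type-I rate is calibrated at p < 0.01", {
  withr::local_seed(24)
  n <- 135; G <- 1000
  X <- matrix(rnorm(n * G, 8, 1), n, G,
              dimnames = list(NULL, sprintf("g%04d", 1:G)))
  y <- rbinom(n, 1, 0.36)
  ex <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                         tibble::as_tibble(X))
  res <- univariate_screen(ex, outcome = y)
  hits <- sum(res$screened)
  bounds <- qbinom(c(0.005, 0.995), G, 0.01)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("the lasso returns a subset of screened genes and full shrinkage is valid", {
  sim <- simulate_cohort(sim_params(seed = 25))
  scr <- univariate_screen(sim$cohort)
  screened <- scr$gene[scr$screened]
  expect_gte(length(screened), 2)
  withr::local_seed(26)
  sel <- fit_l1_signature(sim$cohort, screened)
  expect_true(all(sel %in% screened))
  expect_error(fit_l1_signature(sim$cohort, screened[1]), "at least 2")
})

test_that("stability selection recovers planted genes and respects its invariants", {
  sim <- simulate_cohort(sim_params(seed = 31))
  res <- stability_select(
    sim$cohort,
    stability_params(n_iterations = 60, seed = 31),
    paired_profiles = simulate_paired_profiles(sim_params(seed = 31))
  )
  expect_equal(res$n_completed, 60)
  # counts bookkeeping: sum of counts equals sum of per-iteration set sizes
  expect_equal(sum(res$stability$count), sum(res$records$n_selected))
  expect_true(all(res$records$n_selected <= res$records$n_screened))
  expect_true(all(res$records$n_train + res$records$n_test == 135))
  # consensus = the planted signature, with planted directions
  expect_setequal(res$consensus$genes$gene, sim$truth$planted_genes$gene)
  expect_equal(
    res$consensus$genes$coefficient[match(sim$truth$planted_genes$gene,
                                          res$consensus$genes$gene)],
    sim$truth$planted_genes$direction)
  # the cutoff splits the discovery cohort roughly at the upper tertile
  prof <- score_cohort(sim$cohort, res$consensus)
  expect_equal(mean(prof$risk_class == "high"), 1 / 3, tolerance = 0.03)

  # determinism of the whole loop
  res2 <- stability_select(sim$cohort,
                           stability_params(n_iterations = 60, seed = 31),
                           paired_profiles = simulate_paired_profiles(sim_params(seed = 31)))
  expect_identical(res$stability, res2$stability)

  # a frequency threshold of 1 keeps only ever-present genes
  res3 <- suppressWarnings(stability_select(
    sim$cohort,
    stability_params(n_iterations = 60, frequency_threshold = 1, seed = 31)))
  always <- res$stability$gene[res$stability$frequency == 1]
  if (is.null(res3$consensus)) {
    expect_length(always, 0)
  } else {
    expect_setequal(res3$consensus$genes$gene, always)
  }
})

test_that("directions fall back to outcome association with a warning", {
  sim <- simulate_cohort(sim_params(seed = 28))
  expect_warning(
    res <- stability_select(sim$cohort,
                            stability_params(n_iterations = 40, seed = 28)),
    "paired profiles")
  expect_setequal(res$consensus$genes$gene, sim$truth$planted_genes$gene)
  expect_equal(
    res$consensus$genes$coefficient[match(sim$truth$planted_genes$gene,
                                          res$consensus$genes$gene)],
    sim$truth$planted_genes$direction)
})
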