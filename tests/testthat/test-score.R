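test_that("z-scoring standardizes, handles degenerate genes, and is affine-invariant", {
  ex <- tibble::tibble(sample_id = c("a", "b", "c"), g1 = c(1, 2, 3),
                       g2 = c(5, 5, 5))
  expect_warning(z <- zscore_genes(ex), "zero-variance")
  expect_equal(z$g1, c(-1, 0, 1))
  expect_equal(z$g2, c(0, 0, 0))

  withr::local_seed(9)
  x <- rnorm(20)
  za <- zscore_genes(tibble::tibble(sample_id = as.character(1:20), g = x))
  zb <- zscore_genes(tibble::tibble(sample_id = as.character(1:20), g = 3.7 * x + 11))
  expect_equal(za$g, zb$g, tolerance = 1e-12)
})

test_that("compute_score is the signed sum of z-scores (hand oracle)", {
  cls <- published_classifier()
  z <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    PDLIM3 = c(1, 0, 0.5), AMIGO2 = c(1, 0, -0.2), SLC7A2 = c(1, 0, 1.1),
    ULBP2 = c(1, 0, -0.4), CCL11 = c(1, 0, 0.3)
  )
  s <- compute_score(z, cls)
  # hand addition: 4 risk z's minus the protective z
  expect_equal(s$score, c(1 + 1 + 1 + 1 - 1,
                          0,
                          0.5 - 0.2 + 1.1 - 0.4 - 0.3), tolerance = 1e-12)
  expect_error(compute_score(z[, -2], cls), "PDLIM3")
})

test_that("flipping one gene's sign changes the score by exactly twice its z", {
  withr::local_seed(10)
  z <- zscore_genes(toy_cohort(n = 30, n_genes = 5)$expression)
  a <- compute_score(z, classifier(c("PDLIM3", "CCL11"), c(1, -1), 0))
  b <- compute_score(z, classifier(c("PDLIM3", "CCL11"), c(1, 1), 0))
  expect_equal(b$score - a$score, 2 * z$CCL11, tolerance = 1e-12)
})

test_that("the tertile cutoff interpolates linearly and classifies with tie-to-low", {
  expect_equal(derive_cutoff(c(0, 1, 2, 3, 4, 5)), 3.333, tolerance = 1e-3)
  expect_error(derive_cutoff(c(1, 2)), "at least 3")
  expect_equal(derive_cutoff(rep(4, 10)), 4)
  expect_equal(as.character(classify_risk(c(4, 4.01), 4)), c("low", "high"))
  expect_equal(as.character(classify_risk(c(0, 2), 1.1328)), c("low", "high"))

  # the derived cutoff puts about one third of the training scores on the
  # high-risk side
  withr::local_seed(11)
  for (n in c(135, 317)) {
    s <- rnorm(n)
    frac <- mean(s > derive_cutoff(s))
    expect_lte(abs(frac - 1 / 3), 2 / n + 1e-9)
  }
})

test_that("score is invariant to positive affine rescaling of raw expression", {
  co <- toy_cohort(n = 40, n_genes = 5)
  cls <- published_classifier()
  s1 <- compute_score(zscore_genes(co$expression), cls)
  ex2 <- co$expression
  withr::local_seed(99)
  for (g in setdiff(names(ex2), "sample_id")) {
    ex2[[g]] <- ex2[[g]] * runif(1, 0.5, 3) + rnorm(1)
  }
  s2 <- compute_score(zscore_genes(ex2), cls)
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
})

test_that("meta-cohort pooling z-scores per dataset and keeps provenance", {
  sizes <- c(28, 106, 70, 113)  # 317 total
  cohorts <- lapply(seq_along(sizes), function(i) {
    sim <- simulate_cohort(sim_params(n_samples = sizes[i], n_genes = 10,
                                      seed = 300 + i))
    co <- sim$cohort
    co$expression$sample_id <- paste0("d", i, "_", co$expression$sample_id)
    co$clinical$sample_id <- co$expression$sample_id
    # plant a dataset-specific batch shift on one gene
    co$expression$PDLIM3 <- co$expression$PDLIM3 + i * 5
    co$dataset_id <- paste0("d", i)
    co
  })
  pooled <- pool_metacohort(cohorts)
  expect_equal(n_samples(pooled), 317)
  expect_equal(sort(unique(pooled$clinical$dataset)), paste0("d", 1:4))
  m <- dplyr::summarise(dplyr::group_by(
    dplyr::left_join(pooled$expression, pooled$clinical[c("sample_id", "dataset")],
                     by = "sample_id"), dataset),
    mu = mean(PDLIM3), .groups = "drop")
  expect_true(all(abs(m$mu) < 1e-12))  # batch shift removed within dataset

  expect_error(pool_metacohort(cohorts[1]), "at least 2")
  dup <- cohorts
  dup[[2]] <- dup[[1]]
  expect_error(pool_metacohort(dup), "duplicated")
})

test_that("pooling a cohort with a renamed copy duplicates the score distribution", {
  sim <- simulate_cohort(sim_params(n_samples = 50, n_genes = 10, seed = 310))
  a <- sim$cohort
  b <- sim$cohort
  b$expression$sample_id <- paste0("copy_", b$expression$sample_id)
  b$clinical$sample_id <- b$expression$sample_id
  b$dataset_id <- "copy"
  pooled <- pool_metacohort(list(a, b))
  sc <- compute_score(pooled$expression, published_classifier())
  first <- sc$score[seq_len(50)]
  second <- sc$score[50 + seq_len(50)]
  expect_equal(first, second, tolerance = 1e-12)
})

test_that("collagen score averages standardized collagen genes", {
  ex <- tibble::tibble(sample_id = c("a", "b", "c"),
                       COL1A1 = c(1, 2, 3), COL3A1 = c(10, 20, 30))
  cs <- collagen_score(ex, standardize = FALSE)
  expect_equal(cs$collagen_score, c(5.5, 11, 16.5))
  zs <- collagen_score(ex)  # standardized: both genes give (-1, 0, 1)
  expect_equal(zs$collagen_score, c(-1, 0, 1))
  expect_error(collagen_score(ex[, -2]), "COL1A1")
})

test_that("the collagen-percentile filter retains the top slice deterministically", {
  withr::local_seed(12)
  n <- 142
  sim <- simulate_cohort(sim_params(n_samples = n, seed = 313))
  profile <- score_cohort(sim$cohort)
  out <- suppressMessages(filter_by_collagen(sim$cohort, profile, 25))
  expect_equal(attr(out, "n_retained"), 107)

  out0 <- suppressMessages(filter_by_collagen(sim$cohort, profile, 0))
  expect_equal(n_samples(out0), n)
  expect_error(filter_by_collagen(sim$cohort, profile, 100), "percentile")

  # exactly the top 75% by collagen score survive
  thr <- sort(profile$collagen_score)[36]
  kept <- out$expression$sample_id
  expect_true(all(profile$collagen_score[profile$sample_id %in% kept] >= thr))
})
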