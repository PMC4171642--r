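test_that("standard curves recover slope and efficiency in closed form", {
  # perfect doubling: slope -3.3219 -> 100% efficiency
  curve <- fit_standard_curve(0:-4, 20 + 3.3219 * (0:4))
  expect_equal(curve$efficiency, 1, tolerance = 1e-4)
  expect_equal(curve$r2, 1, tolerance = 1e-12)

  # noisy 5-point fixture against closed-form least squares
  withr::local_seed(50)
  x <- c(0, -1, -2, -3, -4)
  ycq <- 19 - 3.1 * x + rnorm(5, 0, 0.15)
  curve2 <- fit_standard_curve(x, ycq)
  beta_hand <- sum((x - mean(x)) * (ycq - mean(ycq))) / sum((x - mean(x))^2)
  expect_equal(curve2$slope, beta_hand, tolerance = 1e-12)

  expect_error(fit_standard_curve(c(0, 0, -1), c(20, 20, 23)), "3 distinct")
  expect_error(fit_standard_curve(0:-3, c(16, 14, 12, 10)), "slope")
})

test_that("quantification inverts the curve", {
  curve <- fit_standard_curve(0:-4, 18 + 3.3219 * (0:4))
  expect_equal(quantify_cq(curve$intercept, curve), 1, tolerance = 1e-9)
  a1 <- quantify_cq(25, curve)
  expect_equal(quantify_cq(25 + curve$slope, curve), 10 * a1, tolerance = 1e-9)
  # round trip
  amounts <- c(0.01, 0.1, 1, 10)
  cqs <- curve$slope * log10(amounts) + curve$intercept
  expect_equal(quantify_cq(cqs, curve), amounts, tolerance = 1e-9)
})

test_that("geNorm M matches the brute-force pairwise-SD oracle", {
  withr::local_seed(51)
  n <- 6
  base <- exp(rnorm(n, 0, 0.8))           # shared per-sample input amount
  Q <- cbind(
    A = base * exp(rnorm(n, 0, 0.05)),
    B = base * exp(rnorm(n, 0, 0.05)),
    C = base * exp(rnorm(n, 0, 0.6))
  )
  qt <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                         tibble::as_tibble(Q))
  res <- genorm_stability(qt)
  oracle <- brute_genorm_m(Q)
  expect_equal(res$m[match(names(oracle), res$gene)], unname(oracle),
               tolerance = 1e-12)
  expect_true(all(res$rank[res$gene %in% c("A", "B")] == 1))
  expect_equal(res$rank[res$gene == "C"], 3)

  # perfectly proportional genes have zero pairwise log-ratio SD
  Q2 <- cbind(A = base, B = 3 * base, C = base * exp(rnorm(n, 0, 0.3)))
  expect_equal(sd(log2(Q2[, "A"] / Q2[, "B"])), 0)

  # per-sample global scaling leaves M untouched
  Q3 <- Q * runif(n, 0.2, 5)
  qt3 <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                          tibble::as_tibble(Q3))
  expect_equal(genorm_stability(qt3)$m, res$m, tolerance = 1e-9)

  expect_error(genorm_stability(qt[, 1:3]), "3 candidate")
  expect_error(genorm_stability(qt[1:3, ]), "5 samples")
})

test_that("delta-Ct stability matches the hand oracle and its symmetries", {
  withr::local_seed(52)
  n <- 5
  CQ <- cbind(
    G1 = 20 + rnorm(n, 0, 0.1),
    G2 = 22 + rnorm(n, 0, 0.1),
    G3 = 25 + rnorm(n, 0, 1.5)
  )
  qt <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                         tibble::as_tibble(CQ))
  res <- delta_ct_stability(qt)
  oracle <- brute_delta_ct(CQ)
  expect_equal(res$delta_ct_sd[match(names(oracle), res$gene)], unname(oracle),
               tolerance = 1e-12)

  # duplicated gene columns have zero mutual delta-Ct SD
  dup <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(1:n)),
                          tibble::as_tibble(cbind(A = CQ[, 1], B = CQ[, 1])))
  expect_equal(min(brute_delta_ct(cbind(A = CQ[, 1], B = CQ[, 1]))), 0)

  # permuting samples changes nothing
  perm <- qt[sample(n), ]
  expect_equal(delta_ct_stability(perm)$delta_ct_sd, res$delta_ct_sd,
               tolerance = 1e-12)
})

test_that("reference normalization divides by the geometric mean and standardizes", {
  am <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       ACTB = c(4, 2, 1), PMM1 = c(9, 8, 4),
                       TGT = c(12, 8, 4))
  # geometric mean at s1 = sqrt(36) = 6
  raw <- normalize_to_references(am, log2_transform = FALSE, standardize = FALSE)
  expect_equal(raw$TGT[1], 12 / 6)

  # a target proportional to the references normalizes to a constant
  am2 <- am
  am2$TGT <- 5 * sqrt(am2$ACTB * am2$PMM1)
  raw2 <- normalize_to_references(am2, log2_transform = FALSE, standardize = FALSE)
  expect_equal(raw2$TGT, rep(5, 3), tolerance = 1e-12)

  # full pipeline against a hand-computed spreadsheet-style oracle
  withr::local_seed(53)
  n <- 8
  am3 <- tibble::tibble(
    sample_id = sprintf("s%d", 1:n),
    ACTB = exp(rnorm(n)), PMM1 = exp(rnorm(n)),
    T1 = exp(rnorm(n)), T2 = exp(rnorm(n))
  )
  z <- normalize_to_references(am3)
  gm <- sqrt(am3$ACTB * am3$PMM1)
  l1 <- log2(am3$T1 / gm)
  oracle <- (l1 - mean(l1)) / sd(l1)
  expect_equal(z$T1, oracle, tolerance = 1e-9)

  # scaling one gene's amounts by a constant leaves its z-scores unchanged
  am4 <- am3
  am4$T1 <- am4$T1 * 37
  expect_equal(normalize_to_references(am4)$T1, z$T1, tolerance = 1e-9)

  am_bad <- am
  am_bad$ACTB[2] <- 0
  expect_error(normalize_to_references(am_bad), "s2")
})

test_that("candidate ranking puts planted stable references first", {
  withr::local_seed(54)
  n <- 12
  load <- rnorm(n, 0, 1)   # per-sample input amount, log2 scale
  cq_of <- function(base, noise_sd) base - load + rnorm(n, 0, noise_sd)
  long <- tidyr::pivot_longer(
    tibble::tibble(
      sample = sprintf("s%02d", 1:n),
      ACTB = cq_of(18, 0.08), PMM1 = cq_of(24, 0.08),
      GAPDH = cq_of(20, 0.5), B2M = cq_of(22, 0.7),
      HPRT1 = cq_of(26, 0.6), PPIA = cq_of(21, 1.0)
    ), -sample, names_to = "gene", values_to = "cq")
  rk <- rank_reference_candidates(long)
  expect_setequal(rk$gene[1:2], c("ACTB", "PMM1"))
  expect_equal(rk$gene[which.max(rk$combined_rank)], "PPIA")
  expect_true(all(sort(rk$genorm_rank) == rk$genorm_rank[order(rk$genorm_m)]))

  # replicate wells are averaged before analysis
  long2 <- dplyr::bind_rows(long, long)
  rk2 <- rank_reference_candidates(long2)
  expect_equal(rk2$genorm_m, rk$genorm_m, tolerance = 1e-12)

  expect_error(rank_reference_candidates(long, candidates = c("ACTB", "PMM1")),
               "at least 3")
})
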