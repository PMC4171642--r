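# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own numerical code paths.

# AUC by explicit pair counting (ties count one half).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# geNorm M by direct pairwise log-ratio SDs.
brute_genorm_m <- function(Q) {
  L <- log2(Q)
  g <- ncol(L)
  out <- numeric(g)
  for (i in seq_len(g)) {
    sds <- c()
    for (j in seq_len(g)) {
      if (i != j) sds <- c(sds, sd(L[, i] - L[, j]))
    }
    out[i] <- mean(sds)
  }
  setNames(out, colnames(Q))
}

# delta-Ct stability by direct loops.
brute_delta_ct <- function(CQ) {
  g <- ncol(CQ)
  out <- numeric(g)
  for (i in seq_len(g)) {
    sds <- c()
    for (j in seq_len(g)) if (i != j) sds <- c(sds, sd(CQ[, i] - CQ[, j]))
    out[i] <- mean(sds)
  }
  setNames(out, colnames(CQ))
}

# A tiny deterministic cohort for plumbing tests.
toy_cohort <- function(n = 24, n_genes = 6, seed = 42) {
  withr::with_seed(seed, {
    genes <- c("PDLIM3", "AMIGO2", "SLC7A2", "ULBP2", "CCL11",
               sprintf("G%02d", seq_len(max(0, n_genes - 5))))[seq_len(n_genes)]
    expr <- tibble::tibble(sample_id = sprintf("t%02d", seq_len(n)))
    for (g in genes) expr[[g]] <- rnorm(n, 8, 1)
    clin <- tibble::tibble(
      sample_id = expr$sample_id,
      stage = rep(c("II", "III"), length.out = n),
      recurrence = rep(c(0L, 1L), length.out = n),
      dfs_time = runif(n, 12, 90),
      dfs_event = rep(c(0L, 1L), length.out = n),
      dss_time = runif(n, 12, 90),
      dss_event = rep(c(0L, 0L, 1L), length.out = n)
    )
    cohort(expr, clin, "toy")
  })
}
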