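#' Fit a qPCR standard curve
#'
#' Least-squares line `Cq = slope * log10(amount) + intercept` through
#' serial-dilution points, with the amplification efficiency
#' `E = 10^(-1/slope) - 1` (a perfect doubling per cycle gives slope
#' -3.3219 and E = 1).
#'
#' @param log10_dilution Log10 relative input amounts (at least 3 distinct).
#' @param cq Quantification-cycle values, same length.
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r2`, `n_points`.
#' @examples
#' fit_standard_curve(0:-4, 18 + 3.3219 * (0:4))
#' @export
fit_standard_curve <- function(log10_dilution, cq) {
  if (length(log10_dilution) != length(cq)) abort("inputs must have equal length")
  if (length(unique(log10_dilution)) < 3) {
    abort("need at least 3 distinct dilution points")
  }
  if (any(cq <= 0)) abort("Cq values must be positive")
  fit <- lm(cq ~ log10_dilution)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("non-physical standard curve: slope must be negative")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r2 = 1 - ss_res / ss_tot,
                 n_points = length(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> slope ", format(x$slope, digits = 5),
      ", efficiency ", format(100 * x$efficiency, digits = 4), "%",
      ", R2 ", format(x$r2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Quantify a Cq value against a standard curve
#'
#' Inverts the standard curve: `amount = 10^((cq - intercept) / slope)`,
#' monotone decreasing in `cq`.
#'
#' @param cq Cq value(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Relative amounts.
#' @export
quantify_cq <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' geNorm expression-stability measure M
#'
#' For each candidate reference gene g, `M(g)` is the mean over the other
#' candidates h of the standard deviation across samples of the pairwise
#' log2 expression ratio `log2(q_g / q_h)`. Lower M means more stable.
#' Iteratively removing the least stable gene (highest M) yields the
#' geNorm ranking; the final two genes cannot be distinguished by the
#' measure and share rank 1.
#'
#' @param quantities Tibble (`sample_id` + one column of positive relative
#'   quantities per candidate gene) or a samples-by-genes matrix. At least
#'   3 candidates and 5 samples.
#' @return A tibble: `gene`, `m` (M with all candidates included),
#'   `rank` (iterative-exclusion rank; ties at the top).
#' @export
genorm_stability <- function(quantities) {
  Q <- if (is.data.frame(quantities)) expr_to_matrix(quantities) else quantities
  if (ncol(Q) < 3) abort("geNorm needs at least 3 candidate genes")
  if (nrow(Q) < 5) abort("geNorm needs at least 5 samples")
  if (any(Q <= 0)) abort("quantities must be positive (log-ratios undefined)")
  L <- log2(Q)

  m_values <- function(L) {
    g <- ncol(L)
    vapply(seq_len(g), function(i) {
      mean(vapply(setdiff(seq_len(g), i),
                  function(j) sd(L[, i] - L[, j]), numeric(1)))
    }, numeric(1))
  }

  m_full <- setNames(m_values(L), colnames(L))
  remaining <- colnames(L)
  rank_order <- character(0)
  while (length(remaining) > 2) {
    m <- m_values(L[, remaining, drop = FALSE])
    worst <- remaining[which.max(m)]
    rank_order <- c(worst, rank_order)
    remaining <- setdiff(remaining, worst)
  }
  ranks <- setNames(rep(1, ncol(L)), colnames(L))
  ranks[remaining] <- 1            # final pair shares rank 1
  if (length(rank_order)) ranks[rank_order] <- 2 + seq_along(rank_order)

  tibble(gene = colnames(L), m = unname(m_full),
         rank = unname(ranks[colnames(L)])) %>%
    arrange(.data$rank, .data$m)
}

#' Comparative delta-Ct reference-gene stability
#'
#' For each candidate gene g, the mean over partner candidates h of the
#' standard deviation across samples of the Cq difference
#' `Cq_g - Cq_h`. Lower values indicate more stable expression. Missing
#' Cq values are handled pairwise-complete and the usable sample counts
#' are reported.
#'
#' @param cq_table Tibble (`sample_id` + one Cq column per candidate) or a
#'   samples-by-genes matrix of Cq values. At least 2 candidates.
#' @return A tibble: `gene`, `delta_ct_sd`, `min_pair_n` (smallest
#'   pairwise-complete sample count entering the value).
#' @export
delta_ct_stability <- function(cq_table) {
  Q <- if (is.data.frame(cq_table)) expr_to_matrix(cq_table) else cq_table
  if (ncol(Q) < 2) abort("delta-Ct stability needs at least 2 candidates")
  g <- ncol(Q)
  res <- lapply(seq_len(g), function(i) {
    sds <- npair <- numeric(0)
    for (j in setdiff(seq_len(g), i)) {
      d <- Q[, i] - Q[, j]
      d <- d[!is.na(d)]
      sds <- c(sds, sd(d))
      npair <- c(npair, length(d))
    }
    c(mean(sds), min(npair))
  })
  tibble(gene = colnames(Q),
         delta_ct_sd = vapply(res, `[`, numeric(1), 1),
         min_pair_n = as.integer(vapply(res, `[`, numeric(1), 2))) %>%
    arrange(.data$delta_ct_sd)
}

#' Normalize target amounts to reference genes
#'
#' Divides each target gene's relative amount by the per-sample geometric
#' mean of the reference genes (default *ACTB* and *PMM1*), then log2
#' transforms and standardizes each gene to a z-score, producing
#' expression directly usable by [compute_score()].
#'
#' @param amounts Tibble (`sample_id` + one positive amount column per
#'   gene, references included).
#' @param references Reference gene ids (default ACTB, PMM1); their
#'   amounts must be strictly positive for every sample.
#' @param log2_transform,standardize Apply the log2 transform and per-gene
#'   z-scoring (defaults TRUE; disable for raw normalized ratios).
#' @return Expression tibble of the non-reference genes.
#' @export
normalize_to_references <- function(amounts, references = c("ACTB", "PMM1"),
                                    log2_transform = TRUE, standardize = TRUE) {
  genes <- expr_genes(amounts)
  missing <- setdiff(references, genes)
  if (length(missing)) {
    abort(paste0("reference gene(s) missing: ", paste(missing, collapse = ", ")))
  }
  A <- expr_to_matrix(amounts)
  refm <- A[, references, drop = FALSE]
  bad <- rowSums(refm <= 0 | is.na(refm)) > 0
  if (any(bad)) {
    abort(paste0("non-positive reference amount for sample(s): ",
                 paste(rownames(A)[bad], collapse = ", ")))
  }
  gm <- exp(rowMeans(log(refm)))
  targets <- setdiff(genes, references)
  N <- A[, targets, drop = FALSE] / gm
  if (log2_transform) {
    if (any(N <= 0, na.rm = TRUE)) abort("non-positive normalized amount; cannot log-transform")
    N <- log2(N)
  }
  out <- matrix_to_expr(N)
  if (standardize) out <- zscore_genes(out)
  out
}

#' Rank candidate reference genes by combined stability
#'
#' Runs both implemented stability measures -- geNorm M (on relative
#' quantities `2^-Cq`, equivalent up to per-sample factors that cancel in
#' the ratios) and the comparative delta-Ct SD -- and combines them by the
#' geometric mean of the two per-method ranks, the aggregation used by
#' RefFinder-style comparisons.
#'
#' @param cq_table Long tibble with columns `sample`, `gene`, `cq` (or a
#'   wide `sample_id` + gene tibble of Cq values).
#' @param candidates Candidate gene ids (default: all genes present; at
#'   least 3). Replicate wells (duplicate sample/gene rows) are averaged
#'   before analysis.
#' @return A tibble of class `stability_ranking`, sorted by
#'   `combined_rank`: `gene`, `genorm_m`, `genorm_rank`, `delta_ct_sd`,
#'   `delta_ct_rank`, `combined_rank`.
#' @export
rank_reference_candidates <- function(cq_table, candidates = NULL) {
  wide <- if (all(c("sample", "gene", "cq") %in% names(cq_table))) {
    as_tibble(cq_table) %>%
      group_by(.data$sample, .data$gene) %>%
      summarise(cq = mean(.data$cq), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "gene", values_from = "cq") %>%
      rename(sample_id = "sample")
  } else {
    as_tibble(cq_table)
  }
  candidates <- candidates %||% expr_genes(wide)
  if (length(candidates) < 3) abort("need at least 3 candidate reference genes")
  missing <- setdiff(candidates, expr_genes(wide))
  if (length(missing)) {
    abort(paste0("candidate(s) missing from Cq table: ",
                 paste(missing, collapse = ", ")))
  }
  wide <- wide[c("sample_id", candidates)]
  cqm <- expr_to_matrix(wide)

  gn <- genorm_stability(matrix_to_expr(2^(-cqm)))
  dc <- delta_ct_stability(wide)
  gn$genorm_rank <- rank(gn$m, ties.method = "average")
  dc$delta_ct_rank <- rank(dc$delta_ct_sd, ties.method = "average")

  out <- tibble(gene = candidates) %>%
    left_join(select(gn, "gene", genorm_m = "m", "genorm_rank"), by = "gene") %>%
    left_join(select(dc, "gene", "delta_ct_sd", "delta_ct_rank"), by = "gene") %>%
    mutate(combined_rank = sqrt(.data$genorm_rank * .data$delta_ct_rank)) %>%
    arrange(.data$combined_rank, .data$gene)
  class(out) <- c("stability_ranking", class(out))
  out
}
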