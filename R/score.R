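#' Per-gene z-score standardization
#'
#' Standardizes each gene to mean 0 and sample SD 1 within the dataset.
#' Standardizing per dataset before any score computation (and before
#' pooling cohorts) removes centre/platform location-scale effects, which
#' is what makes the equal-weight score comparable across cohorts.
#' Zero-variance genes are set to all zeros with a warning, so they
#' contribute nothing to downstream scores rather than aborting a cohort.
#'
#' @param expression Expression tibble (`sample_id` + gene columns).
#' @return The standardized expression tibble, same shape.
#' @examples
#' zscore_genes(tibble::tibble(sample_id = c("a", "b", "c"), g = c(1, 2, 3)))
#' @export
zscore_genes <- function(expression) {
  X <- expr_to_matrix(expression)
  if (nrow(X) < 2) abort("need at least 2 samples to standardize")
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  zero <- sds == 0
  if (any(zero)) {
    warn(paste0("zero-variance gene(s) standardized to 0: ",
                paste(colnames(X)[zero], collapse = ", ")))
    sds[zero] <- 1
  }
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  Z[, zero] <- 0
  matrix_to_expr(Z)
}

#' Equal-weight signed z-score risk statistic
#'
#' The recurrence score of a sample is the sum of its standardized
#' expression values over the classifier genes, each multiplied by the
#' gene's +1/-1 coefficient: for the published classifier
#' `S = z_PDLIM3 + z_AMIGO2 + z_SLC7A2 + z_ULBP2 - z_CCL11`.
#'
#' @param expression *Standardized* expression tibble (see
#'   [zscore_genes()]); the function does not re-standardize.
#' @param classifier A [classifier()]. All classifier genes must be
#'   present; a missing gene is an error (never silently imputed).
#' @return A tibble with `sample_id` and `score`.
#' @export
compute_score <- function(expression, classifier) {
  stopifnot(inherits(classifier, "caf_classifier"))
  Z <- expr_to_matrix(expression)
  missing <- setdiff(classifier$genes$gene, colnames(Z))
  if (length(missing)) {
    abort(paste0("classifier gene(s) missing from expression: ",
                 paste(missing, collapse = ", ")))
  }
  s <- as.vector(Z[, classifier$genes$gene, drop = FALSE] %*%
                   classifier$genes$coefficient)
  tibble(sample_id = rownames(Z), score = s)
}

#' Tertile cutoff of training scores
#'
#' Returns the 66.66th percentile (third tertile) of the training scores,
#' computed with linear interpolation between order statistics. The cutoff
#' derived on a training cohort is then applied unchanged to every
#' validation cohort. The published training-set value is 1.1328 (see
#' [published_classifier()]).
#'
#' @param scores Numeric scores (at least 3).
#' @param quantile Percentile as a proportion (default 0.6666).
#' @return The cutoff value.
#' @examples
#' derive_cutoff(c(0, 1, 2, 3, 4, 5))  # 3.333
#' @export
derive_cutoff <- function(scores, quantile = 0.6666) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 3) abort("need at least 3 scores to derive a cutoff")
  unname(stats::quantile(scores, probs = quantile, type = 7))
}

#' Dichotomize scores at a cutoff
#'
#' Scores strictly above the cutoff are called `"high"` risk, scores at or
#' below it `"low"` (a tie goes to low: only strict inequalities are
#' defined by the published rule, so the tie-break must simply be
#' deterministic).
#'
#' @param scores Numeric scores.
#' @param cutoff Finite cutoff, e.g. from [derive_cutoff()] or a
#'   [classifier()]'s `cutoff`.
#' @return Factor with levels `low`, `high`.
#' @export
classify_risk <- function(scores, cutoff) {
  if (!is.finite(cutoff)) abort("cutoff must be finite")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Collagen score: a stromal-quantity proxy
#'
#' The collagen score of a sample is the mean expression of the
#' fibroblast-specific collagen genes *COL1A1* and *COL3A1*. It tracks the
#' quantity of fibroblasts in a sample, not their state, and is used to
#' flag samples with too little stroma for a stromal classifier to read.
#' By default the constituent genes are standardized first (the same
#' convention as the risk score, for cross-platform comparability); set
#' `standardize = FALSE` for the raw-scale average.
#'
#' @param expression Expression tibble.
#' @param genes Collagen gene ids (default COL1A1, COL3A1); all must be
#'   present.
#' @param standardize Standardize genes before averaging (default TRUE).
#' @return A tibble with `sample_id` and `collagen_score`.
#' @export
collagen_score <- function(expression, genes = c("COL1A1", "COL3A1"),
                           standardize = TRUE) {
  missing <- setdiff(genes, expr_genes(expression))
  if (length(missing)) {
    abort(paste0("collagen gene(s) missing: ", paste(missing, collapse = ", ")))
  }
  ex <- expression[c("sample_id", genes)]
  if (standardize) ex <- zscore_genes(ex)
  M <- expr_to_matrix(ex)
  tibble(sample_id = rownames(M), collagen_score = unname(rowMeans(M)))
}

#' Score a cohort: risk score, risk class and collagen score
#'
#' Convenience wrapper: standardizes the cohort's expression within the
#' dataset, computes the classifier score, dichotomizes at the
#' classifier's cutoff, and attaches the collagen score when the collagen
#' genes are present.
#'
#' @param cohort A [cohort()].
#' @param classifier A [classifier()] (default [published_classifier()]).
#' @param cutoff Optional cutoff override.
#' @return A `risk_profile` tibble: `sample_id`, `score`, `risk_class`,
#'   and `collagen_score` when available.
#' @examples
#' sim <- simulate_cohort(sim_params(seed = 2))
#' profile <- score_cohort(sim$cohort)
#' table(profile$risk_class)
#' @export
score_cohort <- function(cohort, classifier = published_classifier(),
                         cutoff = NULL) {
  stopifnot(inherits(cohort, "caf_cohort"))
  z <- zscore_genes(cohort$expression)
  out <- compute_score(z, classifier)
  out$risk_class <- classify_risk(out$score, cutoff %||% classifier$cutoff)
  cg <- c("COL1A1", "COL3A1")
  if (all(cg %in% expr_genes(cohort$expression))) {
    out <- left_join(out, collagen_score(cohort$expression), by = "sample_id")
  }
  class(out) <- c("risk_profile", class(out))
  out
}

#' Pool cohorts into a z-scored meta-cohort
#'
#' Expression is transformed to per-gene z-scores within each dataset
#' before samples are concatenated, so that centre/hospital location and
#' scale differences cancel. Only genes common to all cohorts are kept;
#' clinical tables are outer-joined (columns missing in a cohort become
#' explicit `NA`s) and the originating `dataset_id` is retained per sample
#' in a `dataset` column.
#'
#' @param cohorts List of at least 2 [cohort()] objects with disjoint
#'   sample ids.
#' @param dataset_id Label for the pooled cohort.
#' @return A [cohort()] whose expression is already standardized per
#'   source dataset (do not re-standardize before scoring; pass
#'   `standardize = FALSE` conventions accordingly).
#' @export
pool_metacohort <- function(cohorts, dataset_id = "metacohort") {
  if (length(cohorts) < 2) abort("need at least 2 cohorts to pool")
  lapply(cohorts, function(x) stopifnot(inherits(x, "caf_cohort")))
  all_ids <- unlist(lapply(cohorts, function(x) x$expression$sample_id))
  if (anyDuplicated(all_ids)) {
    abort(paste0("duplicated sample ids across cohorts: ",
                 paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  }
  common <- Reduce(intersect, lapply(cohorts, function(x) expr_genes(x$expression)))
  if (!length(common)) abort("cohorts share no genes")
  expr <- bind_rows(lapply(cohorts, function(x) {
    zscore_genes(x$expression[c("sample_id", common)])
  }))
  clin <- bind_rows(lapply(cohorts, function(x) {
    mutate(x$clinical, dataset = x$dataset_id)
  }))
  cohort(expr, clin, dataset_id)
}

#' Exclude very low-stroma samples by collagen-score percentile
#'
#' Removes samples whose collagen score falls below the given percentile
#' of the cohort's collagen-score distribution, retaining samples at or
#' above the empirical (inverse-CDF) percentile value. With distinct
#' scores this retains exactly `ceiling((1 - p/100) * n)` samples, e.g.
#' 107 of 142 at the 25th percentile.
#'
#' @param cohort A [cohort()].
#' @param profile A `risk_profile` (or any tibble with `sample_id` and
#'   `collagen_score`).
#' @param percentile Percentile in `[0, 100)` (default 25).
#' @return The filtered [cohort()]; the number retained is reported via a
#'   message and attribute `n_retained`.
#' @export
filter_by_collagen <- function(cohort, profile, percentile = 25) {
  stopifnot(inherits(cohort, "caf_cohort"))
  if (percentile < 0 || percentile >= 100) abort("`percentile` must be in [0, 100)")
  if (!"collagen_score" %in% names(profile)) {
    abort("`profile` must contain a collagen_score column")
  }
  cs <- profile$collagen_score[match(cohort$expression$sample_id, profile$sample_id)]
  if (anyNA(cs)) abort("collagen scores missing for some cohort samples")
  thr <- unname(stats::quantile(cs, probs = percentile / 100, type = 1))
  keep <- cs >= thr
  out <- cohort(cohort$expression[keep, ], cohort$clinical[keep, ],
                cohort$dataset_id)
  inform(paste0("collagen filter at percentile ", percentile, ": retained ",
                sum(keep), " of ", length(keep), " samples"))
  attr(out, "n_retained") <- sum(keep)
  out
}
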