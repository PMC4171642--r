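#' Assemble an expression + clinical cohort
#'
#' A cohort bundles a log-scale expression table (samples by genes) with an
#' aligned clinical table and a dataset label. It is the unit every pipeline
#' stage consumes: signature discovery, risk scoring, survival evaluation and
#' post-test analysis all take a cohort (or the tibbles inside one).
#'
#' @param expression Tibble with a `sample_id` column followed by one numeric
#'   column per gene (log2-like scale, as produced by RMA-style
#'   normalization). Gene names must be unique.
#' @param clinical Tibble with one row per sample. Must contain `sample_id`;
#'   analyses additionally expect `stage` (one of `"I"`, `"II"`, `"III"`),
#'   `recurrence` (0/1), `dfs_time` / `dfs_event` and optionally `dss_time` /
#'   `dss_event` (times in months) plus any covariates.
#' @param dataset_id Character label for the originating dataset or platform.
#'
#' @return An object of class `caf_cohort`: a list with elements
#'   `expression`, `clinical` and `dataset_id`.
#'
#' @examples
#' expr <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
#'                        PDLIM3 = c(7.1, 8.3, 6.9), CCL11 = c(5.2, 4.8, 5.5))
#' clin <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
#'                        stage = c("II", "III", "II"),
#'                        recurrence = c(0, 1, 0),
#'                        dfs_time = c(60, 14, 48), dfs_event = c(0, 1, 0))
#' cohort(expr, clin, "toy")
#' @export
cohort <- function(expression, clinical, dataset_id = "cohort") {
  expression <- as_tibble(expression)
  clinical <- as_tibble(clinical)
  if (!"sample_id" %in% names(expression)) abort("expression needs a `sample_id` column")
  if (!"sample_id" %in% names(clinical)) abort("clinical needs a `sample_id` column")
  expression$sample_id <- as.character(expression$sample_id)
  clinical$sample_id <- as.character(clinical$sample_id)
  if (anyDuplicated(expression$sample_id)) abort("duplicated sample ids in expression")
  if (anyDuplicated(clinical$sample_id)) abort("duplicated sample ids in clinical")
  if (anyDuplicated(expr_genes(expression))) abort("duplicated gene ids in expression")
  if (!setequal(expression$sample_id, clinical$sample_id)) {
    abort("expression and clinical must cover the same sample ids")
  }
  # align clinical to expression order
  clinical <- clinical[match(expression$sample_id, clinical$sample_id), ]
  if ("stage" %in% names(clinical) &&
      !all(clinical$stage %in% c("I", "II", "III", NA))) {
    abort("stage labels must be one of I, II, III")
  }
  if ("recurrence" %in% names(clinical)) check_binary(clinical$recurrence, "recurrence")
  for (tm in c("dfs", "dss")) {
    tcol <- paste0(tm, "_time"); ecol <- paste0(tm, "_event")
    if (tcol %in% names(clinical)) {
      if (any(clinical[[tcol]] < 0, na.rm = TRUE)) abort(paste0(tcol, " must be non-negative"))
    }
    if (ecol %in% names(clinical)) {
      check_binary(clinical[[ecol]], ecol)
      if (tcol %in% names(clinical) &&
          any(clinical[[ecol]] == 1 & is.na(clinical[[tcol]]), na.rm = TRUE)) {
        abort(paste0(ecol, " = 1 requires a recorded ", tcol))
      }
    }
  }
  structure(
    list(expression = expression, clinical = clinical,
         dataset_id = as.character(dataset_id)),
    class = "caf_cohort"
  )
}

#' @export
print.caf_cohort <- function(x, ...) {
  cat("<caf_cohort> ", x$dataset_id, ": ",
      nrow(x$expression), " samples x ", length(expr_genes(x$expression)),
      " genes\n", sep = "")
  cc <- x$clinical
  if ("stage" %in% names(cc)) {
    cat("  stage: ", paste(names(table(cc$stage)), table(cc$stage),
                           sep = "=", collapse = ", "), "\n", sep = "")
  }
  if ("recurrence" %in% names(cc)) {
    cat("  recurrence: ", sum(cc$recurrence == 1, na.rm = TRUE), "/",
        nrow(cc), "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A [cohort()] object.
#' @return Integer sample count.
#' @export
n_samples <- function(cohort) {
  stopifnot(inherits(cohort, "caf_cohort"))
  nrow(cohort$expression)
}
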