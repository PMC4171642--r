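#' Build a signed equal-weight gene classifier
#'
#' A classifier is an ordered gene list with coefficients restricted to
#' +1 (risk gene, overexpressed in CAFs versus paired normal fibroblasts)
#' or -1 (protective gene, underexpressed in CAFs), together with a score
#' cutoff. No per-gene weights are estimated: every gene carries the same
#' biological weight and the risk score is the signed sum of per-gene
#' z-scores (see [compute_score()]).
#'
#' @param genes Character vector of gene ids (unique).
#' @param coefficients Numeric vector of +1 / -1, one per gene.
#' @param cutoff Finite score threshold; scores strictly above it are called
#'   high risk.
#' @return An object of class `caf_classifier`.
#' @seealso [published_classifier()] for the published 5-gene instance.
#' @export
classifier <- function(genes, coefficients, cutoff) {
  genes <- as.character(genes)
  coefficients <- as.numeric(coefficients)
  if (length(genes) != length(coefficients)) abort("one coefficient per gene required")
  if (length(genes) == 0) abort("classifier needs at least one gene")
  if (anyDuplicated(genes)) abort("classifier gene ids must be unique")
  if (!all(coefficients %in% c(-1, 1))) abort("coefficients must be +1 or -1")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff)) {
    abort("cutoff must be a single finite number")
  }
  structure(
    list(genes = tibble(gene = genes, coefficient = coefficients),
         cutoff = as.numeric(cutoff)),
    class = "caf_classifier"
  )
}

#' The published 5-gene CAF classifier
#'
#' The published prognostic classifier for colorectal-cancer recurrence:
#' four risk genes (*PDLIM3*, *AMIGO2*, *SLC7A2*, *ULBP2*, coefficient +1)
#' and one protective gene (*CCL11*, coefficient -1), with the published
#' training-set cutoff 1.1328 (the third tertile of the classifier score in
#' the training cohort). The cutoff is a published constant: it can only be
#' re-derived from the original training data, so it ships verbatim and is
#' applied unchanged to any validation cohort.
#'
#' @return A [classifier()] object.
#' @examples
#' published_classifier()
#' @export
published_classifier <- function() {
  classifier(
    genes = c("PDLIM3", "AMIGO2", "SLC7A2", "ULBP2", "CCL11"),
    coefficients = c(1, 1, 1, 1, -1),
    cutoff = 1.1328
  )
}

#' @export
print.caf_classifier <- function(x, ...) {
  cat("<caf_classifier> ", nrow(x$genes), " genes, cutoff ",
      format(x$cutoff), "\n", sep = "")
  sgn <- ifelse(x$genes$coefficient > 0, "+", "-")
  cat("  ", paste0(sgn, x$genes$gene, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @describeIn classifier Tidy a classifier into a gene/coefficient tibble.
#' @param x A `caf_classifier`.
#' @param ... Unused.
#' @method tidy caf_classifier
#' @export
tidy.caf_classifier <- function(x, ...) x$genes

#' Read or write a classifier as JSON
#'
#' The JSON schema is `{"genes": [{"id": ..., "coefficient": ...}, ...],
#' "cutoff": ...}`.
#'
#' @param x A [classifier()].
#' @param path File path.
#' @return `write_classifier()` returns `path` invisibly; `read_classifier()`
#'   returns a [classifier()].
#' @export
write_classifier <- function(x, path) {
  stopifnot(inherits(x, "caf_classifier"))
  obj <- list(
    genes = lapply(seq_len(nrow(x$genes)), function(i) {
      list(id = x$genes$gene[i], coefficient = x$genes$coefficient[i])
    }),
    cutoff = x$cutoff
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path)
  classifier(
    genes = vapply(obj$genes, function(g) g$id, character(1)),
    coefficients = vapply(obj$genes, function(g) g$coefficient, numeric(1)),
    cutoff = obj$cutoff
  )
}
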