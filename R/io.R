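#' Read an expression table
#'
#' Reads a TSV/CSV expression file (first column = row ids) into the
#' package's samples-by-genes convention. Files may store samples as rows
#' or genes as rows; declare which with `orientation`, or pass
#' `sample_ids` (e.g. from an already-read clinical table) for
#' auto-detection by id overlap.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param orientation `"samples_rows"`, `"genes_rows"`, or `"auto"`
#'   (requires `sample_ids`).
#' @param sample_ids Optional known sample ids for auto-detection.
#' @return Expression tibble (`sample_id` + gene columns).
#' @export
read_expression <- function(path, orientation = c("samples_rows", "genes_rows", "auto"),
                            sample_ids = NULL) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(raw) < 2) abort("expression file needs an id column plus data")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated row id(s) in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  vals <- raw[-1]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))
      abort(paste0("non-numeric value in column `", names(vals)[j], "`",
                   if (length(bad)) paste0(", row ", bad[1]) else ""))
    }
  }
  if (orientation == "auto") {
    if (is.null(sample_ids)) abort("orientation = 'auto' needs `sample_ids`")
    orientation <- if (mean(ids %in% sample_ids) >=
                       mean(names(vals) %in% sample_ids)) "samples_rows" else "genes_rows"
  }
  if (orientation == "samples_rows") {
    out <- tibble(sample_id = ids) %>% dplyr::bind_cols(vals)
  } else {
    m <- t(as.matrix(vals))
    colnames(m) <- ids
    rownames(m) <- names(vals)
    out <- matrix_to_expr(m)
  }
  if (anyDuplicated(expr_genes(out))) abort("duplicated gene ids after reading")
  out
}

#' Write an expression table
#'
#' @param expression Expression tibble.
#' @param path Output path (`.csv` comma, otherwise tab).
#' @param orientation Store samples as rows (default) or genes as rows.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path,
                             orientation = c("samples_rows", "genes_rows")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- if (orientation == "samples_rows") {
    expression
  } else {
    m <- t(expr_to_matrix(expression))
    tibble(gene = rownames(m)) %>% dplyr::bind_cols(as_tibble(m))
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Reads a CSV/TSV clinical table and validates the controlled
#' vocabularies: `stage` must be I/II/III (stage IV disease is outside the
#' scope of a recurrence classifier), and binary flags must be 0/1.
#'
#' @param path File path.
#' @param require Columns that must be present (besides `sample_id`);
#'   e.g. `c("dfs_time", "dfs_event")` when survival analysis is planned.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path, require = character()) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cc <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!"sample_id" %in% names(cc)) abort("clinical table needs a `sample_id` column")
  missing <- setdiff(require, names(cc))
  if (length(missing)) {
    abort(paste0("required clinical column(s) missing: ",
                 paste(missing, collapse = ", ")))
  }
  if ("stage" %in% names(cc)) {
    bad <- setdiff(unique(stats::na.omit(cc$stage)), c("I", "II", "III"))
    if (length(bad)) {
      abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
    }
  }
  for (flag in intersect(c("recurrence", "dfs_event", "dss_event"), names(cc))) {
    check_binary(cc[[flag]], flag)
  }
  cc
}

#' Run the full pipeline from a configuration
#'
#' Executes the toggled stages -- `simulate` (synthetic cohort),
#' `discover` (stability selection), `score`, `validate` (ROC +
#' Kaplan-Meier) and `posttest` -- and writes every output plus a manifest
#' (parameters, seeds, package version, file checksums) so a run can be
#' reproduced bit for bit.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `seed`, `out_dir`, `stages` (character subset of
#'   simulate/discover/score/validate/posttest), `sim` (overrides for
#'   [sim_params()]), `stability` (overrides for [stability_params()]),
#'   `classifier` (path to a classifier JSON; used instead of discovery),
#'   `cutoff` (override), `expression`/`clinical` (input paths when not
#'   simulating, with `orientation`).
#' @return A list with the stage results (`cohort`, `stability`,
#'   `classifier`, `profile`, `roc`, `km`, `posttest`) and the manifest,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("stromasig_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "discover", "score", "validate", "posttest")
  res <- list()
  manifest <- list(package = "stromasig",
                   version = as.character(utils::packageVersion("stromasig")),
                   seed = seed, stages = stages, parameters = list(),
                   outputs = list(), complete = FALSE)

  write_out <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest$outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  if ("simulate" %in% stages) {
    sp <- do.call(sim_params, modifyList(list(seed = seed), config$sim %||% list()))
    manifest$parameters$sim <- unclass(sp)
    sim <- simulate_cohort(sp)
    res$cohort <- sim$cohort
    res$truth <- sim$truth
    write_out(sim$cohort$expression, "expression.tsv", write_expression)
    write_out(sim$cohort$clinical, "clinical.csv",
              function(x, p) readr::write_csv(x, p))
    write_out(sim$truth, "truth.json",
              function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA))
  } else {
    if (is.null(config$expression) || is.null(config$clinical)) {
      abort("without the simulate stage, `expression` and `clinical` paths are required")
    }
    clin <- read_clinical(config$clinical)
    expr <- read_expression(config$expression,
                            orientation = config$orientation %||% "auto",
                            sample_ids = clin$sample_id)
    res$cohort <- cohort(expr, clin, config$dataset_id %||% "input")
  }

  cls <- NULL
  if (!is.null(config$classifier)) cls <- read_classifier(config$classifier)
  if ("discover" %in% stages && is.null(cls)) {
    stp <- do.call(stability_params,
                   modifyList(list(seed = substream_seed(seed, "discover")),
                              config$stability %||% list()))
    manifest$parameters$stability <- unclass(stp)
    res$stability <- stability_select(res$cohort, stp)
    write_out(res$stability$stability, "stability.tsv",
              function(x, p) readr::write_tsv(x, p))
    cls <- res$stability$consensus
    if (is.null(cls)) {
      warn("empty consensus signature; falling back to the published classifier")
    }
  }
  cls <- cls %||% published_classifier()
  if (!is.null(config$cutoff)) cls$cutoff <- config$cutoff
  res$classifier <- cls
  write_out(cls, "classifier.json", write_classifier)

  if ("score" %in% stages) {
    res$profile <- score_cohort(res$cohort, cls)
    write_out(res$profile, "risk_profile.csv",
              function(x, p) readr::write_csv(x, p))
  }
  if ("validate" %in% stages && !is.null(res$profile)) {
    clin <- res$cohort$clinical
    res$roc <- roc_auc(res$profile$score, clin$recurrence)
    res$km <- km_logrank(clin$dfs_time, clin$dfs_event, res$profile$risk_class)
    metrics <- c(as.list(res$roc), glance(res$km))
    write_out(metrics, "validate.json",
              function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA))
  }
  if ("posttest" %in% stages && !is.null(res$profile)) {
    res$posttest <- posttest_table(res$cohort, res$profile)
    write_out(res$posttest, "posttest.csv",
              function(x, p) readr::write_csv(x, p))
  }

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
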