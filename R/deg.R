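#' Criteria for paired CAF/NCF differential-expression filtering
#'
#' The filter retains genes that (i) have an annotated gene symbol,
#' (ii) mean log expression above `min_mean_log_expr`, (iii) standard
#' deviation of log expression above `min_sd_log_expr`, (iv) paired-test
#' q-value (Benjamini-Hochberg over the tested genes) below `max_q`, and
#' (v) a mean per-pair linear-scale fold change strictly above `fc_up`
#' (overexpressed) or strictly below `fc_down` (underexpressed).
#'
#' @param min_mean_log_expr Minimum mean log2 expression (default 4).
#' @param min_sd_log_expr Minimum SD of log2 expression (default 0.1).
#' @param max_q Maximum Benjamini-Hochberg q-value (default 0.05).
#' @param fc_up,fc_down Fold-change bounds on the linear scale (defaults 2
#'   and 0.5); both comparisons are strict.
#' @param require_gene_symbol Drop genes with empty/NA ids (default TRUE).
#' @return A list of class `deg_criteria`.
#' @export
deg_criteria <- function(min_mean_log_expr = 4, min_sd_log_expr = 0.1,
                         max_q = 0.05, fc_up = 2, fc_down = 0.5,
                         require_gene_symbol = TRUE) {
  if (!(fc_down < 1 && 1 < fc_up)) abort("need fc_down < 1 < fc_up")
  if (max_q <= 0 || max_q >= 1) abort("`max_q` must be in (0, 1)")
  if (min_mean_log_expr <= 0 || min_sd_log_expr <= 0) {
    abort("expression thresholds must be positive")
  }
  structure(list(min_mean_log_expr = min_mean_log_expr,
                 min_sd_log_expr = min_sd_log_expr, max_q = max_q,
                 fc_up = fc_up, fc_down = fc_down,
                 require_gene_symbol = require_gene_symbol),
            class = "deg_criteria")
}

#' Filter differentially expressed genes between paired CAF and NCF profiles
#'
#' Applies the full DEG filter to paired fibroblast profiles: per gene a
#' two-sided paired t-test on the log2 CAF-vs-NCF differences with
#' Benjamini-Hochberg adjustment across tested genes, a mean/SD expression
#' floor, and a mean per-pair fold change computed on the linear scale
#' (`mean(2^(caf - ncf))`). All criteria must hold simultaneously.
#'
#' Genes whose paired differences have zero variance cannot be tested and
#' are skipped with a warning.
#'
#' @param profiles A `paired_profiles` tibble (columns `gene`, `pair`,
#'   `ncf`, `caf`), e.g. from [simulate_paired_profiles()], with at least 3
#'   complete pairs per gene.
#' @param criteria A [deg_criteria()] object.
#' @return A tibble with one row per gene: `gene`, `mean_log_expr`,
#'   `sd_log_expr`, `fold_change`, `p_value`, `q_value`, `deg` (logical).
#'   The DEG gene ids are also attached as attribute `genes`.
#' @examples
#' pp <- simulate_paired_profiles(sim_params(n_genes = 30, seed = 3), n_pairs = 8)
#' degs <- filter_degs(pp)
#' attr(degs, "genes")
#' @export
filter_degs <- function(profiles, criteria = deg_criteria()) {
  stopifnot(inherits(criteria, "deg_criteria"))
  req <- c("gene", "pair", "ncf", "caf")
  if (!all(req %in% names(profiles))) {
    abort("`profiles` must have columns gene, pair, ncf, caf (paired structure)")
  }
  prof <- as_tibble(profiles)[req]
  npairs <- prof %>% count(.data$gene) %>% pull(n)
  if (any(npairs < 3)) abort("at least 3 pairs per gene are required")
  if (length(unique(npairs)) != 1) {
    abort("unbalanced pairs: every gene must appear once per pair")
  }

  stats <- prof %>%
    group_by(.data$gene) %>%
    summarise(
      mean_log_expr = mean(c(.data$ncf, .data$caf)),
      sd_log_expr = sd(c(.data$ncf, .data$caf)),
      fold_change = mean(2^(.data$caf - .data$ncf)),
      diff_mean = mean(.data$caf - .data$ncf),
      diff_sd = sd(.data$caf - .data$ncf),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )

  zero_var <- stats$diff_sd == 0
  if (any(zero_var)) {
    warn(paste0("skipping zero-variance gene(s) under the paired test: ",
                paste(stats$gene[zero_var], collapse = ", ")))
  }
  tstat <- ifelse(zero_var, NA_real_,
                  stats$diff_mean / (stats$diff_sd / sqrt(stats$n_pairs)))
  p <- 2 * stats::pt(-abs(tstat), df = stats$n_pairs - 1)
  q <- rep(NA_real_, length(p))
  q[!zero_var] <- stats::p.adjust(p[!zero_var], method = "BH")

  has_symbol <- !is.na(stats$gene) & nzchar(stats$gene)
  keep <- (!criteria$require_gene_symbol | has_symbol) &
    stats$mean_log_expr > criteria$min_mean_log_expr &
    stats$sd_log_expr > criteria$min_sd_log_expr &
    !is.na(q) & q < criteria$max_q &
    (stats$fold_change > criteria$fc_up | stats$fold_change < criteria$fc_down)

  out <- stats %>%
    mutate(p_value = p, q_value = q, deg = keep) %>%
    select("gene", "mean_log_expr", "sd_log_expr", "fold_change",
           "p_value", "q_value", "deg") %>%
    arrange(desc(.data$deg), .data$q_value)
  attr(out, "genes") <- out$gene[out$deg]
  out
}
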