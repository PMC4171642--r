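#' Parameters for resampling-based stability selection
#'
#' Controls the signature-discovery loop: in each iteration the eligible
#' cohort is split 2:1 into training and test sets with stage
#' proportionality preserved, genes are screened by univariate logistic
#' regression of recurrence on expression in the training set, the
#' screened genes enter an L1-penalized multivariate logistic regression
#' (penalty chosen by internal cross-validation on the training set only),
#' and the genes with nonzero coefficients are recorded. The consensus
#' signature is the set of genes selected in strictly more than
#' `frequency_threshold` of completed iterations.
#'
#' @param n_iterations Number of resampling iterations (default 1000).
#' @param train_fraction Training proportion per stratum (default 2/3,
#'   rounded per stratum; the remainder forms the test set).
#' @param univariate_p Univariate screen threshold (default 0.01).
#' @param frequency_threshold Consensus frequency threshold (default 0.5,
#'   strict inequality).
#' @param min_followup_years Non-recurrent samples with less follow-up than
#'   this are excluded before resampling (default 3).
#' @param stratify_by Clinical column used for proportional resampling
#'   (default `"stage"`).
#' @param screen_on Whether the univariate screen uses the `"train"` split
#'   (default; the test split takes no part in gene selection) or the
#'   `"full"` eligible cohort once per iteration set.
#' @param seed Integer seed for the whole loop.
#' @return A list of class `stability_params`.
#' @export
stability_params <- function(n_iterations = 1000, train_fraction = 2 / 3,
                             univariate_p = 0.01, frequency_threshold = 0.5,
                             min_followup_years = 3, stratify_by = "stage",
                             screen_on = c("train", "full"), seed = 1L) {
  if (n_iterations < 1) abort("`n_iterations` must be at least 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1)")
  }
  if (univariate_p <= 0 || univariate_p >= 1) abort("`univariate_p` must be in (0, 1)")
  if (frequency_threshold <= 0 || frequency_threshold > 1) {
    abort("`frequency_threshold` must be in (0, 1]")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 univariate_p = univariate_p,
                 frequency_threshold = frequency_threshold,
                 min_followup_years = min_followup_years,
                 stratify_by = stratify_by,
                 screen_on = match.arg(screen_on),
                 seed = as.integer(seed)),
            class = "stability_params")
}

#' Exclude non-recurrent samples with short follow-up
#'
#' Non-recurrent samples whose disease-free follow-up is shorter than
#' `min_years` are uninformative about recurrence (they may simply not
#' have been observed long enough) and are removed. Recurrent samples are
#' always retained regardless of follow-up.
#'
#' @param cohort A [cohort()] with `recurrence` and `dfs_time` columns.
#' @param min_years Minimum follow-up for non-recurrent samples, in years
#'   (default 3; the comparison is `dfs_time < min_years * 12` months).
#' @return The filtered [cohort()].
#' @export
exclude_short_followup <- function(cohort, min_years = 3) {
  stopifnot(inherits(cohort, "caf_cohort"))
  cc <- cohort$clinical
  if (!all(c("recurrence", "dfs_time") %in% names(cc))) {
    abort("cohort clinical needs `recurrence` and `dfs_time`")
  }
  nonrec <- cc$recurrence == 0
  if (any(nonrec & is.na(cc$dfs_time))) {
    abort(paste0("missing follow-up time for non-recurrent sample(s): ",
                 paste(cc$sample_id[nonrec & is.na(cc$dfs_time)], collapse = ", ")))
  }
  drop <- nonrec & cc$dfs_time < min_years * 12
  keep <- cc$sample_id[!drop]
  cohort(cohort$expression[cohort$expression$sample_id %in% keep, ],
         cc[!drop, ], cohort$dataset_id)
}

#' Stage-proportional train/test resampling
#'
#' Draws a simple random sample of `round(train_fraction * n)` ids within
#' each stratum as the training set; the remainder is the test set. The
#' two are disjoint and exhaust the cohort.
#'
#' @param clinical Clinical tibble (or a [cohort()]).
#' @param train_fraction Training proportion (default 2/3).
#' @param stratify_by Stratification column (no missing values allowed).
#' @return A list with character vectors `train` and `test`.
#' @export
stratified_resample <- function(clinical, train_fraction = 2 / 3,
                                stratify_by = "stage") {
  if (inherits(clinical, "caf_cohort")) clinical <- clinical$clinical
  if (!stratify_by %in% names(clinical)) {
    abort(paste0("stratification column `", stratify_by, "` not found"))
  }
  s <- clinical[[stratify_by]]
  if (anyNA(s)) abort("stratification covariate has missing values")
  tab <- table(s)
  if (any(tab < 2)) {
    abort(paste0("stratum too small to split: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  train <- unlist(lapply(split(clinical$sample_id, s), function(ids) {
    sample(ids, round(train_fraction * length(ids)))
  }), use.names = FALSE)
  list(train = train, test = setdiff(clinical$sample_id, train))
}

# Vectorized Newton-Raphson for per-gene univariate logistic regression
# (intercept + one gene), with a small ridge on the information matrix so
# perfectly separating genes converge to a large bounded coefficient and a
# p-value near zero instead of diverging.
fast_logistic_screen <- function(X, y, ridge = 1e-4, max_iter = 50) {
  n <- length(y)
  G <- ncol(X)
  a <- rep(qlogis(mean(y)), G)
  b <- rep(0, G)
  for (it in seq_len(max_iter)) {
    eta <- sweep(X * rep(b, each = n), 2, a, "+")
    p <- plogis(eta)
    w <- p * (1 - p)
    r <- y - p
    s1 <- colSums(r) - ridge * a
    s2 <- colSums(r * X) - ridge * b
    i11 <- colSums(w) + ridge
    i12 <- colSums(w * X)
    i22 <- colSums(w * X * X) + ridge
    det <- i11 * i22 - i12^2
    da <- (i22 * s1 - i12 * s2) / det
    db <- (-i12 * s1 + i11 * s2) / det
    a <- a + da
    b <- b + db
    if (max(abs(db), abs(da)) < 1e-10) break
  }
  eta <- sweep(X * rep(b, each = n), 2, a, "+")
  p <- plogis(eta)
  w <- p * (1 - p)
  i11 <- colSums(w) + ridge
  i12 <- colSums(w * X)
  i22 <- colSums(w * X * X) + ridge
  se <- sqrt(i11 / (i11 * i22 - i12^2))
  z <- b / se
  pv <- 2 * pnorm(-abs(z))
  # (quasi-)separation: the ridge caps the coefficient but the Wald p is
  # meaningless there, so flag the gene as an extreme pass instead
  separated <- !is.finite(b) | colMeans(abs(y - p)) < 0.01
  pv[separated] <- 0
  tibble(gene = colnames(X), estimate = unname(b), se = unname(se),
         statistic = unname(z), p_value = unname(pv),
         separated = unname(separated))
}

#' Univariate logistic screen of genes against recurrence
#'
#' Fits, for each gene, a single-covariate logistic regression of the
#' binary recurrence status on expression and returns the Wald p-value.
#' Genes with Wald p below `p_threshold` are flagged as screened.
#' Constant (zero-variance) genes cannot be fit and are excluded with a
#' warning; perfectly separating genes are handled by a small ridge on the
#' information matrix and pass with p near zero.
#'
#' @param cohort A [cohort()] (or an expression tibble, in which case
#'   `outcome` must be given).
#' @param genes Genes to screen (default: all).
#' @param p_threshold Screening threshold on the Wald p-value.
#' @param outcome Optional binary outcome vector overriding
#'   `clinical$recurrence`.
#' @return A tibble with `gene`, `estimate`, `se`, `statistic`, `p_value`,
#'   `screened`.
#' @export
univariate_screen <- function(cohort, genes = NULL, p_threshold = 0.01,
                              outcome = NULL) {
  if (inherits(cohort, "caf_cohort")) {
    expression <- cohort$expression
    outcome <- outcome %||% cohort$clinical$recurrence
  } else {
    expression <- cohort
    if (is.null(outcome)) abort("`outcome` required when not passing a cohort")
  }
  check_binary(outcome, "outcome")
  if (anyNA(outcome)) abort("outcome has missing values")
  X <- expr_to_matrix(expression)
  genes <- genes %||% colnames(X)
  missing <- setdiff(genes, colnames(X))
  if (length(missing)) {
    abort(paste0("genes not in expression: ", paste(missing, collapse = ", ")))
  }
  X <- X[, genes, drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("excluding constant gene(s) from the screen: ",
                paste(genes[sds == 0], collapse = ", ")))
  }
  keep <- sds > 0
  res <- fast_logistic_screen(X[, keep, drop = FALSE], outcome)
  out <- tibble(gene = genes) %>%
    left_join(res, by = "gene") %>%
    mutate(screened = !is.na(.data$p_value) & .data$p_value < p_threshold)
  out
}

#' L1-penalized multivariate signature fit
#'
#' Fits an L1-penalized (lasso) logistic regression of recurrence on the
#' screened genes in the training samples, with the penalty chosen by
#' 10-fold cross-validation (binomial deviance) on the training set only,
#' and returns the genes with nonzero coefficients at the
#' deviance-minimizing penalty. An empty selection (full shrinkage) is a
#' valid outcome.
#'
#' @param cohort Training [cohort()] (or expression tibble + `outcome`).
#' @param genes Screened gene ids (at least 2).
#' @param outcome Optional binary outcome vector.
#' @param nfolds Cross-validation folds (default 10).
#' @return Character vector of selected gene ids (possibly empty).
#' @export
fit_l1_signature <- function(cohort, genes, outcome = NULL, nfolds = 10) {
  if (inherits(cohort, "caf_cohort")) {
    expression <- cohort$expression
    outcome <- outcome %||% cohort$clinical$recurrence
  } else {
    expression <- cohort
    if (is.null(outcome)) abort("`outcome` required when not passing a cohort")
  }
  if (length(genes) < 2) abort("need at least 2 screened genes for the penalized fit")
  if (length(unique(outcome)) < 2) abort("both outcome classes must be present")
  X <- expr_to_matrix(expression)[, genes, drop = FALSE]
  n <- nrow(X)
  foldid <- sample(rep_len(seq_len(nfolds), n))
  cv <- glmnet::cv.glmnet(X, outcome, family = "binomial", alpha = 1,
                          standardize = TRUE, foldid = foldid,
                          type.measure = "deviance")
  co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  names(co)[co != 0]
}

#' Stability selection of a consensus gene signature
#'
#' Runs the full discovery loop (stage-proportional resampling ->
#' univariate screen on the training split -> cross-validated lasso on the
#' training split -> record the selected gene set and the test-set AUC of
#' the iteration's fitted model) for `params$n_iterations` iterations, and
#' returns per-gene selection frequencies together with the consensus
#' classifier: genes present in strictly more than
#' `params$frequency_threshold` of completed iterations. Per-iteration
#' regression coefficients are used only transiently; the consensus
#' classifier assigns every gene the same weight, signed +1/-1.
#'
#' Directions are taken from the sign of the mean CAF-vs-NCF difference
#' when `paired_profiles` are supplied (the definition of risk versus
#' protective genes); otherwise the sign of the univariate logistic
#' coefficient on the full cohort is used, with a warning. The test split
#' never takes part in gene selection; its AUC is recorded for reporting
#' only.
#'
#' @param cohort A [cohort()]; the short-follow-up exclusion
#'   (`params$min_followup_years`) is applied first (a no-op if already
#'   applied).
#' @param params A [stability_params()] object.
#' @param genes Candidate genes (default: all genes in the cohort).
#' @param paired_profiles Optional `paired_profiles` tibble for direction
#'   assignment.
#' @return An object of class `stability_result` with elements
#'   `stability` (tibble: gene, count, frequency), `consensus` (a
#'   [classifier()], cutoff = training-cohort tertile of the consensus
#'   score, or NULL if the consensus is empty), `records` (per-iteration
#'   tibble), `n_completed`, and `params`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_params(seed = 1))
#' res <- stability_select(sim$cohort, stability_params(n_iterations = 50, seed = 1))
#' head(tidy(res))
#' }
#' @export
stability_select <- function(cohort, params = stability_params(),
                             genes = NULL, paired_profiles = NULL) {
  stopifnot(inherits(cohort, "caf_cohort"), inherits(params, "stability_params"))
  cohort <- exclude_short_followup(cohort, params$min_followup_years)
  genes <- genes %||% expr_genes(cohort$expression)
  X <- expr_to_matrix(cohort$expression)[, genes, drop = FALSE]
  y <- cohort$clinical$recurrence
  if (anyNA(y)) abort("recurrence has missing values")
  clin <- cohort$clinical

  set.seed(params$seed)
  full_screen <- if (params$screen_on == "full") {
    fast_logistic_screen(X, y)
  }

  counts <- setNames(integer(length(genes)), genes)
  records <- vector("list", params$n_iterations)
  n_completed <- 0L
  failures <- character(0)

  for (i in seq_len(params$n_iterations)) {
    rec <- tryCatch({
      split <- stratified_resample(clin, params$train_fraction, params$stratify_by)
      tr <- match(split$train, rownames(X))
      te <- match(split$test, rownames(X))
      scr <- if (params$screen_on == "full") full_screen
             else fast_logistic_screen(X[tr, , drop = FALSE], y[tr])
      screened <- scr$gene[!is.na(scr$p_value) & scr$p_value < params$univariate_p]
      selected <- character(0)
      test_auc <- NA_real_
      if (length(screened) >= 2 && length(unique(y[tr])) == 2) {
        foldid <- sample(rep_len(seq_len(10), length(tr)))
        cv <- glmnet::cv.glmnet(X[tr, screened, drop = FALSE], y[tr],
                                family = "binomial", alpha = 1,
                                standardize = TRUE, foldid = foldid,
                                type.measure = "deviance")
        co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
        selected <- screened[co != 0]
        lp <- as.vector(predict(cv, X[te, screened, drop = FALSE], s = "lambda.min"))
        if (length(unique(y[te])) == 2 && sd(lp) > 0) {
          r <- rank(lp)
          n1 <- sum(y[te] == 1)
          n0 <- sum(y[te] == 0)
          test_auc <- (sum(r[y[te] == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
        }
      }
      list(iteration = i, n_train = length(tr), n_test = length(te),
           n_screened = length(screened), n_selected = length(selected),
           test_auc = test_auc, screened = list(screened),
           selected = list(selected))
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      failures <- c(failures, paste0("iteration ", i, ": ", conditionMessage(rec)))
      next
    }
    n_completed <- n_completed + 1L
    sel <- rec$selected[[1]]
    counts[sel] <- counts[sel] + 1L
    records[[i]] <- rec
  }

  if (n_completed == 0L) {
    abort(paste0("no iteration completed; failure log:\n",
                 paste(failures, collapse = "\n")))
  }

  stability <- tibble(gene = genes, count = as.integer(counts),
                      frequency = as.numeric(counts) / n_completed) %>%
    arrange(desc(.data$frequency), .data$gene)

  thr <- params$frequency_threshold
  keep <- if (thr >= 1) stability$frequency >= 1 else stability$frequency > thr
  consensus_genes <- stability$gene[keep]
  consensus <- NULL
  if (length(consensus_genes)) {
    dirs <- signature_directions(consensus_genes, cohort, paired_profiles)
    cls <- classifier(consensus_genes, dirs, cutoff = 0)
    score <- compute_score(zscore_genes(cohort$expression), cls)
    cls$cutoff <- derive_cutoff(score$score)
    consensus <- cls
  }

  structure(
    list(stability = stability, consensus = consensus,
         records = bind_rows(lapply(records[!vapply(records, is.null, logical(1))],
                                    as_tibble)),
         n_completed = n_completed, failures = failures, params = params),
    class = "stability_result"
  )
}

signature_directions <- function(genes, cohort, paired_profiles = NULL) {
  if (!is.null(paired_profiles)) {
    d <- as_tibble(paired_profiles) %>%
      filter(.data$gene %in% genes) %>%
      group_by(.data$gene) %>%
      summarise(delta = mean(.data$caf - .data$ncf), .groups = "drop")
    if (all(genes %in% d$gene)) {
      return(sign(d$delta[match(genes, d$gene)]))
    }
    warn("some consensus genes missing from paired profiles; falling back to outcome association for all")
  } else {
    warn("no paired profiles supplied; assigning directions from the univariate outcome association")
  }
  scr <- univariate_screen(cohort, genes = genes)
  sign(scr$estimate[match(genes, scr$gene)])
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> ", x$n_completed, " completed iterations\n", sep = "")
  if (!is.null(x$consensus)) {
    cat("consensus (frequency > ", x$params$frequency_threshold, "):\n", sep = "")
    print(x$consensus)
  } else {
    cat("consensus: empty\n")
  }
  invisible(x)
}

#' @describeIn stability_select Per-gene selection counts and frequencies.
#' @param x A `stability_result`.
#' @param ... Unused.
#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, ...) x$stability

#' @describeIn stability_select One-row summary (iterations completed,
#'   consensus size, median test AUC).
#' @method glance stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble(
    n_iterations = x$params$n_iterations,
    n_completed = x$n_completed,
    n_consensus = if (is.null(x$consensus)) 0L else nrow(x$consensus$genes),
    median_test_auc = median(x$records$test_auc, na.rm = TRUE)
  )
}
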