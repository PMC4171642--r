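#' ROC AUC with DeLong confidence interval
#'
#' The area under the ROC curve equals the probability that a randomly
#' chosen positive sample outscores a randomly chosen negative one, with
#' ties counting one half. The 95% confidence interval is DeLong's.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param outcome Binary outcome (0/1).
#' @return A tibble: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, outcome) {
  check_binary(outcome, "outcome")
  ok <- !is.na(scores) & !is.na(outcome)
  scores <- scores[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2) abort("both outcome classes must be present")
  r <- pROC::roc(response = outcome, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  tibble(auc = as.numeric(pROC::auc(r)), ci_low = ci[1], ci_high = ci[3],
         n_pos = sum(outcome == 1), n_neg = sum(outcome == 0))
}

#' Kaplan-Meier curves with log-rank test and hazard ratio
#'
#' Product-limit survival estimates per group, a two-sided unstratified
#' log-rank test, and a Cox proportional-hazards fit of the group factor
#' (Efron tie handling; hazard ratios are relative to the first group
#' level).
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (0/1).
#' @param group Group labels (factor or character; at least 2 non-empty
#'   groups).
#' @return An object of class `km_fit`: list with `survfit`, `logrank_chisq`,
#'   `logrank_df`, `logrank_p`, `hr` (tibble per non-reference level),
#'   `n_per_group`, and the assembled `data`.
#' @examples
#' f <- km_logrank(c(5, 10, 15, 20, 25, 30), c(1, 1, 0, 1, 0, 0),
#'                 rep(c("a", "b"), 3))
#' f$logrank_p
#' @export
km_logrank <- function(time, event, group) {
  check_binary(event, "event")
  if (any(time < 0, na.rm = TRUE)) abort("negative follow-up time")
  d <- tibble(time = time, event = event, group = factor(group))
  d <- d[complete.cases(d), ]
  d$group <- droplevels(d$group)
  if (nlevels(d$group) < 2) abort("need at least 2 non-empty groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)

  logrank_chisq <- logrank_p <- NA_real_
  logrank_df <- nlevels(d$group) - 1L
  if (sum(d$event) == 0) {
    warn("no events in any group; the log-rank test is degenerate")
  } else if (any(tapply(d$event, d$group, sum) == 0)) {
    warn("a group has no events; the log-rank test may be degenerate")
  }
  if (sum(d$event) > 0) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    logrank_chisq <- unname(sd_$chisq)
    logrank_p <- stats::pchisq(sd_$chisq, df = logrank_df, lower.tail = FALSE)
  }

  hr <- tibble(contrast = character(0), hr = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0))
  if (sum(d$event) > 0) {
    cx <- tryCatch(
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ group,
                                       data = d, ties = "efron")),
      error = function(e) NULL)
    if (!is.null(cx)) {
      s <- summary(cx)
      hr <- tibble(
        contrast = paste(levels(d$group)[-1], "vs", levels(d$group)[1]),
        hr = unname(s$conf.int[, "exp(coef)"]),
        ci_low = unname(s$conf.int[, "lower .95"]),
        ci_high = unname(s$conf.int[, "upper .95"]),
        p = unname(s$coefficients[, "Pr(>|z|)"])
      )
    }
  }

  structure(list(survfit = fit, logrank_chisq = logrank_chisq,
                 logrank_df = logrank_df, logrank_p = logrank_p, hr = hr,
                 n_per_group = table(d$group), data = d),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> groups: ",
      paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = ", "),
      "\n  log-rank chi-square ", format(x$logrank_chisq, digits = 4),
      " (df ", x$logrank_df, "), p = ", format(x$logrank_p, digits = 3),
      "\n", sep = "")
  if (nrow(x$hr)) {
    cat("  HR ", x$hr$contrast[1], ": ", format(x$hr$hr[1], digits = 3),
        " (", format(x$hr$ci_low[1], digits = 3), "-",
        format(x$hr$ci_high[1], digits = 3), ")\n", sep = "")
  }
  invisible(x)
}

#' @describeIn km_logrank Step-function curves as a tibble (time, n_risk,
#'   n_event, survival, group).
#' @param x A `km_fit`.
#' @param ... Unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  s <- summary(x$survfit, censored = TRUE)
  strata <- if (is.null(s$strata)) factor(rep(names(x$n_per_group)[1], length(s$time)))
            else factor(sub("^group=", "", as.character(s$strata)))
  tibble(group = strata, time = s$time, n_risk = s$n.risk,
         n_event = s$n.event, survival = s$surv)
}

#' @describeIn km_logrank One-row summary.
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble(n = sum(x$n_per_group), n_events = sum(x$data$event),
         logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
         hr = if (nrow(x$hr)) x$hr$hr[1] else NA_real_)
}

#' Survival rate at a landmark time
#'
#' Kaplan-Meier estimate at `months` (default 60 = five years), carrying
#' the last value forward when no event or censoring falls exactly there.
#' If a group's follow-up ends before the landmark, its last estimate is
#' returned with a warning.
#'
#' @param fit A [km_logrank()] result.
#' @param months Landmark time in months (default 60).
#' @return Tibble with `group` and `rate`.
#' @export
five_year_rate <- function(fit, months = 60) {
  stopifnot(inherits(fit, "km_fit"))
  groups <- names(fit$n_per_group)
  maxt <- tapply(fit$data$time, fit$data$group, max)
  short <- maxt < months
  if (any(short)) {
    warn(paste0("follow-up ends before ", months, " months in group(s): ",
                paste(names(maxt)[short], collapse = ", "),
                "; returning the last available estimate"))
  }
  s <- summary(fit$survfit, times = pmin(months, maxt), extend = TRUE)
  strata <- if (is.null(s$strata)) rep(groups[1], length(s$time))
            else sub("^group=", "", as.character(s$strata))
  tibble(group = groups, rate = s$surv[match(groups, strata)])
}

#' Cox proportional-hazards evaluation of a risk profile
#'
#' Fits a Cox model (Efron ties) of disease-free or disease-specific
#' survival on the risk score, either dichotomized at the classifier
#' cutoff (`"dichotomized"`, high vs low) or continuous rescaled by its
#' cohort SD (`"continuous_per_sd"`, hazard ratio per +1 SD of score).
#' Additional clinical covariates enter the model unchanged (factors are
#' coded against their first level).
#'
#' Monotone-likelihood / perfect-separation warnings from the fit are
#' caught; the affected fit is re-run with a small ridge penalty on the
#' score term and flagged.
#'
#' @param cohort A [cohort()].
#' @param profile A `risk_profile` from [score_cohort()].
#' @param outcome `"dfs"` or `"dss"`.
#' @param covariates Character vector of clinical columns to adjust for.
#' @param score_form `"dichotomized"` or `"continuous_per_sd"`.
#' @return Tibble with one row per model term: `term`, `estimate`
#'   (log hazard), `hr`, `ci_low`, `ci_high`, `p`, `flagged`.
#' @export
cox_fit <- function(cohort, profile, outcome = c("dfs", "dss"),
                    covariates = character(),
                    score_form = c("dichotomized", "continuous_per_sd")) {
  stopifnot(inherits(cohort, "caf_cohort"))
  outcome <- match.arg(outcome)
  score_form <- match.arg(score_form)
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  cc <- cohort$clinical
  if (!all(c(tcol, ecol) %in% names(cc))) {
    abort(paste0("cohort clinical lacks ", tcol, "/", ecol))
  }
  missing_cov <- setdiff(covariates, names(cc))
  if (length(missing_cov)) {
    abort(paste0("covariate(s) not in clinical table: ",
                 paste(missing_cov, collapse = ", ")))
  }
  d <- left_join(cc, profile, by = "sample_id")
  d$.time <- d[[tcol]]; d$.event <- d[[ecol]]
  if (any(d$.time <= 0, na.rm = TRUE)) abort("non-positive survival times")
  if (sum(d$.event, na.rm = TRUE) == 0) abort("no events; Cox model undefined")
  d$.score <- if (score_form == "dichotomized") d$risk_class
              else d$score / sd(d$score, na.rm = TRUE)
  rhs <- paste(c(".score", covariates), collapse = " + ")
  fml <- as.formula(paste0("survival::Surv(.time, .event) ~ ", rhs))

  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (flagged) {
    # monotone likelihood: stabilize the score term with a light ridge
    fml2 <- as.formula(paste0("survival::Surv(.time, .event) ~ ",
                              paste(c("survival::ridge(.score, theta = 1)",
                                      covariates), collapse = " + ")))
    fit <- suppressWarnings(survival::coxph(fml2, data = d, ties = "efron"))
    warn("monotone likelihood detected; score term refit with a ridge penalty")
  }
  s <- summary(fit)
  est <- s$coefficients[, "coef"]
  se <- s$coefficients[, if ("se(coef)" %in% colnames(s$coefficients)) "se(coef)" else "se2"]
  pcol <- grep("^Pr|^p$", colnames(s$coefficients), value = TRUE)[1]
  tibble(
    term = sub("^\\.score", paste0("score_", score_form), rownames(s$coefficients)),
    estimate = unname(est),
    hr = exp(unname(est)),
    ci_low = exp(unname(est) - 1.96 * unname(se)),
    ci_high = exp(unname(est) + 1.96 * unname(se)),
    p = unname(s$coefficients[, pcol]),
    flagged = flagged
  )
}

#' Risk-class survival within collagen strata
#'
#' Splits the cohort at the median (or tertiles) of the collagen score and
#' runs [km_logrank()] of the risk class within each stratum. In a world
#' where the classifier reads CAF state from stromal mRNA, risk
#' stratification should be strong in high-collagen (stroma-rich) samples
#' and weak in low-collagen ones.
#'
#' @param cohort A [cohort()].
#' @param profile A `risk_profile` with `collagen_score` and `risk_class`.
#' @param split `"median"` or `"tertile"`.
#' @param outcome `"dfs"` or `"dss"`.
#' @return Named list of [km_logrank()] fits (one per stratum) with a
#'   `summary` attribute tibble.
#' @export
stratified_by_collagen <- function(cohort, profile, split = c("median", "tertile"),
                                   outcome = c("dfs", "dss")) {
  stopifnot(inherits(cohort, "caf_cohort"))
  split <- match.arg(split)
  outcome <- match.arg(outcome)
  if (!"collagen_score" %in% names(profile)) abort("profile lacks collagen_score")
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  d <- left_join(cohort$clinical, profile, by = "sample_id")
  br <- if (split == "median") {
    stats::quantile(d$collagen_score, 0.5)
  } else {
    stats::quantile(d$collagen_score, c(1 / 3, 2 / 3))
  }
  labs <- if (split == "median") c("low_collagen", "high_collagen")
          else c("low_collagen", "mid_collagen", "high_collagen")
  stratum <- cut(d$collagen_score, breaks = c(-Inf, br, Inf), labels = labs)
  if (any(table(stratum) == 0)) abort("empty collagen stratum")
  fits <- lapply(split(seq_len(nrow(d)), stratum), function(idx) {
    km_logrank(d[[tcol]][idx], d[[ecol]][idx], d$risk_class[idx])
  })
  summ <- bind_rows(lapply(names(fits), function(nm) {
    g <- glance(fits[[nm]]); g$stratum <- nm; g
  }))
  attr(fits, "summary") <- summ
  fits
}

#' Interaction between the risk score and the collagen score
#'
#' Cox model with main effects for the continuous risk score and collagen
#' score plus their product; returns the product term. A positive
#' interaction means the score's hazard effect grows with stromal content.
#'
#' @inheritParams stratified_by_collagen
#' @return One-row tibble: `estimate` (product-term log hazard), `hr`,
#'   `ci_low`, `ci_high`, `p`, `collinear` flag.
#' @export
collagen_interaction <- function(cohort, profile, outcome = c("dfs", "dss")) {
  stopifnot(inherits(cohort, "caf_cohort"))
  outcome <- match.arg(outcome)
  if (!"collagen_score" %in% names(profile)) abort("profile lacks collagen_score")
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  d <- left_join(cohort$clinical, profile, by = "sample_id")
  collinear <- abs(cor(d$score, d$collagen_score)) > 0.99
  if (collinear) warn("score and collagen score are nearly collinear")
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(d[[tcol]], d[[ecol]]) ~ score * collagen_score,
    data = d, ties = "efron"))
  s <- summary(fit)$coefficients
  row <- grep(":", rownames(s))
  tibble(estimate = s[row, "coef"], hr = exp(s[row, "coef"]),
         ci_low = exp(s[row, "coef"] - 1.96 * s[row, "se(coef)"]),
         ci_high = exp(s[row, "coef"] + 1.96 * s[row, "se(coef)"]),
         p = s[row, "Pr(>|z|)"], collinear = collinear)
}
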