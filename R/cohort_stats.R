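#' Cross-tabulate glycolytic group against a clinical variable
#'
#' Builds the group x variable count matrix used by [association_test()].
#' Samples missing either value are excluded; the number excluded is attached
#' as attribute `"n_excluded"`. Levels keep their declared order.
#'
#' @param cohort A cohort `data.frame` with a `group` column.
#' @param variable Name of the categorical column to cross-tabulate.
#'
#' @return Integer count matrix (groups x levels).
#' @export
contingency <- function(cohort, variable) {
  if (!variable %in% names(cohort)) {
    stop("variable not found in cohort: ", variable, call. = FALSE)
  }
  g <- cohort$group
  v <- cohort[[variable]]
  keep <- !is.na(g) & !is.na(v)
  tab <- table(group = factor(g[keep]), variable = factor(v[keep]))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop(sprintf("degenerate table for '%s': a factor has fewer than 2 observed levels",
                 variable), call. = FALSE)
  }
  out <- unclass(tab)
  names(dimnames(out)) <- c("group", variable)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Association test for a contingency table
#'
#' Computes both the chi-square test (with continuity correction for 2x2
#' tables only) and, where feasible, Fisher's exact test, then chooses the
#' primary p-value by the usual small-expected-count rule: Fisher when any
#' expected count is below 5, or for a 2x2 table with total n below 40;
#' chi-square otherwise. Fisher is always computed for 2x2 tables, and for
#' larger tables when any expected count is below 5 and total n is at most
#' 500 (the exact network algorithm is infeasible beyond that). The primary
#' p is reported rounded to four decimal places with the exact value kept in
#' `p_exact`; `significant` is `p_primary < 0.05`.
#'
#' @param tab Non-negative integer count matrix, at least 2x2.
#' @param variable Optional variable name carried into the result.
#'
#' @return An object of class `"association_result"`: `variable`, `table`,
#'   `p_fisher`, `p_chisq`, `p_primary` (4 decimals), `p_exact`, `method`,
#'   `significant`.
#' @export
#' @examples
#' association_test(matrix(c(8, 1, 2, 9), 2, 2))
association_test <- function(tab, variable = NA_character_) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)) || anyNA(tab)) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  small_expected <- any(expected < 5)
  is2x2 <- nrow(tab) == 2 && ncol(tab) == 2

  p_chisq <- suppressWarnings(
    stats::chisq.test(tab, correct = is2x2)$p.value)
  p_fisher <- NA_real_
  if (is2x2 || (small_expected && n <= 500)) {
    p_fisher <- tryCatch(stats::fisher.test(tab)$p.value,
                         error = function(e) NA_real_)
  }
  use_fisher <- (small_expected || (is2x2 && n < 40)) && !is.na(p_fisher)
  p_exact <- if (use_fisher) p_fisher else p_chisq
  structure(list(variable = variable,
                 table = tab,
                 p_fisher = p_fisher,
                 p_chisq = p_chisq,
                 p_primary = round(p_exact, 4),
                 p_exact = p_exact,
                 method = if (use_fisher) "fisher" else "chisq",
                 significant = round(p_exact, 4) < 0.05),
            class = "association_result")
}

#' @exportS3Method base::print
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s: p = %.4f (%s)%s\n",
              ifelse(is.na(x$variable), "(unnamed)", x$variable),
              x$p_primary, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Test all clinical variables against the glycolytic group and rank them
#'
#' Runs [contingency()] + [association_test()] for each named variable,
#' ranks results by significance, and flags those with primary p < 0.05.
#' Variables whose table is degenerate (a factor collapsing to one level)
#' are skipped with a warning.
#'
#' @param cohort A cohort `data.frame` with a `group` column.
#' @param variables Character vector of categorical column names (default:
#'   KRAS status, stage, purity bin, subtype).
#'
#' @return A `data.frame` with one row per tested variable: `variable`,
#'   `p_primary`, `method`, `significant`, `rank`; the full
#'   `association_result` objects are attached as attribute `"results"`.
#' @export
rank_associations <- function(cohort,
                              variables = c("kras", "stage", "purity_bin",
                                            "subtype")) {
  results <- list()
  for (v in variables) {
    res <- tryCatch(association_test(contingency(cohort, v), variable = v),
                    error = function(e) {
                      warning(sprintf("skipping '%s': %s", v, conditionMessage(e)),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) results[[v]] <- res
  }
  if (length(results) == 0) stop("no testable variables", call. = FALSE)
  df <- data.frame(
    variable = vapply(results, `[[`, "", "variable"),
    p_primary = vapply(results, `[[`, 0, "p_primary"),
    method = vapply(results, `[[`, "", "method"),
    significant = vapply(results, `[[`, TRUE, "significant"),
    stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(df$p_primary), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "results") <- results
  df
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; order-preserving with the input,
#' each adjusted value in \[0, 1\] and monotone in rank.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Kaplan-Meier fit and tests at a fixed horizon
#'
#' Implements the 3-year overall-survival endpoint: all follow-up beyond
#' `horizon` months is administratively censored at the horizon, then
#' per-group product-limit curves are fitted, group differences are tested
#' with the (unweighted) log-rank test, and — when three or more ordered
#' groups are present — a trend is tested with a proportional-hazards score
#' test on the integer-coded group (Low < Intermediate < High).
#'
#' With zero events overall the curves are returned flat at 1 and both tests
#' are absent (`NA`).
#'
#' @param cohort A cohort `data.frame` with columns `group`, `time` (months),
#'   `event` (0/1).
#' @param horizon Censoring horizon in months (default 36).
#'
#' @return An object of class `"survival_fit"`: `curves` (tidy data.frame:
#'   group, time, n_risk, n_event, estimate), `logrank_p`, `logrank_chisq`,
#'   `trend_p`, `horizon`, `n_events`, and the underlying `survfit` object.
#' @export
km_fit <- function(cohort, horizon = 36) {
  if (!all(c("group", "time", "event") %in% names(cohort))) {
    stop("cohort must have group, time and event columns", call. = FALSE)
  }
  if (any(cohort$time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(cohort$event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  g <- droplevels(factor(cohort$group))
  if (nlevels(g) < 2) stop("at least 2 groups are required", call. = FALSE)
  event <- ifelse(cohort$time > horizon, 0L, as.integer(cohort$event))
  time <- pmin(cohort$time, horizon)
  dat <- data.frame(time = time, event = event, group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata_names <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(group = strata_names, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       estimate = fit$surv, stringsAsFactors = FALSE)
  n_events <- sum(event)
  logrank_p <- logrank_chisq <- trend_p <- NA_real_
  if (n_events > 0) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    logrank_chisq <- sd$chisq
    logrank_p <- stats::pchisq(sd$chisq, df = nlevels(g) - 1,
                               lower.tail = FALSE)
    ordered_levels <- c("Low", "Intermediate", "High")
    if (nlevels(g) >= 3 && all(levels(g) %in% ordered_levels)) {
      code <- match(as.character(g), ordered_levels) - 1
      cx <- survival::coxph(survival::Surv(time, event) ~ code, data = dat)
      trend_p <- summary(cx)$sctest["pvalue"][[1]]
    }
  }
  structure(list(curves = curves, logrank_p = logrank_p,
                 logrank_chisq = logrank_chisq, trend_p = trend_p,
                 horizon = horizon, n_events = n_events, survfit = fit),
            class = "survival_fit")
}

#' @exportS3Method base::print
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> horizon %g months, %d events\n",
              x$horizon, x$n_events))
  cat(sprintf("  log-rank p = %.4g; trend p = %.4g\n",
              x$logrank_p, x$trend_p))
  invisible(x)
}
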