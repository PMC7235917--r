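# Cohort-level statistics: median [min, max] descriptives by fusion status,
# explorative univariate logistic regressions (OR, Wald 95% CI, p), and
# Spearman correlation of graft uptake with the one-year change in each
# clinical score. Missing data are handled per test (available-case); no
# multiple-testing correction is applied, matching the explorative framing —
# the report carries the number of tests run instead.

#' One-year change score
#'
#' 12-month score minus baseline score for one variable; `NA` when either
#' timepoint is missing (such records are dropped from the affected test
#' only).
#'
#' @param cohort Patient data frame (see [generate_cohort()]).
#' @param variable Variable stem, e.g. `"vas_b"` for columns `vas_b_bs` and
#'   `vas_b_12m`.
#' @return Numeric vector of changes, `NA` where a timepoint is missing.
#' @export
score_change <- function(cohort, variable) {
  bs <- cohort[[paste0(variable, "_bs")]]
  m12 <- cohort[[paste0(variable, "_12m")]]
  if (is.null(bs) || is.null(m12))
    stop_gq("variable '%s' lacks _bs/_12m columns", variable,
            class = "gq_argument_error")
  m12 - bs
}

#' Univariate logistic regression of fusion on one predictor
#'
#' Maximum-likelihood logistic fit of the binary fused outcome on a single
#' predictor; reports the odds ratio per unit of the predictor with a Wald
#' 95% confidence interval and p-value. Quasi-complete separation is
#' detected (fitted probabilities collapsing to 0/1 or an exploding standard
#' error) and flagged instead of reporting a spurious finite OR.
#'
#' @param cohort Patient data frame with logical/0-1 column `fused`.
#' @param predictor Column name of the predictor.
#' @param outcome Outcome column name (default `"fused"`).
#' @return A list: `or`, `ci_lo`, `ci_hi`, `p`, `n`, `separation` (logical),
#'   `predictor`.
#' @export
univariate_logit <- function(cohort, predictor, outcome = "fused") {
  x <- cohort[[predictor]]
  y <- cohort[[outcome]]
  if (is.null(x)) stop_gq("no column '%s'", predictor, class = "gq_argument_error")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- as.integer(y[keep])
  if (length(unique(y)) < 2L)
    stop_gq("outcome has a single class; logistic fit impossible",
            class = "gq_single_class_error")
  if (min(table(y)) < 2L)
    stop_gq("need >= 2 records per outcome class", class = "gq_single_class_error")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  sm <- suppressWarnings(summary(fit))
  beta <- coef(fit)[["x"]]
  se <- sm$coefficients["x", "Std. Error"]
  pval <- sm$coefficients["x", "Pr(>|z|)"]
  eps <- 1e-8
  separation <- any(fit$fitted.values > 1 - eps) &&
    any(fit$fitted.values < eps) || se > 100 || !fit$converged
  z <- qnorm(0.975)
  list(or = if (separation) NA_real_ else exp(beta),
       ci_lo = if (separation) NA_real_ else exp(beta - z * se),
       ci_hi = if (separation) NA_real_ else exp(beta + z * se),
       p = if (separation) NA_real_ else pval,
       n = length(y), separation = separation, predictor = predictor)
}

#' Spearman correlation of uptake with one-year clinical change
#'
#' Nonparametric Spearman rank correlation (average ranks for ties) between
#' a graft uptake metric and the 12-month-minus-baseline change of one
#' clinical variable, with a two-sided p-value. Records missing either
#' quantity are dropped pairwise.
#'
#' @param cohort Patient data frame.
#' @param uptake_metric Column name, e.g. `"suv_total"` or `"c_suv_total"`.
#' @param change_variable Variable stem passed to [score_change()].
#' @return A list: `rho`, `p`, `n`, `uptake_metric`, `change_variable`.
#' @export
spearman_uptake_vs_change <- function(cohort, uptake_metric = "suv_total",
                                      change_variable) {
  u <- cohort[[uptake_metric]]
  if (is.null(u)) stop_gq("no column '%s'", uptake_metric,
                          class = "gq_argument_error")
  d <- score_change(cohort, change_variable)
  keep <- !is.na(u) & !is.na(d)
  u <- u[keep]; d <- d[keep]
  if (length(u) < 3L)
    stop_gq("need >= 3 complete pairs (got %d)", length(u),
            class = "gq_argument_error")
  if (length(unique(u)) < 2L || length(unique(d)) < 2L)
    stop_gq("constant variable: Spearman rho undefined",
            class = "gq_constant_error")
  ct <- suppressWarnings(cor.test(u, d, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(u),
       uptake_metric = uptake_metric, change_variable = change_variable)
}

# median [min, max] of the non-missing values of x, NA-safe
med_range <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(c(median = NA_real_, min = NA_real_,
                                max = NA_real_, n = 0))
  c(median = median(x), min = min(x), max = max(x), n = length(x))
}

#' Cohort descriptives and group comparisons in report-table shape
#'
#' For every variable and timepoint (baseline, 1-month uptake, one-year
#' change), median [min, max] within the fused and unfused groups plus the
#' univariate logistic OR with Wald 95% CI and p-value. Continuous
#' predictors enter the logistic fit on their native per-unit scale, which
#' is printed alongside each OR.
#'
#' @param cohort Patient data frame (columns as in [generate_cohort()]).
#' @return An object of class `cohort_report`: a data frame with one row per
#'   variable x timepoint and attributes `n_fused`, `n_unfused`,
#'   `n_tests_run`.
#' @export
describe_cohort <- function(cohort) {
  if (nrow(cohort) == 0L)
    stop_gq("empty cohort", class = "gq_argument_error")
  score_vars <- c("wlk_d", "vas_b", "vas_l", "tan", "odi", "eq5d")
  rows <- list()
  add_row <- function(timepoint, variable, values) {
    f <- med_range(values[cohort$fused])
    u <- med_range(values[!cohort$fused])
    lg <- tryCatch({
      tmp <- cohort["fused"]
      tmp$x <- values
      univariate_logit(tmp, "x")
    }, graftquant_error = function(e) list(or = NA_real_, ci_lo = NA_real_,
                                           ci_hi = NA_real_, p = NA_real_,
                                           n = sum(!is.na(values)),
                                           separation = NA))
    rows[[length(rows) + 1L]] <<- data.frame(
      timepoint = timepoint, variable = variable,
      fused_median = f[["median"]], fused_min = f[["min"]],
      fused_max = f[["max"]],
      unfused_median = u[["median"]], unfused_min = u[["min"]],
      unfused_max = u[["max"]],
      or = lg$or, ci_lo = lg$ci_lo, ci_hi = lg$ci_hi, p = lg$p,
      n = lg$n, separation = isTRUE(lg$separation))
  }
  for (v in intersect(c("age", "bmi"), names(cohort)))
    add_row("baseline", v, cohort[[v]])
  for (v in score_vars)
    if (!is.null(cohort[[paste0(v, "_bs")]]))
      add_row("baseline", v, cohort[[paste0(v, "_bs")]])
  for (v in intersect(c("suv_total", "c_suv_total"), names(cohort)))
    add_row("1 month", v, cohort[[v]])
  for (v in score_vars)
    if (!is.null(cohort[[paste0(v, "_bs")]]))
      add_row("1 year - baseline", v, score_change(cohort, v))
  out <- do.call(rbind, rows)
  attr(out, "n_fused") <- sum(cohort$fused)
  attr(out, "n_unfused") <- sum(!cohort$fused)
  attr(out, "n_tests_run") <- sum(!is.na(out$or) | out$separation)
  class(out) <- c("cohort_report", "data.frame")
  out
}

#' Format a cohort report as a readable text table
#'
#' @param report A [describe_cohort()] result.
#' @return Character vector of lines (invisibly printed by
#'   `print.cohort_report`).
#' @export
format_cohort_report <- function(report) {
  fmt_mr <- function(m, lo, hi)
    ifelse(is.na(m), "-", sprintf("%.3g [%.3g, %.3g]", m, lo, hi))
  fmt_or <- function(or, lo, hi, sep)
    ifelse(sep, "separation",
           ifelse(is.na(or), "-", sprintf("%.3g [%.3g, %.3g]", or, lo, hi)))
  lines <- sprintf(
    "%-18s %-12s %-24s %-24s %-26s %s",
    report$timepoint, report$variable,
    fmt_mr(report$fused_median, report$fused_min, report$fused_max),
    fmt_mr(report$unfused_median, report$unfused_min, report$unfused_max),
    fmt_or(report$or, report$ci_lo, report$ci_hi, report$separation),
    ifelse(is.na(report$p), "-", sprintf("p=%.2g", report$p)))
  header <- sprintf("%-18s %-12s %-24s %-24s %-26s %s",
                    "timepoint", "variable",
                    sprintf("fused (n=%d) med [min,max]",
                            attr(report, "n_fused")),
                    sprintf("unfused (n=%d) med [min,max]",
                            attr(report, "n_unfused")),
                    "OR [95% CI] (per unit)", "p")
  c(header, strrep("-", nchar(header)), lines,
    sprintf("(%d univariate tests run; no multiplicity correction)",
            attr(report, "n_tests_run")))
}

#' @export
print.cohort_report <- function(x, ...) {
  needed <- c("timepoint", "variable", "fused_median", "or", "p")
  if (!all(needed %in% names(x))) return(NextMethod())
  cat(format_cohort_report(x), sep = "\n")
  invisible(x)
}
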