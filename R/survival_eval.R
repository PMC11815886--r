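# Survival stratification of predicted clusters: Kaplan-Meier curves and
# log-rank tests (Mantel-Cox, chi-square approximation), computed with the
# survival package. Event coding is fixed: event = 1 observed, 0 censored.

#' Kaplan-Meier product-limit curve for one group
#'
#' Censored times do not step the curve; at tied times, deaths are processed
#' before censorings (standard product-limit conventions).
#'
#' @param records survival data.frame (`sample_id`, `time`, `event`,
#'   optional `group`).
#' @param group optional group label to subset on (matched against the
#'   `group` column); NULL uses all records.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, with the group's median survival (possibly NA when the curve
#'   never reaches 0.5) in attribute `"median"`.
#' @export
km_curve <- function(records, group = NULL) {
  validate_survival(records)
  if (!is.null(group)) {
    if (!"group" %in% names(records))
      stop("records have no 'group' column to subset on")
    records <- records[records$group == group, , drop = FALSE]
  }
  if (!nrow(records)) stop("no records in group ", group)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  med <- unname(summary(fit)$table["median"])
  attr(curve, "median") <- med
  curve
}

#' Log-rank test across predicted groups
#'
#' `mode = "all_groups"` tests all k groups (k - 1 degrees of freedom);
#' `mode = "one_vs_rest"` collapses every non-protective group into "rest"
#' and tests the protective group against it. Groups with zero members are
#' dropped with a warning.
#'
#' @param records survival data.frame.
#' @param grouping named character vector, sample_id -> group.
#' @param mode `"all_groups"` or `"one_vs_rest"`.
#' @param protective protective group label (required for one_vs_rest).
#' @return list with `statistic` (chi-square), `df`, `p_value`, `mode`,
#'   `groups` (group sizes used).
#' @export
logrank_test <- function(records, grouping,
                         mode = c("all_groups", "one_vs_rest"),
                         protective = NULL) {
  mode <- match.arg(mode)
  validate_survival(records)
  df <- records[records$sample_id %in% names(grouping), , drop = FALSE]
  if (!nrow(df)) stop("no survival records match the grouping")
  df$grp <- unname(grouping[df$sample_id])
  present <- unique(df$grp)
  absent <- setdiff(unique(grouping), present)
  if (length(absent))
    warning("group(s) with no survival records dropped: ",
            paste(absent, collapse = ", "))
  if (mode == "one_vs_rest") {
    if (is.null(protective)) stop("one_vs_rest needs a protective group")
    if (!protective %in% present)
      stop("protective group '", protective, "' has no members")
    df$grp <- ifelse(df$grp == protective, protective, "rest")
  }
  if (length(unique(df$grp)) < 2)
    stop("log-rank test needs >= 2 groups with members")
  if (sum(df$event) < 1) stop("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  k <- length(sd$n)
  list(statistic = unname(sd$chisq), df = k - 1L,
       p_value = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE),
       mode = mode, groups = table(df$grp))
}

#' Survival summary of predicted clusters
#'
#' Kaplan-Meier curve and median survival per group, plus the all-groups
#' log-rank test and the protective-vs-rest log-rank test.
#'
#' @param records survival data.frame.
#' @param grouping named character vector sample_id -> group (e.g., best
#'   calls from [predict.pair_ensemble()]).
#' @param protective protective group label.
#' @return object of class `survival_summary`: list with `curves` (named list
#'   of [km_curve()] outputs), `medians`, `logrank_all`,
#'   `logrank_protective`.
#' @export
survival_summary <- function(records, grouping, protective) {
  validate_survival(records)
  df <- records[records$sample_id %in% names(grouping), , drop = FALSE]
  df$group <- unname(grouping[df$sample_id])
  groups <- unique(df$group)
  curves <- stats::setNames(
    lapply(groups, function(g) km_curve(df, group = g)), groups)
  medians <- vapply(curves, attr, numeric(1), "median")
  structure(list(
    curves = curves, medians = medians,
    logrank_all = logrank_test(df, stats::setNames(df$group, df$sample_id),
                               mode = "all_groups"),
    logrank_protective = logrank_test(
      df, stats::setNames(df$group, df$sample_id),
      mode = "one_vs_rest", protective = protective)
  ), class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat("<survival_summary>\n  medians:",
      paste(names(x$medians), round(x$medians, 1), sep = "=",
            collapse = " "), "\n")
  cat(sprintf("  log-rank all groups: chisq=%.3f df=%d p=%.4g\n",
              x$logrank_all$statistic, x$logrank_all$df,
              x$logrank_all$p_value))
  cat(sprintf("  log-rank protective vs rest: chisq=%.3f p=%.4g\n",
              x$logrank_protective$statistic, x$logrank_protective$p_value))
  invisible(x)
}
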