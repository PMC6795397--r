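#' Per-sample delta-Ct normalization
#'
#' Computes dCt = Cq(target) - Cq(control) for every sample of a long-format
#' Cq table, normalizing the target assay to an endogenous control (such as
#' U6 snRNA or miR-103) measured in the same sample.
#'
#' @param table data.frame with columns `sample_id`, `group`, `assay`, `cq`
#'   (as produced by [simulate_cq_table()]).
#' @param target target assay label (default `"target"`).
#' @param control endogenous-control assay label (default `"control"`).
#' @return data.frame with columns `sample_id`, `group`, `dct`, one row per
#'   sample in first-appearance order.
#' @export
normalize_dct <- function(table, target = "target", control = "control") {
  need <- c("sample_id", "group", "assay", "cq")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stopf("Cq table needs columns %s", paste(need, collapse = ", "))
  tgt <- table[table$assay == target, ]
  ctl <- table[table$assay == control, ]
  if (nrow(tgt) == 0) stopf("no rows for target assay '%s'", target)
  missing <- setdiff(tgt$sample_id, ctl$sample_id)
  if (length(missing))
    stopf("missing control Cq for sample(s): %s",
          paste(missing, collapse = ", "))
  idx <- match(tgt$sample_id, ctl$sample_id)
  data.frame(sample_id = tgt$sample_id, group = tgt$group,
             dct = tgt$cq - ctl$cq[idx], stringsAsFactors = FALSE)
}

#' Relative fold change by the 2^-ddCt method
#'
#' ddCt = mean(dCt, treated) - mean(dCt, control); the relative expression
#' of the treated group is 2^(-ddCt). Lower Cq means more template, so a
#' treated group with smaller dCt yields a fold change above 1.
#'
#' @param dct_treated,dct_control numeric vectors of per-sample dCt values
#'   (nonempty).
#' @return the fold change, a positive scalar.
#' @export
#' @examples
#' fold_change_ddct(c(7.1, 7.2), c(9.4, 9.5))  # ~4.9-fold up
fold_change_ddct <- function(dct_treated, dct_control) {
  if (length(dct_treated) == 0 || length(dct_control) == 0)
    stopf("both groups must be nonempty")
  if (any(!is.finite(dct_treated)) || any(!is.finite(dct_control)))
    stopf("dCt values must be finite")
  2^(-(mean(dct_treated) - mean(dct_control)))
}

#' Fold change from already-normalized group mean Cq values
#'
#' For group-level summaries where only the per-group mean (already
#' normalized) Cq is available: fold = 2^(mean Cq, control - mean Cq,
#' treated). Equivalent to [fold_change_ddct()] applied to the group means.
#' Satisfies `fold_from_mean_cq(a, b) * fold_from_mean_cq(b, a) == 1`.
#'
#' @param mean_cq_control,mean_cq_treated finite group mean Cq values
#'   (negative values are legitimate on pre-normalized scales).
#' @return the fold change of treated relative to control.
#' @export
#' @examples
#' fold_from_mean_cq(9.46, 7.17)   # ~4.9
#' fold_from_mean_cq(-7.52, -8.2)  # ~1.60, i.e. 60% more
fold_from_mean_cq <- function(mean_cq_control, mean_cq_treated) {
  if (!is_number(mean_cq_control) || !is_number(mean_cq_treated))
    stopf("mean Cq values must be single finite numbers")
  2^(mean_cq_control - mean_cq_treated)
}

#' Percent difference between group means
#'
#' `100 * (alternative - reference) / reference`: the percent by which the
#' alternative group exceeds (positive) or falls below (negative) the
#' reference group.
#'
#' @param mean_reference reference group mean (nonzero).
#' @param mean_alternative alternative group mean.
#' @return signed percent difference.
#' @export
#' @examples
#' percent_difference(1.30, 1.52)  # +16.9%
percent_difference <- function(mean_reference, mean_alternative) {
  if (!is_number(mean_reference) || !is_number(mean_alternative))
    stopf("group means must be single finite numbers")
  if (mean_reference == 0) stopf("reference mean must be nonzero")
  100 * (mean_alternative - mean_reference) / mean_reference
}

#' Group summary: mean, SEM, n
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' sqrt(n); it is reported as `NA` for a single observation.
#'
#' @param values numeric vector (nonempty).
#' @return list with `mean`, `sem`, `n`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0) stopf("empty group")
  if (any(!is.finite(values))) stopf("values must be finite")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Unpaired two-sample t test with group summaries
#'
#' Standard unpaired t test (pooled-variance Student by default, Welch
#' optionally), reporting per-group mean, SEM and n together with the t
#' statistic, degrees of freedom and p value. For `tails = 1` the one-tailed
#' p value for the observed direction of the difference is reported (half
#' the two-tailed p).
#'
#' @param group_a,group_b numeric vectors, each with n >= 2.
#' @param tails 1 or 2.
#' @param variance `"pooled"` (Student) or `"welch"`.
#' @return a `group_comparison` list: `mean_a`, `sem_a`, `n_a`, `mean_b`,
#'   `sem_b`, `n_b`, `difference` (mean_b - mean_a), `percent_difference`
#'   (`NA` when mean_a is 0), `t` (sign of mean_a - mean_b, the usual
#'   two-sample convention), `df`, `p`, `tails`, `variance`.
#' @export
#' @examples
#' unpaired_t_test(c(0.012, 0.014, 0.016), c(0.018, 0.019, 0.020))
unpaired_t_test <- function(group_a, group_b, tails = 2,
                            variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  if (!tails %in% c(1, 2)) stopf("tails must be 1 or 2")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("each group needs at least 2 observations")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stopf("both groups have zero within-group variance; the t statistic is undefined")
  ht <- t.test(group_a, group_b, var.equal = (variance == "pooled"))
  p <- if (tails == 1) ht$p.value / 2 else ht$p.value
  sa <- group_summary(group_a); sb <- group_summary(group_b)
  structure(list(mean_a = sa$mean, sem_a = sa$sem, n_a = sa$n,
                 mean_b = sb$mean, sem_b = sb$sem, n_b = sb$n,
                 difference = sb$mean - sa$mean,
                 percent_difference = if (sa$mean != 0)
                   percent_difference(sa$mean, sb$mean) else NA_real_,
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = p, tails = tails, variance = variance),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group_comparison (%s, %d-tailed)\n  a: %.4g +/- %.3g (n = %d)   b: %.4g +/- %.3g (n = %d)\n  difference %.4g (%s%%), t = %.3f, df = %.3g, p = %.4g\n",
    x$variance, x$tails, x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b,
    x$n_b, x$difference,
    if (is.na(x$percent_difference)) "NA"
    else sprintf("%+.1f", x$percent_difference),
    x$t, x$df, x$p))
  invisible(x)
}
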