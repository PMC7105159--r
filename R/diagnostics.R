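#' Build a 2x2 contingency table from a marker threshold
#'
#' Disease-positive is the `positive_label` diagnosis; test-positive is
#' a marker value above the cutoff, inclusively (`"ge"`, the LDH rule
#' convention: >= 279 U/L) or strictly (`"gt"`, the age rule: > 49
#' years).
#'
#' @param values numeric marker values, one per patient.
#' @param labels diagnosis labels, same length.
#' @param cutoff threshold value.
#' @param positive_direction `"ge"` (inclusive) or `"gt"` (strict).
#' @param positive_label the disease-positive label (default `"LMS"`).
#' @return List of class `contingency_table` with integer `tp, fp, fn,
#'   tn`.
#' @export
contingency_from_threshold <- function(values, labels, cutoff,
                                       positive_direction = c("ge", "gt"),
                                       positive_label = "LMS") {
  positive_direction <- match.arg(positive_direction)
  stopifnot(length(values) == length(labels), all(is.finite(values)) || !length(values))
  test_pos <- if (positive_direction == "ge") values >= cutoff
              else values > cutoff
  disease <- labels == positive_label
  structure(list(tp = sum(test_pos & disease),
                 fp = sum(test_pos & !disease),
                 fn = sum(!test_pos & disease),
                 tn = sum(!test_pos & !disease)),
            class = "contingency_table")
}

#' Make a contingency table from explicit counts
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "contingency_table")
}

# Wilson score interval, no continuity correction
.wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

# standard logit interval
.logit_ci <- function(x, n, conf = 0.95) {
  if (n == 0 || x == 0 || x == n) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  se <- sqrt(1 / (n * p * (1 - p)))
  stats::plogis(stats::qlogis(p) + c(-z, z) * se)
}

#' Diagnostic metrics from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`
#' and NPV `tn/(tn+fn)`, with confidence intervals (Wilson for
#' sensitivity/specificity, standard logit for the predictive values by
#' default). Zero denominators give `NA` estimates flagged in
#' `undefined`, never an error. When `prevalence` is supplied the
#' predictive values are additionally recomputed at that prevalence via
#' Bayes' rule (see [bayes_predictive_values()]).
#'
#' @param table a `contingency_table`.
#' @param ci_method `"wilson_logit"` (default: Wilson for sens/spec,
#'   logit for PPV/NPV) or `"wilson"` for Wilson everywhere.
#' @param conf confidence level (default 0.95).
#' @param prevalence optional prevalence in `[0, 1]` for adjusted
#'   predictive values.
#' @return List of class `diagnostic_report`: `estimates` (named
#'   fractions), `ci` (2-column matrix), `undefined` (named logicals),
#'   `ci_method`, `prevalence_used`, and (with `prevalence`)
#'   `ppv_adjusted`, `npv_adjusted`.
#' @export
test_metrics <- function(table, ci_method = c("wilson_logit", "wilson"),
                         conf = 0.95, prevalence = NULL) {
  stopifnot(inherits(table, "contingency_table"))
  ci_method <- match.arg(ci_method)
  num <- c(sensitivity = table$tp, specificity = table$tn,
           ppv = table$tp, npv = table$tn)
  den <- c(sensitivity = table$tp + table$fn,
           specificity = table$tn + table$fp,
           ppv = table$tp + table$fp,
           npv = table$tn + table$fn)
  est <- ifelse(den > 0, num / den, NA_real_)
  ci <- t(vapply(names(num), function(m) {
    if (den[m] == 0) return(c(NA_real_, NA_real_))
    if (ci_method == "wilson" || m %in% c("sensitivity", "specificity"))
      .wilson_ci(num[m], den[m], conf)
    else .logit_ci(num[m], den[m], conf)
  }, numeric(2)))
  colnames(ci) <- c("low", "high")
  n_total <- table$tp + table$fp + table$fn + table$tn
  out <- list(estimates = est, ci = ci, undefined = den == 0,
              ci_method = ci_method,
              prevalence_used = if (!is.null(prevalence)) prevalence
                                else if (n_total > 0)
                                  (table$tp + table$fn) / n_total
                                else NA_real_)
  if (!is.null(prevalence)) {
    pv <- bayes_predictive_values(est["sensitivity"], est["specificity"],
                                  prevalence)
    out$ppv_adjusted <- pv$ppv
    out$npv_adjusted <- pv$npv
  }
  class(out) <- "diagnostic_report"
  out
}

#' @export
print.diagnostic_report <- function(x, ...) {
  for (m in names(x$estimates)) {
    if (x$undefined[m]) cat(sprintf("  %-12s undefined (zero denominator)\n", m))
    else cat(sprintf("  %-12s %6.2f%%  (95%% CI %.2f%%-%.2f%%)\n", m,
                     100 * x$estimates[m], 100 * x$ci[m, 1], 100 * x$ci[m, 2]))
  }
  invisible(x)
}

#' Prevalence-adjusted predictive values (Bayes' rule)
#'
#' `PPV = se*pi / (se*pi + (1-sp)*(1-pi))` and
#' `NPV = sp*(1-pi) / (sp*(1-pi) + (1-se)*pi)` for prevalence `pi`.
#' At a leiomyosarcoma prevalence of 0.12% even a test with 95%
#' sensitivity and specificity yields a PPV of only ~2% while the NPV
#' is ~99.99%.
#'
#' @param sensitivity,specificity,prevalence fractions in `[0, 1]`.
#' @return List with `ppv` and `npv`.
#' @export
bayes_predictive_values <- function(sensitivity, specificity, prevalence) {
  for (v in c(sensitivity, specificity, prevalence))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("sensitivity, specificity and prevalence must be in [0, 1]")
  se <- sensitivity; sp <- specificity; pi <- prevalence
  ppv_den <- se * pi + (1 - sp) * (1 - pi)
  npv_den <- sp * (1 - pi) + (1 - se) * pi
  list(ppv = if (ppv_den > 0) unname(se * pi / ppv_den) else NA_real_,
       npv = if (npv_den > 0) unname(sp * (1 - pi) / npv_den) else NA_real_)
}

#' Welch two-sample t-test
#'
#' Unpaired t-test with Welch's correction (unequal variances,
#' Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values
#'   and positive variance in at least one group.
#' @return List with `t`, `df`, `p_value`, and the group means.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(group_a) + stats::var(group_b) <= 0)
    stop("at least one group must have positive variance")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Recurrently mutated genes across a cohort
#'
#' Counts, per gene, the number of distinct patients carrying a
#' deleterious mutation (multiple mutations of one gene in one patient
#' count once) and keeps genes mutated in at least `min_recurrence`
#' patients.
#'
#' @param mutations data.frame with columns `patient_id`, `gene`, and
#'   `deleterious` (logical).
#' @param n_patients cohort size (denominator for the percentages).
#' @param min_recurrence minimum number of mutated patients (default 2).
#' @return data.frame `gene, n_patients_mutated, pct` (integer percent),
#'   ordered by decreasing count.
#' @export
recurrent_gene_tally <- function(mutations, n_patients, min_recurrence = 2) {
  stopifnot(all(c("patient_id", "gene", "deleterious") %in% names(mutations)),
            n_patients >= 1)
  del <- mutations[mutations$deleterious, c("patient_id", "gene")]
  del <- unique(del)
  if (!nrow(del))
    return(data.frame(gene = character(), n_patients_mutated = integer(),
                      pct = numeric()))
  counts <- table(del$gene)
  keep <- counts[counts >= min_recurrence]
  out <- data.frame(gene = names(keep),
                    n_patients_mutated = as.integer(keep),
                    pct = round(100 * as.integer(keep) / n_patients),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_patients_mutated, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
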