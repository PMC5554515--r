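#' Paired test-vs-reference comparison of one metric
#'
#' One study's metric under a test AC method paired with the reference,
#' with the absolute difference, the relative difference (reference
#' denominator), and the log ratio `d = ln(test/ref)` used by the
#' agreement statistics. Both values must be positive for the log ratio to
#' exist; by construction `rel_diff_pct = 100 * (exp(d) - 1)`.
#'
#' @param subject_id,study_id Identifiers.
#' @param metric_name One of `"t_mean_over_b"`, `"t_max_over_b"`,
#'   `"btv_ml"`.
#' @param value_test,value_ref Positive metric values.
#' @param method Optional test-method label carried along.
#' @return One-row data frame.
#' @export
paired_comparison <- function(subject_id, study_id, metric_name,
                              value_test, value_ref, method = NA_character_) {
  metric_name <- match.arg(metric_name,
                           c("t_mean_over_b", "t_max_over_b", "btv_ml"))
  if (!is.finite(value_test) || !is.finite(value_ref) ||
      value_test <= 0 || value_ref <= 0)
    stop(sprintf("study %s, metric %s: paired values must be positive (test=%s, ref=%s)",
                 study_id, metric_name, format(value_test), format(value_ref)))
  data.frame(subject_id = subject_id, study_id = study_id, method = method,
             metric_name = metric_name,
             value_test = value_test, value_ref = value_ref,
             abs_diff = value_test - value_ref,
             rel_diff_pct = 100 * (value_test - value_ref) / value_ref,
             log_ratio = log(value_test / value_ref),
             stringsAsFactors = FALSE)
}

#' Standard deviation of log differences corrected for repeated measures
#'
#' When subjects contribute several studies (follow-up examinations), the
#' SD entering the limits of agreement is estimated by one-way variance
#' components: with k subjects contributing m_i values each
#' (N = sum m_i), within-subject mean square `MS_W`, between-subject mean
#' square `MS_B` and `m0 = (N - sum(m_i^2)/N) / (k - 1)`, the
#' between-subject variance is `max(0, (MS_B - MS_W)/m0)` and
#' `SD_d = sqrt(sigma_b^2 + MS_W)`. With one value per subject this reduces
#' exactly to the ordinary sample SD.
#'
#' @param d_values Numeric log differences.
#' @param subject_ids Subject tag per value.
#' @return The corrected SD (scalar).
#' @export
sd_with_repeated_measures <- function(d_values, subject_ids) {
  stopifnot(length(d_values) == length(subject_ids))
  subject_ids <- as.character(subject_ids)
  k <- length(unique(subject_ids))
  N <- length(d_values)
  if (k < 2)
    stop("between-subject variance is inestimable from a single subject")
  means <- tapply(d_values, subject_ids, mean)
  m_i <- tapply(d_values, subject_ids, length)
  grand <- mean(d_values)
  ss_w <- sum((d_values - means[subject_ids])^2)
  ms_w <- if (N > k) ss_w / (N - k) else 0
  ms_b <- sum(m_i * (means - grand)^2) / (k - 1)
  m0 <- (N - sum(m_i^2) / N) / (k - 1)
  sigma_b2 <- max(0, (ms_b - ms_w) / m0)
  sqrt(sigma_b2 + ms_w)
}

#' Bland-Altman agreement statistics on log-transformed ratios
#'
#' For paired comparisons of one metric, computes the mean log difference
#' `d_bar`, its SD (repeated-measures corrected via
#' [sd_with_repeated_measures] when any subject contributes more than one
#' study), and exponentiates back to percentage scale:
#' mean difference `100*(exp(d_bar)-1)` with 95% CI
#' `100*(exp(d_bar +/- 1.96*SD_d/sqrt(n))-1)`, 95% limits of agreement
#' `100*(exp(d_bar +/- 1.96*SD_d)-1)`, and a 95% CI for each limit.
#'
#' The CI of the limits defaults to the standard large-sample variance of
#' an agreement limit, `LoA_log +/- 1.96*sqrt(3)*SD_d/sqrt(n)`;
#' `ci_loa_variant = "literal"` instead uses
#' `100*(exp(d_bar +/- 3*SD_d/sqrt(2*n))-1)`.
#'
#' A two-sided paired t-test on the log ratios is reported as `p_value`.
#'
#' @param comparisons Data frame of [paired_comparison] rows (one metric).
#' @param ci_loa_variant `"standard"` (default) or `"literal"`.
#' @return A `bland_altman_result`: `n` (studies), `n_subjects`, `d_bar`,
#'   `sd_d`, `mean_pct`, `ci_mean_pct`, `loa_pct`, `ci_loa_pct` (list of
#'   lower/upper pairs), `p_value`.
#' @export
bland_altman <- function(comparisons, ci_loa_variant = c("standard", "literal")) {
  ci_loa_variant <- match.arg(ci_loa_variant)
  if (length(unique(comparisons$metric_name)) > 1)
    stop("comparisons mix metrics: ", paste(unique(comparisons$metric_name), collapse = ", "))
  n <- nrow(comparisons)
  if (n < 3) stop("at least 3 paired studies are required")
  bad <- comparisons$value_test <= 0 | comparisons$value_ref <= 0
  if (any(bad))
    stop("nonpositive paired values in study ",
         paste(comparisons$study_id[bad], collapse = ", "))
  d <- comparisons$log_ratio
  subj <- comparisons$subject_id
  d_bar <- mean(d)
  sd_d <- if (any(duplicated(subj))) sd_with_repeated_measures(d, subj) else sd(d)
  pct <- function(x) 100 * (exp(x) - 1)
  se <- sd_d / sqrt(n)
  loa_log <- d_bar + c(-1, 1) * 1.96 * sd_d
  ci_loa <- switch(ci_loa_variant,
    standard = list(lower = pct(loa_log[1] + c(-1, 1) * 1.96 * sqrt(3) * se),
                    upper = pct(loa_log[2] + c(-1, 1) * 1.96 * sqrt(3) * se)),
    literal = {
      half <- 3 * sd_d / sqrt(2 * n)
      list(lower = pct(d_bar - half), upper = pct(d_bar + half))
    })
  p <- if (sd(d) == 0) NA_real_ else t.test(d)$p.value
  structure(list(
    n = n, n_subjects = length(unique(subj)),
    d_bar = d_bar, sd_d = sd_d,
    mean_pct = pct(d_bar),
    ci_mean_pct = pct(d_bar + c(-1, 1) * 1.96 * se),
    loa_pct = pct(loa_log),
    ci_loa_pct = ci_loa,
    p_value = p,
    metric_name = comparisons$metric_name[1],
    ci_loa_variant = ci_loa_variant), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman_result> %s: n = %d studies (%d subjects)\n",
              x$metric_name, x$n, x$n_subjects))
  cat(sprintf("  mean %% difference %.2f (95%% CI %.2f to %.2f), p = %.3g\n",
              x$mean_pct, x$ci_mean_pct[1], x$ci_mean_pct[2], x$p_value))
  cat(sprintf("  95%% limits of agreement %.2f to %.2f\n",
              x$loa_pct[1], x$loa_pct[2]))
  invisible(x)
}

#' Clinically motivated acceptance thresholds
#'
#' Differences to the reference are acceptable when below an absolute OR a
#' relative bound: < +/-0.05 or 5% for T_MEAN/B, < +/-0.1 or 5% for
#' T_MAX/B, < +/-2 mL or 10% for the BTV, and a peak shift < 10 mm. The
#' mix of absolute and relative cut-offs reflects that a larger absolute
#' change is acceptable in large or very active tumors.
#'
#' @param t_mean_abs,t_max_abs Absolute ratio bounds.
#' @param ratio_rel_pct Relative bound (%) for both ratios.
#' @param btv_abs_ml,btv_rel_pct BTV bounds (mL, %).
#' @param peak_mm Peak-shift criterion (mm).
#' @return An `acceptance_thresholds` object.
#' @export
acceptance_thresholds <- function(t_mean_abs = 0.05, t_max_abs = 0.1,
                                  ratio_rel_pct = 5, btv_abs_ml = 2,
                                  btv_rel_pct = 10, peak_mm = 10) {
  vals <- c(t_mean_abs, t_max_abs, ratio_rel_pct, btv_abs_ml, btv_rel_pct, peak_mm)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(t_mean_abs = t_mean_abs, t_max_abs = t_max_abs,
                 ratio_rel_pct = ratio_rel_pct, btv_abs_ml = btv_abs_ml,
                 btv_rel_pct = btv_rel_pct, peak_mm = peak_mm),
            class = "acceptance_thresholds")
}

#' Acceptance-criteria check for one study
#'
#' A metric passes iff its absolute difference is strictly below the
#' absolute bound OR its relative difference is strictly below the relative
#' bound; the study passes overall iff all three metrics pass.
#'
#' @param c_tmean,c_tmax,c_btv [paired_comparison] rows for
#'   `t_mean_over_b`, `t_max_over_b` and `btv_ml` of the same study.
#' @param thresholds An [acceptance_thresholds].
#' @return `list(t_mean_over_b, t_max_over_b, btv_ml, overall)` of logicals
#'   (`TRUE` = pass).
#' @export
acceptance_check <- function(c_tmean, c_tmax, c_btv,
                             thresholds = acceptance_thresholds()) {
  expect_metric <- function(cmp, name) {
    if (!identical(cmp$metric_name, name))
      stop(sprintf("expected a %s comparison, got %s", name, cmp$metric_name))
  }
  expect_metric(c_tmean, "t_mean_over_b")
  expect_metric(c_tmax, "t_max_over_b")
  expect_metric(c_btv, "btv_ml")
  ids <- unique(c(c_tmean$study_id, c_tmax$study_id, c_btv$study_id))
  if (length(ids) > 1)
    stop("comparisons refer to different studies: ", paste(ids, collapse = ", "))
  pass <- function(cmp, abs_bound, rel_bound)
    abs(cmp$abs_diff) < abs_bound || abs(cmp$rel_diff_pct) < rel_bound
  p1 <- pass(c_tmean, thresholds$t_mean_abs, thresholds$ratio_rel_pct)
  p2 <- pass(c_tmax, thresholds$t_max_abs, thresholds$ratio_rel_pct)
  p3 <- pass(c_btv, thresholds$btv_abs_ml, thresholds$btv_rel_pct)
  list(t_mean_over_b = p1, t_max_over_b = p2, btv_ml = p3,
       overall = p1 && p2 && p3)
}

#' Clinical T_MAX/B category
#'
#' `< 2.0` is considered reactive tissue, `> 2.4` indicative of active
#' tumor; values in the closed interval \[2.0, 2.4\] (boundaries included)
#' are equivocal.
#'
#' @param t_max_over_b Positive ratio value(s); vectorized.
#' @return Factor with levels `reactive`, `equivocal`, `active`.
#' @export
classify_category <- function(t_max_over_b) {
  if (any(!is.finite(t_max_over_b)) || any(t_max_over_b <= 0))
    stop("t_max_over_b must be positive")
  out <- ifelse(t_max_over_b < 2.0, "reactive",
                ifelse(t_max_over_b > 2.4, "active", "equivocal"))
  factor(out, levels = c("reactive", "equivocal", "active"))
}

#' Category shift contingency table
#'
#' Tallies reference-vs-test clinical categories and counts category
#' changes (off-diagonal entries).
#'
#' @param ref_categories,test_categories Category vectors (as from
#'   [classify_category]) over the same studies.
#' @return `list(table` (3x3 counts, reference in rows)`, n_shifted)`.
#' @export
category_shift_table <- function(ref_categories, test_categories) {
  lev <- c("reactive", "equivocal", "active")
  ref <- factor(ref_categories, levels = lev)
  test <- factor(test_categories, levels = lev)
  if (length(ref) != length(test))
    stop("category vectors must cover the same studies")
  tab <- table(reference = ref, test = test)
  list(table = tab, n_shifted = sum(tab) - sum(diag(tab)))
}

#' Cohort agreement summary table
#'
#' Per (method, metric): mean percentage difference with 95% CI and
#' p-value, and lower/upper 95% limits of agreement — one row per
#' combination, shaped like a methods-comparison summary table.
#'
#' @param comparisons Data frame of [paired_comparison] rows with a
#'   `method` column.
#' @param ... Passed to [bland_altman].
#' @return Data frame with columns `method`, `metric_name`, `n`,
#'   `n_subjects`, `mean_pct`, `ci_lo`, `ci_hi`, `p_value`, `loa_lo`,
#'   `loa_hi`.
#' @export
agreement_table <- function(comparisons, ...) {
  groups <- split(comparisons,
                  list(comparisons$method, comparisons$metric_name),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    ba <- bland_altman(g, ...)
    data.frame(method = g$method[1], metric_name = g$metric_name[1],
               n = ba$n, n_subjects = ba$n_subjects,
               mean_pct = ba$mean_pct,
               ci_lo = ba$ci_mean_pct[1], ci_hi = ba$ci_mean_pct[2],
               p_value = ba$p_value,
               loa_lo = ba$loa_pct[1], loa_hi = ba$loa_pct[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$metric_name), , drop = FALSE]
}
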