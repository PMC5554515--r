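#' Baseline-to-follow-up change of one metric
#'
#' Absolute and percentage change relative to the baseline value, with a
#' direction label: `stable` when |percent change| is below the stability
#' band (default 2%), else `increase`/`decrease`. Percentages are kept at
#' full precision; round only at presentation (the clinical convention is
#' nearest integer percent).
#'
#' @param baseline_value Positive baseline value.
#' @param followup_value Follow-up value.
#' @param metric_name Optional metric label carried along.
#' @param subject_id,ac_baseline,ac_followup Optional labels (subject, AC
#'   method at each end of the pairing).
#' @param stability_band Half-width (%) of the `stable` band (default 2).
#' @return One-row data frame: identifiers, `value_baseline`,
#'   `value_followup`, `abs_change`, `pct_change`, `direction`.
#' @export
change_metrics <- function(baseline_value, followup_value,
                           metric_name = NA_character_,
                           subject_id = NA_character_,
                           ac_baseline = NA_character_,
                           ac_followup = NA_character_,
                           stability_band = 2) {
  if (!is.finite(baseline_value) || baseline_value <= 0)
    stop("baseline value must be positive")
  pct <- 100 * (followup_value - baseline_value) / baseline_value
  direction <- if (abs(pct) < stability_band) "stable"
  else if (pct > 0) "increase" else "decrease"
  data.frame(subject_id = subject_id, metric_name = metric_name,
             ac_baseline = ac_baseline, ac_followup = ac_followup,
             value_baseline = baseline_value,
             value_followup = followup_value,
             abs_change = followup_value - baseline_value,
             pct_change = pct, direction = direction,
             stringsAsFactors = FALSE)
}

#' Deviation of a test follow-up change from the reference change
#'
#' Compares the percent change observed under a test AC pairing with the
#' reference pairing for the same subject and metric. The deviation is
#' flagged when it exceeds `btv_points` percentage points for the BTV
#' (default 10) or `ratio_points` for ratio metrics (default 5), strictly;
#' a discordant direction (one increase, the other decrease) is flagged
#' separately.
#'
#' @param change_test,change_ref Rows from [change_metrics] for the same
#'   subject and metric.
#' @param ratio_points,btv_points Deviation criteria in percentage points.
#' @return One-row data frame: identifiers, `pct_change_test`,
#'   `pct_change_ref`, `deviation_points`, `exceeds_criterion`,
#'   `discordant_direction`.
#' @export
compare_changes <- function(change_test, change_ref,
                            ratio_points = 5, btv_points = 10) {
  if (!identical(change_test$metric_name, change_ref$metric_name))
    stop("metric mismatch: ", change_test$metric_name, " vs ",
         change_ref$metric_name)
  if (!identical(change_test$subject_id, change_ref$subject_id))
    stop("subject mismatch: ", change_test$subject_id, " vs ",
         change_ref$subject_id)
  dev <- change_test$pct_change - change_ref$pct_change
  bound <- if (identical(change_test$metric_name, "btv_ml")) btv_points else ratio_points
  discordant <- (change_test$direction == "increase" & change_ref$direction == "decrease") |
    (change_test$direction == "decrease" & change_ref$direction == "increase")
  data.frame(subject_id = change_test$subject_id,
             metric_name = change_test$metric_name,
             ac_baseline_test = change_test$ac_baseline,
             ac_followup_test = change_test$ac_followup,
             pct_change_test = change_test$pct_change,
             pct_change_ref = change_ref$pct_change,
             deviation_points = dev,
             exceeds_criterion = abs(dev) > bound,
             discordant_direction = discordant,
             stringsAsFactors = FALSE)
}

#' Follow-up changes under a stated AC pairing
#'
#' Computes baseline-to-follow-up changes when a chosen AC method is used
#' at each end: `ref->ref` and `test->test` are within-modality changes;
#' `ref->test` and `test->ref` simulate switching AC method between the
#' examinations.
#'
#' @param study_pairs Data frame with one row per (subject, metric) and
#'   columns `subject_id`, `metric_name`, `ref_baseline`, `ref_followup`,
#'   `test_baseline`, `test_followup`. `NA` values for a requested pairing
#'   are an error naming the study.
#' @param pairing One of `"ref->ref"`, `"ref->test"`, `"test->ref"`,
#'   `"test->test"`.
#' @param ref_label,test_label Method labels recorded in the output.
#' @param stability_band Passed to [change_metrics].
#' @return Data frame of [change_metrics] rows, one per input row.
#' @export
cross_modality_change <- function(study_pairs,
                                  pairing = c("ref->ref", "ref->test",
                                              "test->ref", "test->test"),
                                  ref_label = "ref", test_label = "test",
                                  stability_band = 2) {
  pairing <- match.arg(pairing)
  ends <- strsplit(pairing, "->", fixed = TRUE)[[1]]
  col_b <- paste0(ends[1], "_baseline")
  col_f <- paste0(ends[2], "_followup")
  lab <- c(ref = ref_label, test = test_label)
  missing_rows <- !is.finite(study_pairs[[col_b]]) | !is.finite(study_pairs[[col_f]])
  if (any(missing_rows))
    stop("missing value for pairing ", pairing, " in subject(s): ",
         paste(unique(study_pairs$subject_id[missing_rows]), collapse = ", "))
  rows <- lapply(seq_len(nrow(study_pairs)), function(i)
    change_metrics(study_pairs[[col_b]][i], study_pairs[[col_f]][i],
                   metric_name = study_pairs$metric_name[i],
                   subject_id = study_pairs$subject_id[i],
                   ac_baseline = lab[[ends[1]]], ac_followup = lab[[ends[2]]],
                   stability_band = stability_band))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
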