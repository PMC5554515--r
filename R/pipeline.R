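#' Analysis configuration
#'
#' Collects every tunable of the phantom-to-report pipeline: cohort
#' composition, delineation threshold, acceptance thresholds,
#' shape-deviation parameters, stability band, output directory and seed.
#' A config round-trips losslessly through its JSON file form
#' ([write_config] / [read_config]).
#'
#' @param n_subjects Number of subjects to simulate.
#' @param followup_fraction Fraction of subjects with a follow-up pair.
#' @param seed Master seed for all randomness.
#' @param grid_shape,spacing Phantom grid (voxels, mm).
#' @param noise_sd Relative Gaussian noise SD of the simulated images.
#' @param profiles Named list of [method_profile]s (must include
#'   `reference`).
#' @param reference Label of the reference (CT-analog, identity-bias)
#'   method all comparisons are made against.
#' @param threshold_ratio Isocontour ratio over background (default 1.6).
#' @param thresholds An [acceptance_thresholds].
#' @param shape_fwhm_mm,shape_level Shape-deviation smoothing FWHM (mm) and
#'   binarization level.
#' @param stability_band Follow-up `stable` band, percent.
#' @param min_component_ml Minimum kept component volume when no prior is
#'   used.
#' @param use_prior Restrict delineation to components intersecting the
#'   ground-truth tumor mask (clinician-seed analog; default TRUE).
#' @param vary_geometry Randomize tumor geometry across subjects (passed to
#'   [generate_cohort]; default TRUE).
#' @param output_dir Optional directory for tables/volumes.
#' @param write_volumes Also write every study's NIfTI volumes (default
#'   FALSE; tables and JSON only).
#' @return An `analysis_config`.
#' @export
analysis_config <- function(n_subjects = 20, followup_fraction = 0.2,
                            seed = 1L,
                            grid_shape = c(128, 128, 128),
                            spacing = c(2, 2, 2), noise_sd = 0.03,
                            profiles = default_method_profiles(),
                            reference = "CTAC",
                            threshold_ratio = 1.6,
                            thresholds = acceptance_thresholds(),
                            shape_fwhm_mm = 5, shape_level = 0.5,
                            stability_band = 2, min_component_ml = 0.1,
                            use_prior = TRUE, vary_geometry = TRUE,
                            output_dir = NULL, write_volumes = FALSE) {
  if (!reference %in% names(profiles))
    stop("reference method '", reference, "' is not among the profiles")
  structure(list(n_subjects = n_subjects,
                 followup_fraction = followup_fraction, seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
                 noise_sd = noise_sd, profiles = profiles, reference = reference,
                 threshold_ratio = threshold_ratio, thresholds = thresholds,
                 shape_fwhm_mm = shape_fwhm_mm, shape_level = shape_level,
                 stability_band = stability_band,
                 min_component_ml = min_component_ml, use_prior = use_prior,
                 vary_geometry = vary_geometry,
                 output_dir = output_dir, write_volumes = write_volumes),
            class = "analysis_config")
}

#' Write a configuration to JSON
#' @param config An [analysis_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  plain$profiles <- lapply(config$profiles, unclass)
  plain$thresholds <- unclass(config$thresholds)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a configuration from JSON
#' @param path A file written by [write_config].
#' @return An [analysis_config].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  profiles <- lapply(x$profiles, function(p) {
    p[names(p) != "label"] <- lapply(p[names(p) != "label"], as.numeric)
    do.call(method_profile, p)   # "Inf" round-trips as a JSON string
  })
  thresholds <- do.call(acceptance_thresholds, x$thresholds)
  analysis_config(n_subjects = x$n_subjects,
                  followup_fraction = x$followup_fraction, seed = x$seed,
                  grid_shape = x$grid_shape, spacing = x$spacing,
                  noise_sd = x$noise_sd, profiles = profiles,
                  reference = x$reference,
                  threshold_ratio = x$threshold_ratio,
                  thresholds = thresholds, shape_fwhm_mm = x$shape_fwhm_mm,
                  shape_level = x$shape_level,
                  stability_band = x$stability_band,
                  min_component_ml = x$min_component_ml,
                  use_prior = x$use_prior,
                  vary_geometry = x$vary_geometry,
                  output_dir = x$output_dir,
                  write_volumes = x$write_volumes)
}

# Analyze one study record: delineate every method, compare to reference.
# Returns per-study rows, comparisons, acceptance verdicts, spatial metrics.
analyze_study <- function(record, config) {
  scene <- record$scene
  methods <- names(scene$biased)
  ref <- config$reference
  prior <- if (config$use_prior) scene$tumor_truth_mask else NULL
  delins <- list()
  per_study <- list()
  for (m in methods) {
    pet <- scene$biased[[m]]
    b <- background_mean(pet, scene$background_roi_mask)
    delin <- delineate_btv(pet, b, exclusion_mask = scene$exclusion_mask,
                           tumor_prior_mask = prior,
                           threshold_ratio = config$threshold_ratio,
                           min_component_ml = config$min_component_ml)
    if (delin$empty)
      stop("empty delineation for method ", m, " in study ", record$study_id)
    delins[[m]] <- delin
    tm <- tumor_metrics(delin)
    per_study[[m]] <- data.frame(
      subject_id = record$subject_id, study_id = record$study_id,
      timepoint = record$timepoint, method = m,
      background_b = b, btv_ml = delin$btv_ml,
      t_mean = delin$t_mean, t_max = delin$t_max,
      t_mean_over_b = tm$t_mean_over_b, t_max_over_b = tm$t_max_over_b,
      category = as.character(classify_category(tm$t_max_over_b)),
      stringsAsFactors = FALSE)
  }
  ref_row <- per_study[[ref]]
  comparisons <- list(); acceptance <- list(); spatial <- list()
  for (m in setdiff(methods, ref)) {
    row <- per_study[[m]]
    cmp <- list(
      t_mean = paired_comparison(record$subject_id, record$study_id,
                                 "t_mean_over_b", row$t_mean_over_b,
                                 ref_row$t_mean_over_b, method = m),
      t_max = paired_comparison(record$subject_id, record$study_id,
                                "t_max_over_b", row$t_max_over_b,
                                ref_row$t_max_over_b, method = m),
      btv = paired_comparison(record$subject_id, record$study_id,
                              "btv_ml", row$btv_ml, ref_row$btv_ml,
                              method = m),
      t_mean_act = paired_comparison(record$subject_id, record$study_id,
                                     "t_mean_over_b", row$t_mean,
                                     ref_row$t_mean, method = m))
    cmp$t_mean_act$metric_name <- "t_mean"   # activity, not a ratio
    comparisons[[m]] <- do.call(rbind, cmp)
    verdict <- acceptance_check(cmp$t_mean, cmp$t_max, cmp$btv,
                                config$thresholds)
    ps <- peak_shift(delins[[m]], delins[[ref]],
                     criterion_mm = config$thresholds$peak_mm)
    sd_rep <- shape_deviation(delins[[ref]], delins[[m]],
                              smoothing_fwhm_mm = config$shape_fwhm_mm,
                              binarization_level = config$shape_level)
    acceptance[[m]] <- data.frame(
      subject_id = record$subject_id, study_id = record$study_id,
      method = m, pass_t_mean = verdict$t_mean_over_b,
      pass_t_max = verdict$t_max_over_b, pass_btv = verdict$btv_ml,
      pass_overall = verdict$overall, stringsAsFactors = FALSE)
    spatial[[m]] <- data.frame(
      subject_id = record$subject_id, study_id = record$study_id,
      method = m, jaccard = jaccard(delins[[m]], delins[[ref]]),
      peak_shift_mm = ps$distance_mm,
      peak_exceeds = ps$exceeds_criterion,
      n_warps_over_1ml = sd_rep$n_warps_over_1ml,
      stringsAsFactors = FALSE)
  }
  list(per_study = do.call(rbind, per_study),
       comparisons = do.call(rbind, comparisons),
       acceptance = do.call(rbind, acceptance),
       spatial = do.call(rbind, spatial))
}

# Follow-up analysis over accumulated per-study metric rows.
analyze_followup <- function(per_study, config) {
  ref <- config$reference
  within <- list(); cross <- list()
  fu_subjects <- unique(per_study$subject_id[per_study$timepoint == 2])
  metrics <- c("btv_ml", "t_mean_over_b", "t_max_over_b")
  for (s in fu_subjects) {
    sub <- per_study[per_study$subject_id == s, ]
    for (m in setdiff(unique(sub$method), ref)) {
      for (metric in metrics) {
        val <- function(method, tp)
          sub[[metric]][sub$method == method & sub$timepoint == tp]
        pairs <- data.frame(subject_id = s, metric_name = metric,
                            ref_baseline = val(ref, 1),
                            ref_followup = val(ref, 2),
                            test_baseline = val(m, 1),
                            test_followup = val(m, 2),
                            stringsAsFactors = FALSE)
        ch <- function(p) cross_modality_change(
          pairs, p, ref_label = ref, test_label = m,
          stability_band = config$stability_band)
        ref_change <- ch("ref->ref")
        for (p in c("test->test", "ref->test", "test->ref")) {
          dev <- compare_changes(ch(p), ref_change,
                                 ratio_points = config$thresholds$ratio_rel_pct,
                                 btv_points = config$thresholds$btv_rel_pct)
          dev$pairing <- p
          dev$method <- m
          if (p == "test->test") within[[length(within) + 1]] <- dev
          else cross[[length(cross) + 1]] <- dev
        }
      }
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(within = bind(within), cross = bind(cross))
}

#' Run the full phantom-to-report pipeline
#'
#' Simulates the cohort described by the config (streaming, one study at a
#' time), delineates every AC method of every study, compares each test
#' method against the reference (clinical ratios, BTV, acceptance
#' verdicts, category, Jaccard, peak shift, shape deviation), computes
#' per-metric-per-method Bland-Altman tables, and runs the follow-up
#' consistency analysis. Per-study failures are quarantined with their
#' message, not fatal. Deterministic given the config seed.
#'
#' @param config An [analysis_config].
#' @return A result bundle: data frames `per_study`, `comparisons`,
#'   `acceptance`, `spatial`, `agreement` (Bland-Altman summary),
#'   `followup_within`, `followup_cross`, `quarantine`, plus `summary`
#'   (named list of cohort-level counts) and the `config`. Written as CSV +
#'   JSON under `config$output_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  acc <- new.env(parent = emptyenv())
  acc$per_study <- list(); acc$comparisons <- list()
  acc$acceptance <- list(); acc$spatial <- list(); acc$quarantine <- list()
  base_spec <- phantom_spec(grid_shape = config$grid_shape,
                            spacing = config$spacing,
                            noise_sd = config$noise_sd)
  vol_dir <- if (!is.null(config$output_dir) && config$write_volumes)
    file.path(config$output_dir, "volumes") else NULL
  cb <- function(record) {
    res <- tryCatch(analyze_study(record, config), error = function(e) e)
    if (inherits(res, "error")) {
      acc$quarantine[[length(acc$quarantine) + 1]] <- data.frame(
        study_id = record$study_id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    i <- length(acc$per_study) + 1
    acc$per_study[[i]] <- res$per_study
    acc$comparisons[[i]] <- res$comparisons
    acc$acceptance[[i]] <- res$acceptance
    acc$spatial[[i]] <- res$spatial
    invisible(NULL)
  }
  records <- generate_cohort(config$n_subjects, config$profiles,
                             followup_fraction = config$followup_fraction,
                             seed = config$seed, base_spec = base_spec,
                             vary_geometry = config$vary_geometry,
                             output_dir = vol_dir, callback = cb)
  manifest <- attr(records, "manifest")
  bind <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else NULL
  per_study <- bind(acc$per_study)
  comparisons <- bind(acc$comparisons)
  acceptance <- bind(acc$acceptance)
  spatial <- bind(acc$spatial)
  quarantine <- bind(acc$quarantine)
  ratio_cmp <- comparisons[comparisons$metric_name %in%
                             c("t_mean_over_b", "t_max_over_b", "btv_ml"), ]
  agreement <- agreement_table(ratio_cmp)
  fu <- analyze_followup(per_study, config)

  fail_by_method <- tapply(!acceptance$pass_overall, acceptance$method, sum)
  summary <- list(
    n_subjects = config$n_subjects,
    n_studies = length(unique(per_study$study_id)),
    n_followup_pairs = sum(manifest$timepoint == 2),
    n_quarantined = if (is.null(quarantine)) 0L else nrow(quarantine),
    failed_acceptance = as.list(fail_by_method),
    mean_jaccard = as.list(tapply(spatial$jaccard, spatial$method, mean)),
    peak_over_criterion = as.list(tapply(spatial$peak_exceeds,
                                         spatial$method, mean)),
    warp_fraction = as.list(tapply(spatial$n_warps_over_1ml > 0,
                                   spatial$method, mean)))
  bundle <- list(per_study = per_study, comparisons = comparisons,
                 acceptance = acceptance, spatial = spatial,
                 agreement = agreement, followup_within = fu$within,
                 followup_cross = fu$cross, quarantine = quarantine,
                 manifest = manifest, summary = summary, config = config)
  if (!is.null(config$output_dir)) write_tables(bundle, config$output_dir)
  bundle
}

#' Write all result tables of a pipeline run
#'
#' Emits each data frame of the bundle as CSV (fixed column schemas as
#' documented on [run_pipeline]) and the cohort summary as
#' `summary.json`.
#'
#' @param bundle Result of [run_pipeline].
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_tables <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("per_study", "comparisons", "acceptance", "spatial",
            "agreement", "followup_within", "followup_cross",
            "quarantine", "manifest")
  for (t in tabs)
    if (!is.null(bundle[[t]]))
      write.csv(bundle[[t]], file.path(output_dir, paste0(t, ".csv")),
                row.names = FALSE)
  jsonlite::write_json(bundle$summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(output_dir)
}
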