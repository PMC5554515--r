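#' Mean background uptake in a ROI
#'
#' Arithmetic mean of the PET image over the background ROI ("banana"
#' region in healthy contralateral tissue). An identical ROI should be used
#' for every AC method of a study.
#'
#' @param pet A [volume_image].
#' @param roi_mask Logical [volume_image], grid-compatible, non-empty.
#' @return Mean activity (units of `pet`).
#' @export
background_mean <- function(pet, roi_mask) {
  stop_if_grid_mismatch(pet, roi_mask, "PET and background ROI")
  if (!any(roi_mask$values)) stop("background ROI is empty")
  mean(pet$values[roi_mask$values])
}

#' Delineate the biological tumor volume by adaptive isocontour
#'
#' Segments tumor tissue at a unique threshold of `threshold_ratio` (default
#' 1.6) times the background mean: voxels with activity strictly above the
#' threshold, minus the exclusion mask (extratumoral hot structures),
#' restricted to 26-connected components that intersect `tumor_prior_mask`
#' if one is supplied, otherwise to all components of at least
#' `min_component_ml`.
#'
#' An empty result is a valid delineation (`btv_ml = 0`, `empty = TRUE`,
#' `t_mean`/`t_max` set to `NA`), not an error. The T_MAX peak voxel is the
#' lexicographically smallest index triple among maxima (deterministic).
#'
#' @param pet A [volume_image].
#' @param background_b Background mean B (> 0) from [background_mean].
#' @param exclusion_mask Optional logical [volume_image] removed before
#'   component analysis.
#' @param tumor_prior_mask Optional logical [volume_image]; keep only
#'   components intersecting it (clinician's seed analog).
#' @param threshold_ratio Ratio over B defining tumor tissue (default 1.6).
#' @param min_component_ml Minimum component volume (mL) kept when no prior
#'   is given (default 0.1).
#' @return A `tumor_delineation`: `mask` ([volume_image]), `btv_ml`,
#'   `t_mean`, `t_max`, `peak_index` (1-based voxel triple), `peak_world`
#'   (mm), `background_b`, `threshold_used`, `empty`, `n_components`.
#' @export
delineate_btv <- function(pet, background_b, exclusion_mask = NULL,
                          tumor_prior_mask = NULL, threshold_ratio = 1.6,
                          min_component_ml = 0.1) {
  stopifnot(inherits(pet, "volume_image"))
  if (!is.finite(background_b) || background_b <= 0)
    stop("background_b must be > 0")
  threshold <- threshold_ratio * background_b
  above <- pet$values > threshold
  if (!is.null(exclusion_mask)) {
    stop_if_grid_mismatch(pet, exclusion_mask, "PET and exclusion mask")
    above <- above & !exclusion_mask$values
  }
  mask <- array(FALSE, dim(pet$values))
  n_components <- 0L
  if (any(above)) {
    labels <- cpp_label_components(above, as.integer(dim(above)))
    nlab <- max(labels)
    keep <- logical(nlab)
    if (!is.null(tumor_prior_mask)) {
      stop_if_grid_mismatch(pet, tumor_prior_mask, "PET and tumor prior mask")
      hit <- unique(labels[labels > 0 & tumor_prior_mask$values])
      keep[hit] <- TRUE
    } else {
      vox_ml <- voxel_volume_ml(pet)
      sizes <- tabulate(labels[labels > 0], nbins = nlab)
      keep[sizes * vox_ml >= min_component_ml] <- TRUE
    }
    mask <- array(labels > 0 & keep[pmax(labels, 1L)], dim(above))
    n_components <- sum(keep)
  }
  vox_ml <- voxel_volume_ml(pet)
  btv_ml <- sum(mask) * vox_ml
  if (btv_ml == 0) {
    out <- list(mask = volume_image(mask, pet$spacing, pet$origin),
                btv_ml = 0, t_mean = NA_real_, t_max = NA_real_,
                peak_index = NULL, peak_world = NULL,
                background_b = background_b, threshold_used = threshold,
                empty = TRUE, n_components = 0L)
    return(structure(out, class = "tumor_delineation"))
  }
  vals <- pet$values[mask]
  t_max <- max(vals)
  idx <- which(mask & pet$values == t_max, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3])[1], , drop = TRUE]
  structure(list(
    mask = volume_image(mask, pet$spacing, pet$origin),
    btv_ml = btv_ml, t_mean = mean(vals), t_max = t_max,
    peak_index = as.integer(idx),
    peak_world = voxel_to_world(pet, idx),
    background_b = background_b, threshold_used = threshold,
    empty = FALSE, n_components = as.integer(n_components)),
    class = "tumor_delineation")
}

#' @export
print.tumor_delineation <- function(x, ...) {
  if (x$empty) {
    cat("<tumor_delineation> empty (BTV 0 mL), threshold",
        format(x$threshold_used), "\n")
  } else {
    cat(sprintf(
      "<tumor_delineation> BTV %.2f mL, T_MEAN %.3f, T_MAX %.3f, B %.3f (threshold %.3f)\n",
      x$btv_ml, x$t_mean, x$t_max, x$background_b, x$threshold_used))
    cat(sprintf("  T_MEAN/B %.3f, T_MAX/B %.3f, peak voxel (%s)\n",
                x$t_mean / x$background_b, x$t_max / x$background_b,
                paste(x$peak_index, collapse = ",")))
  }
  invisible(x)
}

#' Clinical uptake ratios of a delineation
#'
#' Ratios of the stored scalars; the image is not re-scanned.
#'
#' @param delineation A `tumor_delineation` with `btv_ml > 0`.
#' @return `list(t_mean_over_b, t_max_over_b)`.
#' @export
tumor_metrics <- function(delineation) {
  stopifnot(inherits(delineation, "tumor_delineation"))
  if (delineation$btv_ml <= 0 || isTRUE(delineation$empty))
    stop("delineation is empty (btv_ml = 0); ratios are undefined — check the `empty` flag")
  if (delineation$background_b <= 0) stop("background_b must be > 0")
  list(t_mean_over_b = delineation$t_mean / delineation$background_b,
       t_max_over_b = delineation$t_max / delineation$background_b)
}

#' Shift of the T_MAX peak location between two delineations
#'
#' Euclidean distance (mm) between peak world coordinates, with a biopsy
#' relevance flag: displacements of `criterion_mm` (default 10 mm, the
#' approximate size of a stereotactic biopsy) or more exceed the criterion;
#' strictly smaller shifts pass.
#'
#' @param delin_a,delin_b Non-empty, grid-compatible `tumor_delineation`s.
#' @param criterion_mm Distance criterion in mm (default 10).
#' @return `list(distance_mm, exceeds_criterion)`.
#' @export
peak_shift <- function(delin_a, delin_b, criterion_mm = 10) {
  if (isTRUE(delin_a$empty) || isTRUE(delin_b$empty))
    stop("peak_shift requires non-empty delineations on both sides")
  stop_if_grid_mismatch(delin_a$mask, delin_b$mask, "delineation masks")
  d <- sqrt(sum((delin_a$peak_world - delin_b$peak_world)^2))
  list(distance_mm = d, exceeds_criterion = d >= criterion_mm)
}

#' Jaccard similarity of two binary masks
#'
#' @param mask_a,mask_b Grid-compatible logical [volume_image]s (or a
#'   `tumor_delineation`, whose mask is used); union must be non-empty.
#' @return |A intersect B| / |A union B|, in \[0, 1\].
#' @export
jaccard <- function(mask_a, mask_b) {
  get_mask <- function(m) if (inherits(m, "tumor_delineation")) m$mask else m
  mask_a <- get_mask(mask_a); mask_b <- get_mask(mask_b)
  stop_if_grid_mismatch(mask_a, mask_b, "masks")
  a <- mask_a$values; b <- mask_b$values
  uni <- sum(a | b)
  if (uni == 0) stop("Jaccard index is undefined for two empty masks")
  sum(a & b) / uni
}

#' Shape-deviation analysis of two tumor masks
#'
#' Distinguishes focal warps of the tumor outline from uniform one-voxel
#' contour shifts: the signed difference `indicator(test) - indicator(ref)`
#' is Gaussian-smoothed (default FWHM 5 mm, matching typical reconstruction
#' post-filtering) and thresholded at `binarization_level` (default 0.5) in
#' absolute value; surviving 26-connected components of each sign are
#' reported with volume and centroid. A thin uniform rim is averaged away
#' by the smoothing, while a focal nodule survives.
#'
#' @param mask_ref,mask_test Grid-compatible logical [volume_image]s (or
#'   `tumor_delineation`s).
#' @param smoothing_fwhm_mm Gaussian FWHM in mm (default 5).
#' @param binarization_level Threshold on the smoothed difference
#'   (default 0.5).
#' @return A `shape_deviation_report`: `components` data frame (direction
#'   `"expansion"`/`"erosion"`, `volume_ml`, centroid mm), plus
#'   `n_warps_over_1ml` and the parameters used. Identical masks yield an
#'   empty report.
#' @export
shape_deviation <- function(mask_ref, mask_test, smoothing_fwhm_mm = 5,
                            binarization_level = 0.5) {
  get_mask <- function(m) if (inherits(m, "tumor_delineation")) m$mask else m
  mask_ref <- get_mask(mask_ref); mask_test <- get_mask(mask_test)
  stop_if_grid_mismatch(mask_ref, mask_test, "masks")
  D <- volume_image(array(as.numeric(mask_test$values) - as.numeric(mask_ref$values),
                          dim(mask_ref$values)),
                    mask_ref$spacing, mask_ref$origin)
  sm <- gaussian_smooth(D, smoothing_fwhm_mm)$values
  vox_ml <- voxel_volume_ml(mask_ref)
  comps <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) sm > binarization_level else sm < -binarization_level
    if (!any(sel)) next
    labels <- cpp_label_components(sel, as.integer(dim(sel)))
    for (l in seq_len(max(labels))) {
      idx <- which(labels == l, arr.ind = TRUE)
      centroid <- mask_ref$origin + (colMeans(idx) - 1) * mask_ref$spacing
      comps[[length(comps) + 1]] <- data.frame(
        direction = if (sgn > 0) "expansion" else "erosion",
        volume_ml = nrow(idx) * vox_ml,
        centroid_x = centroid[1], centroid_y = centroid[2],
        centroid_z = centroid[3], stringsAsFactors = FALSE)
    }
  }
  components <- if (length(comps)) do.call(rbind, comps) else
    data.frame(direction = character(), volume_ml = numeric(),
               centroid_x = numeric(), centroid_y = numeric(),
               centroid_z = numeric(), stringsAsFactors = FALSE)
  structure(list(components = components,
                 n_warps_over_1ml = sum(components$volume_ml > 1),
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 binarization_level = binarization_level),
            class = "shape_deviation_report")
}

#' @export
print.shape_deviation_report <- function(x, ...) {
  cat(sprintf("<shape_deviation_report> %d component(s), %d warp(s) > 1 mL (FWHM %.1f mm, level %.2f)\n",
              nrow(x$components), x$n_warps_over_1ml,
              x$smoothing_fwhm_mm, x$binarization_level))
  if (nrow(x$components)) print(x$components, ...)
  invisible(x)
}
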