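#' Specification of a synthetic FET-PET brain phantom
#'
#' Describes a digital phantom: an ellipsoidal brain with uniform background
#' uptake, one or more spherical tumor foci at a stated contrast over
#' background, an optional resection cavity, and extratumoral high-uptake
#' structures (skin, vascular) outside the brain. Units are SUV-like and
#' arbitrary: every downstream metric is a ratio or a volume.
#'
#' @param grid_shape Integer length-3, voxels per axis. Default 128^3.
#' @param spacing Numeric length-3, mm per voxel. Default 2 mm isotropic,
#'   approximating clinical PET reconstruction resolution.
#' @param background_uptake Background activity inside the brain (> 0).
#' @param tumor_foci List of foci, each `list(center =` voxel index triple
#'   (1-based, may be fractional)`, radius_mm, contrast)` with contrast the
#'   multiplier over background. At least one focus must exceed the
#'   delineation ratio so a biological tumor volume exists. Optional
#'   per-focus fields `margin_mm` (default 0) and `margin_contrast`
#'   (default 1.4) add an infiltrative rim of moderately elevated uptake
#'   extending `margin_mm` beyond the focus radius — below the isocontour
#'   threshold under correct AC, but close enough that a local
#'   overestimation can pull it into the delineation (the substrate of
#'   nodular BTV warps).
#' @param cavity Optional `list(center, radius_mm, uptake_fraction)` with
#'   `uptake_fraction < 1`, a resection cavity carved into the brain.
#' @param extratumoral_sources List of `list(center, radius_mm, contrast)`
#'   hot structures placed outside the brain (skin/vascular analogs).
#' @param noise_sd Relative Gaussian noise SD applied when biasing images.
#' @param psf_fwhm_mm Scanner resolution emulation: FWHM (mm) of the
#'   Gaussian blur applied to the sharp truth to form the imaged volume
#'   `pet_truth` (default 5 mm, typical reconstruction post-filtering;
#'   0 disables). Ground-truth masks are defined on the sharp truth.
#' @param focus_peaking Relative center-to-edge uptake elevation within
#'   each focus (default 0.15): focus activity rises parabolically from
#'   `contrast` x background at the rim to `contrast * (1 + focus_peaking)`
#'   at the center, emulating the heterogeneous "hot spot" structure used
#'   for biopsy targeting. 0 gives uniform foci.
#' @param seed Integer seed controlling stochastic parts of generation.
#' @param roi_volume_ml Target background-ROI volume (mL); the ROI is a
#'   curved contralateral slab, see [generate_phantom].
#' @param btv_ratio Threshold ratio over background defining ground-truth
#'   tumor membership (default 1.6, the clinical isocontour level).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128),
                         spacing = c(2, 2, 2),
                         background_uptake = 1,
                         tumor_foci = list(list(
                           center = c(0.65, 0.5, 0.5) * grid_shape,
                           radius_mm = 15, contrast = 3)),
                         cavity = NULL,
                         extratumoral_sources = list(),
                         noise_sd = 0.03,
                         psf_fwhm_mm = 5,
                         focus_peaking = 0.15,
                         seed = 1L,
                         roi_volume_ml = 15,
                         btv_ratio = 1.6) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  if (background_uptake <= 0) stop("background_uptake must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  if (focus_peaking < 0) stop("focus_peaking must be >= 0")
  if (length(tumor_foci) == 0)
    stop("at least one tumor focus is required: no BTV of 1 mL or more is possible without one")
  tumor_foci <- lapply(tumor_foci, function(f) {
    if (is.null(f$margin_mm)) f$margin_mm <- 0
    if (is.null(f$margin_contrast)) f$margin_contrast <- 1.4
    f
  })
  for (f in tumor_foci) {
    if (f$contrast <= 0) stop("tumor contrast multipliers must be > 0")
    if (f$radius_mm <= max(spacing)) stop("tumor radii must exceed one voxel")
    if (f$margin_mm < 0 || f$margin_contrast <= 0)
      stop("focus margin parameters must be nonnegative")
  }
  if (!any(vapply(tumor_foci, function(f) f$contrast, 0) > btv_ratio))
    stop(sprintf("at least one focus must have contrast > %.2f so a BTV exists", btv_ratio))
  for (s in extratumoral_sources) {
    if (s$contrast <= 0) stop("extratumoral contrast multipliers must be > 0")
    if (s$radius_mm <= max(spacing)) stop("extratumoral radii must exceed one voxel")
  }
  if (!is.null(cavity) && cavity$uptake_fraction >= 1)
    stop("cavity uptake_fraction must be < 1")
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 background_uptake = background_uptake,
                 tumor_foci = tumor_foci, cavity = cavity,
                 extratumoral_sources = extratumoral_sources,
                 noise_sd = noise_sd, psf_fwhm_mm = psf_fwhm_mm,
                 focus_peaking = focus_peaking,
                 seed = as.integer(seed),
                 roi_volume_ml = roi_volume_ml, btv_ratio = btv_ratio),
            class = "phantom_spec")
}

# Relative semi-axes of the brain ellipsoid (fraction of grid extent).
BRAIN_SEMIAXES_FRAC <- c(0.32, 0.38, 0.30)
SKULL_THICKNESS_FRAC <- 1.10

# Squared normalized ellipsoid radius u^2 = sum(((w - c)/semi)^2) on the grid.
ellipsoid_u2 <- function(template, center_mm, semi_mm) {
  d <- dim(template$values)
  wx <- (axis_world(template, 1) - center_mm[1]) / semi_mm[1]
  wy <- (axis_world(template, 2) - center_mm[2]) / semi_mm[2]
  wz <- (axis_world(template, 3) - center_mm[3]) / semi_mm[3]
  outer(outer(wx^2, wy^2, `+`), wz^2, `+`)
}

# Squared world distance (mm^2) from every voxel center to a point.
dist2_to_point <- function(template, point_mm) {
  wx <- axis_world(template, 1) - point_mm[1]
  wy <- axis_world(template, 2) - point_mm[2]
  wz <- axis_world(template, 3) - point_mm[3]
  outer(outer(wx^2, wy^2, `+`), wz^2, `+`)
}

#' Generate a synthetic phantom scene
#'
#' Builds the noiseless ground-truth activity volume and all masks from a
#' [phantom_spec]. The brain is an axis-aligned ellipsoid; the skull a thin
#' shell around it. Ground-truth tumor voxels are focus voxels whose
#' noiseless activity exceeds `btv_ratio` x background. The background ROI
#' is a curved slab ("banana") in the hemisphere contralateral to the first
#' focus, above the mid-axial plane, at least 15 mm away from every focus
#' surface, trimmed to approximately `roi_volume_ml`.
#'
#' Generation is fully deterministic given the spec (including its seed).
#'
#' @param spec A [phantom_spec].
#' @return A `phantom_scene`: `truth` (sharp noiseless activity),
#'   `pet_truth` (truth blurred to scanner resolution, the volume AC bias
#'   acts on) plus logical `brain_mask`,
#'   `skull_mask`, `tumor_truth_mask`, `exclusion_mask`,
#'   `background_roi_mask` (all [volume_image]s on the truth grid), an
#'   empty `biased` list to be filled by [apply_bias], and the spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  extent <- d * spec$spacing
  origin <- -(d - 1) / 2 * spec$spacing  # grid centered on the world origin
  template <- volume_image(array(0, d), spacing = spec$spacing, origin = origin)
  center_mm <- c(0, 0, 0)
  semi_mm <- BRAIN_SEMIAXES_FRAC * extent

  u2 <- ellipsoid_u2(template, center_mm, semi_mm)
  brain <- u2 <= 1
  skull <- (ellipsoid_u2(template, center_mm, semi_mm * SKULL_THICKNESS_FRAC) <= 1) & !brain

  bg <- spec$background_uptake
  truth <- array(0, d)
  truth[brain] <- bg

  in_focus <- array(FALSE, d)
  for (f in spec$tumor_foci) {
    cw <- voxel_to_world(template, f$center)
    d2 <- dist2_to_point(template, cw)
    sph <- (d2 <= f$radius_mm^2) & brain
    # parabolic hot core: contrast at the rim, contrast*(1+peaking) at center
    prof <- 1 + spec$focus_peaking * (1 - d2[sph] / f$radius_mm^2)
    truth[sph] <- f$contrast * bg * prof
    in_focus <- in_focus | sph
  }
  # infiltrative margins: only over plain background, never over foci
  for (f in spec$tumor_foci) {
    if (f$margin_mm <= 0) next
    cw <- voxel_to_world(template, f$center)
    d2 <- dist2_to_point(template, cw)
    rim <- (d2 <= (f$radius_mm + f$margin_mm)^2) & brain & !in_focus &
      (truth == bg)
    truth[rim] <- f$margin_contrast * bg
  }
  if (!is.null(spec$cavity)) {
    cw <- voxel_to_world(template, spec$cavity$center)
    cav <- (dist2_to_point(template, cw) <= spec$cavity$radius_mm^2) & brain
    truth[cav] <- spec$cavity$uptake_fraction * bg
  }
  exclusion <- array(FALSE, d)
  for (s in spec$extratumoral_sources) {
    cw <- voxel_to_world(template, s$center)
    sph <- (dist2_to_point(template, cw) <= s$radius_mm^2) & !brain
    truth[sph] <- s$contrast * bg
    exclusion <- exclusion | sph
  }

  tumor <- in_focus & (truth > spec$btv_ratio * bg)
  vox_ml <- prod(spec$spacing) / 1000
  if (sum(tumor) * vox_ml < 1)
    stop(sprintf("ground-truth BTV is %.2f mL; phantoms below 1 mL are rejected",
                 sum(tumor) * vox_ml))

  # Background ROI: contralateral curved slab above the mid-axial plane.
  f1w <- voxel_to_world(template, spec$tumor_foci[[1]]$center)
  side <- if (f1w[1] >= center_mm[1]) -1 else 1
  wx <- axis_world(template, 1)
  wz <- axis_world(template, 3)
  hemi <- array(rep(side * (wx - center_mm[1]) > 0.05 * extent[1], times = d[2] * d[3]), d)
  above <- array(rep(wz > center_mm[3], each = d[1] * d[2]), d)
  u <- sqrt(u2)
  slab <- brain & hemi & above & u >= 0.45 & u <= 0.80
  far <- array(TRUE, d)
  for (f in spec$tumor_foci) {
    cw <- voxel_to_world(template, f$center)
    far <- far & (dist2_to_point(template, cw) > (f$radius_mm + 15)^2)
  }
  cand <- which(slab & far & !tumor)
  n_target <- max(1L, round(spec$roi_volume_ml / vox_ml))
  if (length(cand) * vox_ml < 2)
    stop("background ROI cannot be placed: fewer than 2 mL of eligible contralateral voxels")
  ord <- order(abs(u[cand] - 0.625), cand)       # mid-slab first; deterministic
  roi <- array(FALSE, d)
  roi[cand[ord[seq_len(min(n_target, length(cand)))]]] <- TRUE

  as_mask <- function(m) volume_image(m, spacing = spec$spacing, origin = origin)
  truth_vol <- volume_image(truth, spacing = spec$spacing, origin = origin)
  pet_truth <- if (spec$psf_fwhm_mm > 0)
    gaussian_smooth(truth_vol, spec$psf_fwhm_mm) else truth_vol
  structure(list(
    truth = truth_vol,
    pet_truth = pet_truth,
    brain_mask = as_mask(brain),
    skull_mask = as_mask(skull),
    tumor_truth_mask = as_mask(tumor),
    exclusion_mask = as_mask(exclusion),
    background_roi_mask = as_mask(roi),
    biased = list(),
    spec = spec), class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %s voxels @ %s mm\n",
              paste(dim(x$truth$values), collapse = "x"),
              paste(format(x$truth$spacing), collapse = "x")))
  cat(sprintf("  truth BTV %.2f mL, background ROI %.2f mL, %d biased image(s): %s\n",
              mask_volume_ml(x$tumor_truth_mask),
              mask_volume_ml(x$background_roi_mask),
              length(x$biased), paste(names(x$biased), collapse = ", ")))
  invisible(x)
}

#' Multiplicative attenuation-correction bias model
#'
#' Parameterizes the spatial error structure of an AC method as a strictly
#' positive multiplicative field over the PET volume: a global scale, a
#' radial gradient from the brain surface toward its center, Gaussian
#' nodular warps, and spherical signal-void depressions. With all
#' parameters at identity the field is 1 everywhere.
#'
#' @param global_scale Unitless global multiplier (1 = no global error).
#' @param gradient_surface,gradient_center Relative error at the brain
#'   surface (depth 0) and at the deepest brain voxel (depth 1); the
#'   gradient interpolates linearly in normalized depth.
#' @param nodules List of `list(center` (voxel triple)`, fwhm_mm,
#'   amplitude)` Gaussian bumps.
#' @param voids List of `list(center, radius_mm, amplitude)` spherical
#'   multiplicative depressions (amplitude typically negative).
#' @param seed Optional integer recorded with the model (drawing models
#'   from cohort profiles is seeded; field construction is deterministic).
#' @return A `bias_field_model`.
#' @export
bias_field_model <- function(global_scale = 1, gradient_surface = 0,
                             gradient_center = 0, nodules = list(),
                             voids = list(), seed = NULL) {
  if (global_scale <= 0) stop("global_scale must be > 0")
  structure(list(global_scale = global_scale,
                 gradient_surface = gradient_surface,
                 gradient_center = gradient_center,
                 nodules = nodules, voids = voids, seed = seed),
            class = "bias_field_model")
}

#' Realize a bias model as a multiplicative field
#'
#' Inside the brain the field is
#' `global_scale * (1 + g(depth)) * prod(nodule terms) * prod(void terms)`,
#' where depth is the Euclidean distance to the brain edge normalized to
#' \[0, 1\] over brain voxels and `g` interpolates linearly from
#' `gradient_surface` to `gradient_center`. Outside the brain the field
#' equals `global_scale`. Any nonpositive field value aborts generation.
#'
#' @param model A [bias_field_model].
#' @param brain_mask Logical [volume_image] of the brain.
#' @return A [volume_image] holding the strictly positive field.
#' @export
make_bias_field <- function(model, brain_mask) {
  stopifnot(inherits(model, "bias_field_model"),
            inherits(brain_mask, "volume_image"))
  if (!any(brain_mask$values)) stop("brain_mask is empty")
  d <- dim(brain_mask$values)
  inb <- brain_mask$values

  edt <- distance_to_edge(brain_mask)
  dmin <- min(edt[inb]); dmax <- max(edt[inb])
  depth <- array(0, d)
  if (dmax > dmin) depth[inb] <- (edt[inb] - dmin) / (dmax - dmin)

  g <- model$gradient_surface +
    (model$gradient_center - model$gradient_surface) * depth
  field <- array(model$global_scale, d)
  field[inb] <- model$global_scale * (1 + g[inb])

  for (nd in model$nodules) {
    cw <- voxel_to_world(brain_mask, nd$center)
    sigma <- nd$fwhm_mm / (2 * sqrt(2 * log(2)))
    term <- 1 + nd$amplitude * exp(-dist2_to_point(brain_mask, cw) / (2 * sigma^2))
    field[inb] <- field[inb] * term[inb]
  }
  for (vd in model$voids) {
    cw <- voxel_to_world(brain_mask, vd$center)
    inside <- dist2_to_point(brain_mask, cw) <= vd$radius_mm^2
    field[inb & inside] <- field[inb & inside] * (1 + vd$amplitude)
  }
  if (any(field <= 0))
    stop("bias field has nonpositive values; generation aborted")
  volume_image(field, spacing = brain_mask$spacing, origin = brain_mask$origin)
}

#' Apply a multiplicative bias field with relative noise
#'
#' `output = truth * field * (1 + eps)` with `eps ~ Normal(0, noise_sd)`
#' i.i.d. per voxel; `noise_sd = 0` gives the exact product. Negative
#' outputs are clipped to zero and their count attached as attribute
#' `n_clipped` (with a message).
#'
#' @param truth,field Grid-compatible [volume_image]s.
#' @param noise_sd Relative noise SD (>= 0).
#' @param seed Optional integer; when given, noise is drawn under this seed
#'   without disturbing the caller's RNG state.
#' @return A [volume_image] of biased activity.
#' @export
apply_bias <- function(truth, field, noise_sd = 0, seed = NULL) {
  stop_if_grid_mismatch(truth, field, "truth and bias field")
  vals <- truth$values * field$values
  if (noise_sd > 0) {
    draw <- function() array(rnorm(length(vals), 0, noise_sd), dim(vals))
    eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
    vals <- vals * (1 + eps)
  }
  n_clipped <- sum(vals < 0)
  if (n_clipped > 0) {
    message(sprintf("apply_bias: clipped %d negative voxel(s) to 0", n_clipped))
    vals[vals < 0] <- 0
  }
  out <- volume_image(vals, spacing = truth$spacing, origin = truth$origin)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Derive a follow-up scene from a baseline scene
#'
#' Rescales every focus radius by `(1 + btv_change_pct/100)^(1/3)` and every
#' focus contrast by `(1 + tbr_change_pct/100)`, so the noiseless
#' ground-truth BTV and T_MAX/B change by the requested percentages, then
#' regenerates the scene with everything else held fixed.
#'
#' @param scene A `phantom_scene` with at least one tumor focus.
#' @param btv_change_pct,tbr_change_pct Requested percent changes of the
#'   ground-truth BTV and T_MAX/B.
#' @param seed Optional replacement seed for the follow-up spec.
#' @return A `phantom_scene` for the second timepoint. Shrinkage of the
#'   ground-truth BTV below 1 mL is rejected.
#' @export
make_followup <- function(scene, btv_change_pct = 0, tbr_change_pct = 0,
                          seed = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  spec <- scene$spec
  if (length(spec$tumor_foci) == 0) stop("scene has no tumor focus")
  rscale <- (1 + btv_change_pct / 100)^(1 / 3)
  if (!is.finite(rscale) || rscale <= 0)
    stop("btv_change_pct must keep the volume positive")
  spec$tumor_foci <- lapply(spec$tumor_foci, function(f) {
    f$radius_mm <- f$radius_mm * rscale
    f$contrast <- f$contrast * (1 + tbr_change_pct / 100)
    f
  })
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  out <- tryCatch(generate_phantom(spec), error = function(e)
    stop("follow-up generation rejected: ", conditionMessage(e), call. = FALSE))
  out
}
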