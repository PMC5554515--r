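test_that("ground-truth tumor mask reproduces the analytic sphere volume", {
  r <- 10
  spec <- small_spec(radius_mm = r)
  sc <- generate_phantom(spec)
  # independent voxel count from world coordinates
  center_mm <- (spec$tumor_foci[[1]]$center - 1) * spec$spacing +
    sc$truth$origin
  want <- sphere_mask(sc$truth, center_mm, r)
  expect_identical(sc$tumor_truth_mask$values, want$values & sc$brain_mask$values)
  analytic_ml <- 4 / 3 * pi * r^3 / 1000
  shell_ml <- 4 * pi * r^2 * max(spec$spacing) / 1000  # one-voxel shell
  expect_lt(abs(mask_volume_ml(sc$tumor_truth_mask) - analytic_ml), shell_ml)
})

test_that("phantoms without a usable tumor focus are rejected", {
  expect_error(phantom_spec(tumor_foci = list()), "at least one tumor focus")
  expect_error(phantom_spec(tumor_foci = list(
    list(center = c(64, 64, 64), radius_mm = 10, contrast = 1.5))),
    "contrast")
  # shrinking the only focus below 1 mL is caught at generation
  tiny <- small_spec(radius_mm = 6.5)
  expect_error(generate_phantom({
    s <- tiny; s$tumor_foci[[1]]$radius_mm <- 2.5; s
  }), "1 mL")
})

test_that("generation is bit-identical for identical spec and seed", {
  spec <- small_spec(noise_sd = 0.05)
  expect_identical(generate_phantom(spec), generate_phantom(spec))
  recs1 <- generate_cohort(2, list(CTAC = method_profile("CTAC")),
                           seed = 5, base_spec = spec)
  recs2 <- generate_cohort(2, list(CTAC = method_profile("CTAC")),
                           seed = 5, base_spec = spec)
  expect_identical(recs1, recs2)
})

test_that("scene mask algebra invariants hold on random specs", {
  set.seed(46)
  for (case in 1:25) {
    grid <- c(48, 48, 48)
    spec <- phantom_spec(
      grid_shape = grid, spacing = c(2, 2, 2),
      tumor_foci = list(list(
        center = c(runif(1, 0.58, 0.68), runif(1, 0.45, 0.55),
                   runif(1, 0.45, 0.55)) * grid,
        radius_mm = runif(1, 8, 14), contrast = runif(1, 2, 4),
        margin_mm = runif(1, 0, 8))),
      extratumoral_sources = if (runif(1) < 0.5)
        list(list(center = c(0.5, 0.12, 0.5) * grid, radius_mm = 6,
                  contrast = 3)) else list(),
      roi_volume_ml = runif(1, 8, 15))
    sc <- generate_phantom(spec)
    roi <- sc$background_roi_mask$values
    expect_false(any(roi & sc$tumor_truth_mask$values))
    expect_true(all(sc$brain_mask$values[roi]))
    expect_false(any(sc$exclusion_mask$values & sc$brain_mask$values))
    for (m in c("brain_mask", "skull_mask", "tumor_truth_mask",
                "exclusion_mask", "background_roi_mask"))
      expect_true(same_grid(sc[[m]], sc$truth))
  }
})

test_that("bias field follows its closed form", {
  sc <- generate_phantom(small_spec())
  inb <- sc$brain_mask$values

  # identity model: field is exactly 1 everywhere
  f0 <- make_bias_field(bias_field_model(), sc$brain_mask)
  expect_true(all(f0$values == 1))

  # linear ramp endpoints: surface voxel -15%, deepest voxel -5%
  fg <- make_bias_field(
    bias_field_model(gradient_surface = -0.15, gradient_center = -0.05),
    sc$brain_mask)
  edt <- distance_to_edge(sc$brain_mask)
  expect_equal(fg$values[inb][which.min(edt[inb])], 0.85, tolerance = 1e-6)
  expect_equal(fg$values[inb][which.max(edt[inb])], 0.95, tolerance = 1e-6)

  # Gaussian nodule: value at its (integer) center voxel matches the
  # closed form exactly
  center <- c(31, 24, 24)
  fn <- make_bias_field(
    bias_field_model(gradient_surface = -0.15, gradient_center = -0.05,
                     nodules = list(list(center = center, fwhm_mm = 10,
                                         amplitude = 0.10))),
    sc$brain_mask)
  idx <- center
  depth_c <- (edt[idx[1], idx[2], idx[3]] - min(edt[inb])) /
    (max(edt[inb]) - min(edt[inb]))
  g_c <- -0.15 + (-0.05 - -0.15) * depth_c
  expect_equal(fn$values[idx[1], idx[2], idx[3]], (1 + g_c) * 1.10,
               tolerance = 1e-9)
  expect_equal(max(fn$values / fg$values), 1.10, tolerance = 1e-9)

  # nonpositive fields abort
  expect_error(make_bias_field(
    bias_field_model(voids = list(list(center = center, radius_mm = 8,
                                       amplitude = -1.5))),
    sc$brain_mask), "nonpositive")
})

test_that("apply_bias composes truth, field and noise as stated", {
  sc <- generate_phantom(small_spec())
  ident <- make_bias_field(bias_field_model(), sc$brain_mask)
  expect_identical(apply_bias(sc$pet_truth, ident, 0)$values,
                   sc$pet_truth$values)

  flat <- volume_image(array(0.851, dim(sc$truth$values)),
                       sc$truth$spacing, sc$truth$origin)
  expect_equal(apply_bias(sc$truth, flat, 0)$values,
               sc$truth$values * 0.851, tolerance = 0)

  # law of large numbers on the relative noise SD (>= 1e5 brain voxels)
  big <- generate_phantom(small_spec(grid = c(96, 96, 96)))
  ident_big <- make_bias_field(bias_field_model(), big$brain_mask)
  biased <- apply_bias(big$truth, ident_big, noise_sd = 0.05, seed = 99)
  inb_big <- big$brain_mask$values & big$truth$values > 0
  expect_gte(sum(inb_big), 1e5)
  rel <- biased$values[inb_big] / big$truth$values[inb_big] - 1
  expect_gte(sd(rel), 0.048)
  expect_lte(sd(rel), 0.052)
  # seeded noise is reproducible and does not disturb the caller RNG
  expect_identical(biased$values,
                   apply_bias(big$truth, ident_big, 0.05, seed = 99)$values)

  # negative draws are clipped to zero with a reported count
  expect_message(
    clipped <- apply_bias(sc$truth, ident, noise_sd = 1.0, seed = 7),
    "clipped")
  expect_gt(attr(clipped, "n_clipped"), 0)
  expect_true(all(clipped$values >= 0))
})

test_that("follow-up scenes change ground truth by the requested percentages", {
  sc <- generate_phantom(small_spec())
  same <- make_followup(sc, 0, 0)
  expect_identical(same$truth$values, sc$truth$values)
  expect_identical(same$tumor_truth_mask$values, sc$tumor_truth_mask$values)

  grown <- make_followup(sc, btv_change_pct = 20)
  ratio <- sum(grown$tumor_truth_mask$values) / sum(sc$tumor_truth_mask$values)
  expect_gte(ratio, 1.18)
  expect_lte(ratio, 1.22)
  # T_MAX ground truth scales with the contrast rescaling
  tbr <- make_followup(sc, 0, tbr_change_pct = -10)
  expect_equal(max(tbr$truth$values) / max(sc$truth$values), 0.9,
               tolerance = 1e-12)

  small2 <- generate_phantom(small_spec(radius_mm = 7.8))  # about 2 mL
  expect_lt(mask_volume_ml(small2$tumor_truth_mask), 2.6)
  expect_error(make_followup(small2, btv_change_pct = -99), "rejected")
})

test_that("cohort generation reproduces injected parameter distributions", {
  prof <- list(CTAC = method_profile("CTAC"),
               RESOLUTE = method_profile("RESOLUTE", global_mean = -0.019,
                                         global_sd = 0.019,
                                         global_max = 0.076))
  recs <- generate_cohort(50, prof, seed = 123, base_spec = small_spec(),
                          vary_geometry = FALSE)
  injected <- vapply(recs, function(r) r$injected$RESOLUTE$global_scale - 1, 0)
  expect_lt(abs(mean(injected) - (-0.019)), 0.006)
  expect_true(all(abs(injected) <= 0.076))

  # identity profile: biased image equals the imaged truth exactly (noise 0)
  rec1 <- generate_cohort(1, list(CTAC = method_profile("CTAC")), seed = 3,
                          base_spec = small_spec())[[1]]
  expect_identical(rec1$scene$biased$CTAC$values, rec1$scene$pet_truth$values)

  # deterministic follow-up count
  recs2 <- generate_cohort(10, list(CTAC = method_profile("CTAC")),
                           followup_fraction = 0.2, seed = 9,
                           base_spec = small_spec())
  expect_length(recs2, 12)
  expect_equal(sum(vapply(recs2, `[[`, 0L, "timepoint") == 2L), 2L)
})

test_that("noiseless delineation recovers the injected global scale", {
  sc <- generate_phantom(small_spec())
  for (scale in c(0.85, 0.92, 0.981)) {
    field <- make_bias_field(bias_field_model(global_scale = scale),
                             sc$brain_mask)
    biased <- apply_bias(sc$pet_truth, field, 0)
    dref <- delineate_btv(sc$pet_truth,
                          background_mean(sc$pet_truth, sc$background_roi_mask),
                          sc$exclusion_mask, sc$tumor_truth_mask)
    dtest <- delineate_btv(biased,
                           background_mean(biased, sc$background_roi_mask),
                           sc$exclusion_mask, sc$tumor_truth_mask)
    rel_err <- 100 * (dtest$t_mean - dref$t_mean) / dref$t_mean
    expect_lt(abs(rel_err - 100 * (scale - 1)), 0.5)
    # a pure global scale moves no mask voxel
    expect_identical(dtest$mask$values, dref$mask$values)
  }
})
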