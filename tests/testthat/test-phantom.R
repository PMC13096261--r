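test_that("voxel grid validates inputs and computes voxel volume", {
  g <- voxel_grid(c(96, 96, 96), 4)
  expect_equal(voxel_volume_ml(g), 0.064)
  expect_error(voxel_grid(c(0, 4, 4), 4), "positive")
  expect_error(voxel_grid(c(4, 4, 4), c(4, -1, 4)), "positive")
})

test_that("sphere rasterisation matches the brute-force voxel-centre count", {
  g <- voxel_grid(c(24, 24, 24), 4)
  ctr <- c(46, 46, 46)
  spec <- phantom_spec(g, list(phantom_organ("lesion_1", ctr, 10)),
                       psf_fwhm_mm = 0)
  anat <- build_anatomy(spec)
  expect_equal(sum(anat$labels == anat$legend[["lesion_1"]]),
               sphere_count_oracle(g, ctr, 10))
})

test_that("empty organ list gives an all-background volume", {
  g <- voxel_grid(c(8, 8, 8), 4)
  anat <- build_anatomy(phantom_spec(g, list()))
  expect_true(all(anat$labels == 0L))
  expect_identical(anat$legend, c(background = 0L))
})

test_that("default anatomy has parenchyma, pelvis and cysts in both kidneys", {
  spec <- default_phantom_spec()
  anat <- build_anatomy(spec)
  nm <- names(anat$legend)
  expect_true(all(c("kidney_parenchyma_L", "kidney_parenchyma_R",
                    "renal_pelvis_L", "renal_pelvis_R") %in% nm))
  expect_gte(length(grep("^cyst_", nm)), 2L)
  # every declared region survives carving
  expect_true(all(anat$legend[-1] %in% unique(as.vector(anat$labels))))
})

test_that("organs outside the grid raise a geometry error", {
  g <- voxel_grid(c(16, 16, 16), 4)
  spec <- phantom_spec(g, list(phantom_organ("lesion_1", c(60, 30, 30), 10)))
  expect_error(build_anatomy(spec), "outside the grid")
})

test_that("labels are disjoint: region counts sum to nonzero-label count", {
  anat <- mini_phantom()$anatomy
  counts <- vapply(names(anat$legend)[-1],
                   function(r) sum(region_mask(anat, r)), numeric(1))
  expect_equal(sum(counts), sum(anat$labels != 0L))
})

test_that("unblurred noiseless concentrations equal the closed-form kinetics", {
  spec <- mini_spec(psf_fwhm_mm = 0)
  anat <- build_anatomy(spec)
  ser <- make_activity_series(anat, spec)
  for (k in seq_along(ser$times_h)) {
    t <- ser$times_h[k]
    for (r in c("liver", "lesion_1", "kidney_parenchyma_R", "cyst_extra_R")) {
      kin <- spec$kinetics[[r]]
      expect_equal(unique(ser$volumes[[k]][region_mask(anat, r)]),
                   kin$C0 * exp(-kin$lambda_eff * t),
                   tolerance = 1e-12, info = paste(r, t))
    }
  }
})

test_that("PSF blur conserves total activity away from the grid edge", {
  # single interior sphere, > 3 FWHM from every face
  g <- voxel_grid(c(48, 48, 48), 4)
  kin <- default_kinetics()
  kin$background <- kinetic_params(0, 0.02)  # edge-touching background off
  spec0 <- phantom_spec(g, list(phantom_organ("lesion_1", c(94, 94, 94), 14)),
                        kinetics = kin, psf_fwhm_mm = 0)
  spec1 <- phantom_spec(g, list(phantom_organ("lesion_1", c(94, 94, 94), 14)),
                        kinetics = kin, psf_fwhm_mm = 12)
  anat <- build_anatomy(spec0)
  s0 <- make_activity_series(anat, spec0)
  s1 <- make_activity_series(anat, spec1)
  tot0 <- sum(s0$volumes[[1]]) * voxel_volume_ml(g)
  tot1 <- sum(s1$volumes[[1]]) * voxel_volume_ml(g)
  expect_lt(abs(tot1 - tot0) / tot0, 0.005)
})

test_that("maximum voxel value is non-increasing in PSF FWHM", {
  g <- voxel_grid(c(32, 32, 32), 4)
  organs <- list(phantom_organ("lesion_1", c(62, 62, 62), 12))
  maxima <- vapply(c(0, 6, 12, 18), function(fw) {
    spec <- phantom_spec(g, organs, psf_fwhm_mm = fw)
    max(make_activity_series(build_anatomy(spec), spec)$volumes[[1]])
  }, numeric(1))
  expect_true(all(diff(maxima) <= 1e-12))
})

test_that("identical spec and seed reproduce anatomy and series exactly", {
  spec <- mini_spec(seed = 99, noise_model = "poisson_like")
  a1 <- build_anatomy(spec); a2 <- build_anatomy(spec)
  expect_identical(a1$labels, a2$labels)
  s1 <- make_activity_series(a1, spec)
  s2 <- make_activity_series(a2, spec)
  expect_identical(s1$volumes, s2$volumes)
  # a different seed changes the noise realisation
  s3 <- make_activity_series(a1, mini_spec(seed = 100,
                                           noise_model = "poisson_like"))
  expect_false(identical(s1$volumes, s3$volumes))
})

test_that("missing kinetics for a labelled region is a configuration error", {
  spec <- mini_spec()
  spec$kinetics$cyst_extra_R <- NULL
  anat <- build_anatomy(spec)
  expect_error(make_activity_series(anat, spec), "cyst_extra_R")
})

test_that("true_voi bundles mirror the kidney VOI scenarios", {
  anat <- mini_phantom()$anatomy
  ref <- true_voi(anat, "refined_reference")
  pel <- true_voi(anat, "reference_plus_pelvis")
  cys <- true_voi(anat, "reference_plus_cysts")
  expect_gt(voi_volume_ml(pel), voi_volume_ml(ref))
  expect_gt(voi_volume_ml(cys), voi_volume_ml(ref))
  # disjoint labels: union volume equals sum of member volumes
  vols <- vapply(c("kidney_parenchyma_R", "renal_pelvis_R"),
                 function(r) voi_volume_ml(true_voi(anat, r)), numeric(1))
  expect_equal(voi_volume_ml(pel), sum(vols))
  # empty region set, unknown names
  expect_equal(voi_volume_ml(true_voi(anat, character(0))), 0)
  expect_error(true_voi(anat, "gallbladder"), "unknown region")
})
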