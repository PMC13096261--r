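test_that("VOI scenarios reproduce the cold-structure dose mechanism", {
  ph <- mini_phantom()
  rep <- run_voi_scenarios(ph$series, ph$anatomy,
                           injected_activity_MBq = 7210, sides = "R")
  ref <- rep[rep$scenario == "refined_reference", ]
  expect_equal(ref$pct_diff_volume, 0)
  expect_equal(ref$pct_diff_dose, 0)
  pel <- rep[rep$scenario == "plus_pelvis", ]
  cys <- rep[rep$scenario == "plus_cysts", ]
  # adding a (late-time) cold structure inflates mass more than TIAC,
  # so the absorbed dose drops
  for (row in list(pel, cys)) {
    expect_gt(row$pct_diff_volume, row$pct_diff_tiac)
    expect_lt(row$pct_diff_dose, 0)
  }
  expect_lt(pel$dose_Gy, cys$dose_Gy)
  expect_lt(cys$dose_Gy, ref$dose_Gy)
})

test_that("scenarios lacking a structure are skipped with a warning", {
  grid <- voxel_grid(c(32, 32, 32), 4)
  spec <- phantom_spec(grid, list(
    phantom_organ("kidney_parenchyma_R", c(62, 62, 62), c(24, 20, 30))))
  anat <- build_anatomy(spec)
  ser <- make_activity_series(anat, spec)
  expect_warning(expect_warning(
    rep <- run_voi_scenarios(ser, anat, sides = "R"),
    "pelvis"), "cyst")
  expect_identical(rep$scenario, "refined_reference")
})

test_that("threshold sweep covers the full factorial and its dose trends", {
  ph <- mini_phantom()
  thr <- seq(0.10, 0.75, by = 0.05)
  sw <- run_threshold_sweep(ph$series, ph$anatomy, thresholds = thr)
  expect_equal(nrow(sw), length(thr) * 2 * 2)  # one lesion
  expect_setequal(unique(sw$strategy), c("independent", "propagated"))
  expect_setequal(unique(sw$mass_strategy), c("ct_constant", "spect_variable"))
  ok <- sw[!sw$flagged, ]
  # constant CT mass: dose non-increasing in threshold (activity shrinks)
  for (strat in c("independent", "propagated")) {
    cc <- ok[ok$strategy == strat & ok$mass_strategy == "ct_constant", ]
    cc <- cc[order(cc$threshold_fraction), ]
    expect_true(all(diff(cc$dose_Gy) <= 1e-9), info = strat)
    # variable SPECT mass: dose non-decreasing over low-to-mid thresholds
    sv <- ok[ok$strategy == strat & ok$mass_strategy == "spect_variable" &
               ok$threshold_fraction <= 0.45, ]
    sv <- sv[order(sv$threshold_fraction), ]
    expect_true(all(diff(sv$dose_Gy) >= -1e-9), info = strat)
  }
  # where SPECT volume matches the CT reference volume, strategies agree
  ct_vol <- voi_volume_ml(true_voi(ph$anatomy, "lesion_1"))
  ok$mean_vol <- rowMeans(ok[, grep("^vol_t", names(ok))])
  ind <- ok[ok$strategy == "independent", ]
  close <- ind[which.min(abs(ind$mean_vol - ct_vol)), ]
  other <- ind[ind$threshold_fraction == close$threshold_fraction &
                 ind$mass_strategy != close$mass_strategy, ]
  if (abs(close$mean_vol - ct_vol) / ct_vol < 0.01)
    expect_lt(abs(close$dose_Gy - other$dose_Gy) / other$dose_Gy, 0.01)
})

test_that("propagated VOIs keep the time-2 voxel count at every time point", {
  ph <- mini_phantom()
  sw <- run_threshold_sweep(ph$series, ph$anatomy, thresholds = c(0.3, 0.5))
  pr <- sw[sw$strategy == "propagated" & !sw$flagged, ]
  vol_cols <- grep("^vol_t", names(pr))
  for (r in seq_len(nrow(pr)))
    expect_equal(unname(unlist(pr[r, vol_cols])),
                 rep(pr$vol_t2_ml[r], length(vol_cols)))
})

test_that("cohort simulation is deterministic and honours degenerate configs", {
  ph <- mini_phantom()
  cfg <- cohort_sim_config(n_participants = 8, seed = 21)
  c1 <- simulate_cohort(cfg, ph$series, ph$anatomy,
                        regions = c("kidney_R", "lesion_1"))
  c2 <- simulate_cohort(cfg, ph$series, ph$anatomy,
                        regions = c("kidney_R", "lesion_1"))
  expect_identical(c1, c2)
  expect_true(all(c1$dose_Gy > 0))
  expect_true(all(!is.na(c1$voi_format[c1$task == "task4"])))
  expect_error(cohort_sim_config(n_participants = 2), "n_participants")
  expect_error(cohort_sim_config(organ_method_mix = c(manual = 0.5)),
               "sum to 1")
})

test_that("an all-reference cohort shows zero segmentation variability", {
  ph <- mini_phantom()
  cfg <- cohort_sim_config(
    n_participants = 6,
    organ_method_mix = c(manual = 0, threshold = 0, threshold_manual = 0,
                         sphere = 0, semi_automatic = 0, ai = 1, atlas = 0),
    pelvis_exclusion_prob = 1, cyst_full_inclusion_prob = 0,
    cyst_partial_inclusion_prob = 0, rtstruct_prob = 0, seed = 3)
  coh <- simulate_cohort(cfg, ph$series, ph$anatomy, regions = "kidney_R")
  s <- summarize_cohort(coh)
  expect_equal(s$summary$QCD_difference, 0)
  expect_equal(s$summary$median_delta_pct, 0)
  expect_equal(s$summary$IQR_delta_pct, 0)
})

test_that("wider threshold ranges inflate lesion dose dispersion", {
  ph <- mini_phantom()
  lesion_mix <- c(manual = 0, threshold = 1, threshold_manual = 0,
                  sphere = 0, semi_automatic = 0, gradient = 0)
  qcd_for <- function(range, seed) {
    cfg <- cohort_sim_config(n_participants = 9, lesion_method_mix = lesion_mix,
                             lesion_threshold_range = range, seed = seed)
    coh <- simulate_cohort(cfg, ph$series, ph$anatomy, regions = "lesion_1")
    summarize_cohort(coh)$summary$QCD_task1
  }
  seeds <- 101:120
  wide <- vapply(seeds, function(s) qcd_for(c(0.11, 0.75), s), numeric(1))
  narrow <- vapply(seeds, function(s) qcd_for(c(0.40, 0.45), s), numeric(1))
  expect_gt(mean(wide), mean(narrow))
  expect_gt(mean(wide > narrow), 0.8)  # paired, same seeds
})
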