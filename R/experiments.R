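#' Kidney VOI scenario analysis
#'
#' Runs the identical dosimetry chain (activity recovery, mono-exponential
#' fit, TIAC, local-deposition dose with mass from the VOI volume at unit
#' density) over three kidney VOI scenarios -- functional parenchyma only
#' (refined reference), parenchyma plus renal pelvis, parenchyma plus all
#' cysts -- and reports each metric with its percent difference from the
#' refined reference. Only the segmentation differs between rows.
#'
#' @param series an `activity_series` from [make_activity_series()].
#' @param anatomy the matching `label_volume`.
#' @param injected_activity_MBq administered activity, MBq.
#' @param dose_factor see [absorbed_dose()].
#' @param sides kidneys to analyse (default both, where present).
#' @return data.frame with one row per kidney x scenario: `volume_ml`,
#'   `tiac_h`, `dose_Gy` and `pct_diff_*` columns (0 for the reference row).
#'   Kidneys missing a pelvis or cyst skip the affected scenario with a
#'   warning.
#' @export
run_voi_scenarios <- function(series, anatomy, injected_activity_MBq = 7210,
                              dose_factor = LU177_ELECTRON_DOSE_FACTOR,
                              sides = c("R", "L")) {
  stopifnot(inherits(series, "activity_series"),
            inherits(anatomy, "label_volume"))
  rows <- list()
  for (side in sides) {
    par <- region_names(anatomy, paste0("^kidney_parenchyma_", side, "$"))
    if (!length(par)) next
    scen <- list(refined_reference = "refined_reference",
                 plus_pelvis = "reference_plus_pelvis",
                 plus_cysts = "reference_plus_cysts")
    has_pelvis <- length(region_names(anatomy, paste0("^renal_pelvis_", side, "$"))) > 0
    has_cyst <- length(region_names(anatomy, paste0("^cyst_.*_", side, "$"))) > 0
    if (!has_pelvis) {
      warning(sprintf("kidney %s has no pelvis; scenario skipped", side),
              call. = FALSE)
      scen$plus_pelvis <- NULL
    }
    if (!has_cyst) {
      warning(sprintf("kidney %s has no cysts; scenario skipped", side),
              call. = FALSE)
      scen$plus_cysts <- NULL
    }
    metrics <- lapply(scen, function(bundle) {
      voi <- true_voi(anatomy, bundle, side = side)
      tac <- measure_activity(series, voi, region = paste0("kidney_", side))
      fit <- fit_tac(tac)
      ti <- tiac(fit, injected_activity_MBq)
      mass <- estimate_mass(voi, "spect_variable", average = TRUE)$mass_g
      c(volume_ml = voi_volume_ml(voi), tiac_h = ti, mass_g = mass,
        dose_Gy = absorbed_dose(ti, injected_activity_MBq, mass, dose_factor))
    })
    ref <- metrics$refined_reference
    for (nm in names(metrics)) {
      m <- metrics[[nm]]
      rows[[paste(side, nm)]] <- data.frame(
        kidney = side, scenario = nm,
        volume_ml = m[["volume_ml"]], tiac_h = m[["tiac_h"]],
        mass_g = m[["mass_g"]], dose_Gy = m[["dose_Gy"]],
        pct_diff_volume = percent_difference(m[["volume_ml"]], ref[["volume_ml"]]),
        pct_diff_tiac = percent_difference(m[["tiac_h"]], ref[["tiac_h"]]),
        pct_diff_dose = percent_difference(m[["dose_Gy"]], ref[["dose_Gy"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || !nrow(out))
    stop("no kidney parenchyma present in anatomy", call. = FALSE)
  out
}

# default box-like search region around a lesion: its true VOI dilated to a
# sphere of (equivalent radius + margin) about the lesion centroid
lesion_search_region <- function(anatomy, lesion, margin_mm = 12) {
  mask <- region_mask(anatomy, lesion)
  idx <- which(mask)
  ctr <- colMeans(voxel_centers(anatomy$grid, idx))
  r_eq <- (3 * sum(mask) * voxel_volume_ml(anatomy$grid) * 1000 /
             (4 * pi))^(1 / 3)
  sphere_voi(ctr, r_eq + margin_mm, anatomy$grid)
}

#' Lesion threshold sweep
#'
#' Full factorial over percentage-of-maximum thresholds (default 10-75% in
#' 5% steps), two VOI strategies (independent thresholding per time point;
#' thresholding the second time point and propagating without reshaping --
#' backwards to the first time point as well) and two mass strategies
#' (constant CT-derived mass; variable SPECT-VOI mass, averaged over time
#' points), reporting TIAC and absorbed dose per combination.
#'
#' @param series an `activity_series`.
#' @param anatomy the matching `label_volume` (lesion regions are those whose
#'   name starts with `lesion`).
#' @param injected_activity_MBq administered activity, MBq.
#' @param thresholds threshold fractions; default `seq(0.10, 0.75, 0.05)`.
#' @param dose_factor see [absorbed_dose()].
#' @param search_margin_mm margin added to the lesion-equivalent radius for
#'   the threshold search region.
#' @return data.frame with one row per lesion x threshold x strategy x mass
#'   strategy: per-time volumes `vol_t*_ml`, `mass_g`, `tiac_h`, `dose_Gy`,
#'   `flagged` (TRUE when a threshold produced an empty/degenerate VOI; such
#'   rows carry NA metrics).
#' @export
run_threshold_sweep <- function(series, anatomy, injected_activity_MBq = 7210,
                                thresholds = seq(0.10, 0.75, by = 0.05),
                                dose_factor = LU177_ELECTRON_DOSE_FACTOR,
                                search_margin_mm = 12) {
  stopifnot(inherits(series, "activity_series"),
            inherits(anatomy, "label_volume"))
  lesions <- region_names(anatomy, "^lesion")
  if (!length(lesions)) stop("no lesions in anatomy", call. = FALSE)
  nt <- length(series$times_h)
  rows <- list()
  for (les in lesions) {
    search <- lesion_search_region(anatomy, les, search_margin_mm)
    ref_voi <- true_voi(anatomy, les)  # CT-based anatomical reference
    for (thr in thresholds) {
      for (strat in c("independent", "propagated")) {
        vois <- tryCatch({
          if (strat == "independent") {
            lapply(seq_len(nt), function(k)
              threshold_voi(series$volumes[[k]], thr, series$grid,
                            search_region = search))
          } else {
            src <- threshold_voi(series$volumes[[2]], thr, series$grid,
                                 search_region = search)
            src$source_time_index <- 2L
            lapply(seq_len(nt), function(k) {
              if (k == 2L) src
              else propagate_voi(src, series$volumes[[2]],
                                 series$volumes[[k]])
            })
          }
        }, error = function(e) NULL)
        for (mass_strat in c("ct_constant", "spect_variable")) {
          if (is.null(vois)) {
            rows[[length(rows) + 1L]] <- data.frame(
              lesion = les, threshold_fraction = thr, strategy = strat,
              mass_strategy = mass_strat,
              t(stats::setNames(rep(NA_real_, nt),
                                paste0("vol_t", seq_len(nt), "_ml"))),
              mass_g = NA_real_, tiac_h = NA_real_, dose_Gy = NA_real_,
              flagged = TRUE, stringsAsFactors = FALSE)
            next
          }
          vols <- vapply(vois, voi_volume_ml, numeric(1))
          metrics <- tryCatch({
            tac <- measure_activity(series, vois, region = les)
            fit <- fit_tac(tac)
            ti <- tiac(fit, injected_activity_MBq)
            mass <- if (mass_strat == "ct_constant")
              estimate_mass(vois, "ct_constant", reference_voi = ref_voi)$mass_g
            else
              estimate_mass(vois, "spect_variable", average = TRUE)$mass_g
            list(mass = mass, ti = ti,
                 dose = absorbed_dose(ti, injected_activity_MBq, mass,
                                      dose_factor))
          }, error = function(e) NULL)
          rows[[length(rows) + 1L]] <- data.frame(
            lesion = les, threshold_fraction = thr, strategy = strat,
            mass_strategy = mass_strat,
            t(stats::setNames(vols, paste0("vol_t", seq_len(nt), "_ml"))),
            mass_g = if (is.null(metrics)) NA_real_ else metrics$mass,
            tiac_h = if (is.null(metrics)) NA_real_ else metrics$ti,
            dose_Gy = if (is.null(metrics)) NA_real_ else metrics$dose,
            flagged = is.null(metrics), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Configuration for the synthetic submission cohort
#'
#' Parameters of the cohort simulator: how many synthetic participants, the
#' frequency of each segmentation method (defaults follow the observed
#' method mix in multi-centre Lu-177 dosimetry submissions: manual dominant
#' for organs, threshold dominant for lesions), how often the renal pelvis
#' is excluded (default 0.673) and cysts fully/partially included (defaults
#' 0.654 / 0.135), the lesion threshold range (default 0.11-0.75), and
#' perturbation magnitudes for the manual and sphere emulators (invented,
#' clearly-labelled knobs).
#'
#' @param n_participants number of synthetic participants (>= 3).
#' @param organ_method_mix,lesion_method_mix named probability vectors
#'   summing to 1.
#' @param pelvis_exclusion_prob probability a participant excludes the renal
#'   pelvis.
#' @param cyst_full_inclusion_prob,cyst_partial_inclusion_prob probabilities
#'   of including all cysts / only intraparenchymal cysts.
#' @param organ_threshold_range,lesion_threshold_range uniform threshold
#'   ranges.
#' @param sphere_radius_frac,sphere_radius_jitter sphere radius as a
#'   fraction of the region-equivalent radius, and its uniform jitter.
#' @param rtstruct_prob probability a participant uses the RTStruct-format
#'   task-4 VOI (vs binary mask).
#' @param seed integer RNG seed.
#' @return A `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_participants = 33L,
                              organ_method_mix = c(manual = 0.535,
                                                   threshold = 0.028,
                                                   threshold_manual = 0.151,
                                                   sphere = 0.116,
                                                   semi_automatic = 0.113,
                                                   ai = 0.047, atlas = 0.010),
                              lesion_method_mix = c(manual = 0.253,
                                                    threshold = 0.332,
                                                    threshold_manual = 0.155,
                                                    sphere = 0.091,
                                                    semi_automatic = 0.023,
                                                    gradient = 0.146),
                              pelvis_exclusion_prob = 0.673,
                              cyst_full_inclusion_prob = 0.654,
                              cyst_partial_inclusion_prob = 0.135,
                              organ_threshold_range = c(0.35, 0.45),
                              lesion_threshold_range = c(0.11, 0.75),
                              sphere_radius_frac = 0.5,
                              sphere_radius_jitter = 0.15,
                              rtstruct_prob = 0.5,
                              seed = 1L) {
  if (n_participants < 3L)
    stop("n_participants must be >= 3 (quartile statistics are meaningless below)",
         call. = FALSE)
  for (mix in list(organ_method_mix, lesion_method_mix)) {
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6)
      stop("method mix must be nonnegative and sum to 1", call. = FALSE)
  }
  probs <- c(pelvis_exclusion_prob, cyst_full_inclusion_prob,
             cyst_partial_inclusion_prob, rtstruct_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]", call. = FALSE)
  if (cyst_full_inclusion_prob + cyst_partial_inclusion_prob > 1)
    stop("cyst inclusion probabilities exceed 1", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 organ_method_mix = organ_method_mix,
                 lesion_method_mix = lesion_method_mix,
                 pelvis_exclusion_prob = pelvis_exclusion_prob,
                 cyst_full_inclusion_prob = cyst_full_inclusion_prob,
                 cyst_partial_inclusion_prob = cyst_partial_inclusion_prob,
                 organ_threshold_range = organ_threshold_range,
                 lesion_threshold_range = lesion_threshold_range,
                 sphere_radius_frac = sphere_radius_frac,
                 sphere_radius_jitter = sphere_radius_jitter,
                 rtstruct_prob = rtstruct_prob,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# participant-level VOI emulators ------------------------------------------

sim_region_voi <- function(method, base_voi, anatomy, series, config,
                           kind = c("organ", "lesion"),
                           search = NULL, extra = list()) {
  kind <- match.arg(kind)
  thr_range <- if (kind == "organ") config$organ_threshold_range
               else config$lesion_threshold_range
  perturb <- function(voi) {
    u <- stats::runif(1)
    if (u < 1 / 3) morph_voi(voi, "erode")
    else if (u < 2 / 3) morph_voi(voi, "dilate")
    else voi
  }
  switch(method,
    manual = perturb(base_voi),
    semi_automatic = perturb(base_voi),
    ai = base_voi,
    atlas = morph_voi(base_voi, "dilate"),
    gradient = threshold_voi(series$volumes[[2]], 0.40, series$grid,
                             search_region = search),
    threshold = threshold_voi(series$volumes[[2]],
                              stats::runif(1, thr_range[1], thr_range[2]),
                              series$grid, search_region = search),
    threshold_manual = perturb(
      threshold_voi(series$volumes[[2]],
                    stats::runif(1, thr_range[1], thr_range[2]),
                    series$grid, search_region = search)),
    sphere = {
      idx <- which(base_voi$mask)
      ctr <- colMeans(voxel_centers(base_voi$grid, idx))
      r_eq <- (3 * length(idx) * voxel_volume_ml(base_voi$grid) * 1000 /
                 (4 * pi))^(1 / 3)
      frac <- config$sphere_radius_frac +
        stats::runif(1, -config$sphere_radius_jitter,
                     config$sphere_radius_jitter)
      sphere_voi(ctr, max(r_eq * frac, 1.1 * max(base_voi$grid$spacing_mm)),
                 base_voi$grid)
    },
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

#' Simulate a cohort of segmentation submissions
#'
#' Each synthetic participant draws a segmentation method from the
#' configured mix, produces a task-1 VOI with that method's emulator
#' (kidney participants additionally decide whether to exclude the renal
#' pelvis and which cysts to include, at the configured frequencies), and
#' the full dosimetry chain converts each VOI to an absorbed dose. Task-4
#' doses use the fixed reference VOI in the participant's assigned format
#' (binary mask = refined reference; RTStruct = the same VOI dilated one
#' voxel, emulating contour-rasterisation bias). Deterministic given the
#' seed.
#'
#' @param config a [cohort_sim_config()].
#' @param series an `activity_series`.
#' @param anatomy the matching `label_volume`.
#' @param injected_activity_MBq administered activity, MBq.
#' @param regions which regions to simulate; default right kidney and first
#'   lesion.
#' @param dose_factor see [absorbed_dose()].
#' @return A cohort data.frame (`participant`, `region`, `task`,
#'   `voi_format`, `method`, `dose_Gy`) suitable for [summarize_cohort()].
#' @export
simulate_cohort <- function(config, series, anatomy,
                            injected_activity_MBq = 7210,
                            regions = c("kidney_R", "lesion_1"),
                            dose_factor = LU177_ELECTRON_DOSE_FACTOR) {
  stopifnot(inherits(config, "cohort_sim_config"),
            inherits(series, "activity_series"),
            inherits(anatomy, "label_volume"))
  dose_of <- function(voi) {
    tac <- measure_activity(series, voi)
    fit <- fit_tac(tac)
    ti <- tiac(fit, injected_activity_MBq)
    mass <- estimate_mass(voi, "spect_variable", average = TRUE)$mass_g
    absorbed_dose(ti, injected_activity_MBq, mass, dose_factor)
  }
  with_seed(config$seed, {
    rows <- list()
    for (reg in regions) {
      is_kidney <- grepl("^kidney", reg)
      side <- if (is_kidney) sub("^kidney_", "", reg) else NULL
      base_voi <- if (is_kidney) true_voi(anatomy, "refined_reference",
                                          side = side)
                  else true_voi(anatomy, reg)
      search <- if (is_kidney)
        new_voi(anatomy$grid,
                morph_voi(true_voi(anatomy, "reference_plus_pelvis",
                                   side = side), "dilate")$mask |
                  morph_voi(true_voi(anatomy, "reference_plus_cysts",
                                     side = side), "dilate")$mask,
                method = "manual/reference")
      else lesion_search_region(anatomy, reg)
      mix <- if (is_kidney) config$organ_method_mix else config$lesion_method_mix
      ref_mask <- base_voi
      ref_rtstruct <- morph_voi(base_voi, "dilate")
      dose_t4 <- c(mask = dose_of(ref_mask), RTStruct = dose_of(ref_rtstruct))
      for (p in seq_len(config$n_participants)) {
        method <- sample(names(mix), 1, prob = mix)
        voi1 <- sim_region_voi(method, base_voi, anatomy, series, config,
                               kind = if (is_kidney) "organ" else "lesion",
                               search = search)
        if (is_kidney && method %in% c("manual", "semi_automatic",
                                       "threshold_manual", "ai", "atlas")) {
          # structure-inclusion choices only apply to contour-style methods
          if (stats::runif(1) > config$pelvis_exclusion_prob)
            voi1 <- combine_voi(voi1, true_voi(anatomy,
                                               "reference_plus_pelvis",
                                               side = side), "union")
          u <- stats::runif(1)
          cysts <- region_names(anatomy, paste0("^cyst_.*_", side, "$"))
          if (u < config$cyst_full_inclusion_prob && length(cysts)) {
            voi1 <- combine_voi(voi1, true_voi(anatomy, cysts), "union")
          } else if (u < config$cyst_full_inclusion_prob +
                       config$cyst_partial_inclusion_prob) {
            intra <- region_names(anatomy, paste0("^cyst_intra_", side, "$"))
            if (length(intra))
              voi1 <- combine_voi(voi1, true_voi(anatomy, intra), "union")
          }
        }
        fmt <- if (stats::runif(1) < config$rtstruct_prob) "RTStruct" else "mask"
        pid <- sprintf("P%02d", p)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, region = reg, task = "task1",
          voi_format = NA_character_, method = method,
          dose_Gy = dose_of(voi1), stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, region = reg, task = "task4",
          voi_format = fmt, method = method,
          dose_Gy = unname(dose_t4[fmt]), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
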