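#' Region kinetics for the digital phantom
#'
#' Activity concentration in a region follows either a mono-exponential
#' washout `C0 * exp(-lambda_eff * t)` or, when an uptake constant `mu` is
#' given, an uptake-washout shape `C0 * (1 - exp(-mu * t)) * exp(-lambda_eff
#' * t)`. Times are hours post-injection; concentrations MBq/mL.
#'
#' @param C0 initial (extrapolated) activity concentration, MBq/mL, >= 0.
#'   Cysts carry `C0 = 0`: they take up no radiopharmaceutical.
#' @param lambda_eff effective decay constant, 1/h, > 0 (physical decay plus
#'   biological clearance).
#' @param mu optional uptake rate constant, 1/h.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(C0, lambda_eff, mu = NULL) {
  if (!is.finite(C0) || C0 < 0) stop("C0 must be >= 0", call. = FALSE)
  if (!is.finite(lambda_eff) || lambda_eff <= 0)
    stop("lambda_eff must be > 0", call. = FALSE)
  if (!is.null(mu) && (!is.finite(mu) || mu <= 0))
    stop("mu, when given, must be > 0", call. = FALSE)
  structure(list(C0 = C0, lambda_eff = lambda_eff, mu = mu),
            class = "kinetic_params")
}

kinetic_value <- function(kin, t) {
  v <- kin$C0 * exp(-kin$lambda_eff * t)
  if (!is.null(kin$mu)) v <- v * (1 - exp(-kin$mu * t))
  v
}

#' Default region kinetics
#'
#' Concentrations are scaled so that organ time-integrated activity
#' coefficients and absorbed doses land in the range reported for
#' post-therapy Lu-177 DOTATATE imaging (kidney TIAC of order 0.4-1.3 h for a
#' ~7 GBq administration). The renal pelvis is transiently hot (urinary
#' excretion, fast washout); cysts are cold.
#'
#' @return Named list of [kinetic_params()], one per phantom region plus
#'   `background`.
#' @export
default_kinetics <- function() {
  list(
    background          = kinetic_params(0.03, 0.020),
    liver               = kinetic_params(0.25, 0.015),
    lesion_1            = kinetic_params(3.00, 0.009),
    lesion_2            = kinetic_params(2.20, 0.010),
    spleen              = kinetic_params(0.35, 0.012),
    kidney_parenchyma_R = kinetic_params(0.45, 0.014),
    kidney_parenchyma_L = kinetic_params(0.42, 0.014),
    renal_pelvis_R      = kinetic_params(1.00, 0.150),
    renal_pelvis_L      = kinetic_params(1.00, 0.150),
    cyst_intra_L        = kinetic_params(0.00, 0.010),
    cyst_extra_R        = kinetic_params(0.00, 0.010)
  )
}

#' Define a phantom organ primitive
#'
#' @param name region name (must match a kinetics entry).
#' @param center_mm centre, mm.
#' @param radii_mm sphere radius (length 1) or ellipsoid semi-axes (length 3), mm.
#' @return An organ definition for [phantom_spec()].
#' @export
phantom_organ <- function(name, center_mm, radii_mm) {
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  stopifnot(length(center_mm) == 3L, length(radii_mm) == 3L,
            all(radii_mm > 0))
  list(name = name, center_mm = as.numeric(center_mm),
       radii_mm = as.numeric(radii_mm))
}

#' Specification of the digital SPECT/CT phantom
#'
#' Bundles the grid, the organ geometry (spheres/ellipsoids placed in
#' declaration order, later structures carving earlier ones), per-region
#' kinetics, the imaging model (isotropic Gaussian PSF, optional seeded
#' Poisson-like noise) and the acquisition protocol (time points, injected
#' activity, body weight).
#'
#' @param grid a [voxel_grid()].
#' @param organs list of organ definitions (`name`, `center_mm`, `radii_mm`);
#'   a single radius gives a sphere. Later entries overwrite earlier ones so
#'   that pelvis and cysts carve the kidney parenchyma.
#' @param kinetics named list of [kinetic_params()]; must cover `background`
#'   and every organ name.
#' @param psf_fwhm_mm full width at half maximum of the isotropic Gaussian
#'   point-spread function, mm, >= 0. Default 12 mm (SPECT-like).
#' @param noise_model `"none"` or `"poisson_like"` (independent Gaussian
#'   noise with variance proportional to the local mean, clipped at zero).
#' @param noise_scale noise magnitude: the standard deviation at a voxel of
#'   mean concentration `m` is `noise_scale * sqrt(m)`.
#' @param seed integer RNG seed governing all phantom randomness.
#' @param injected_activity_MBq administered activity, MBq.
#' @param body_weight_kg patient body weight, kg (for SUV normalisation).
#' @param time_points_h strictly increasing acquisition times, hours
#'   post-injection; at least 2 (4 in the default protocol).
#' @return A `phantom_spec` object.
#' @seealso [default_phantom_spec()], [build_anatomy()],
#'   [make_activity_series()]
#' @export
phantom_spec <- function(grid, organs, kinetics = default_kinetics(),
                         psf_fwhm_mm = 12, noise_model = c("none", "poisson_like"),
                         noise_scale = 0.02, seed = 1L,
                         injected_activity_MBq = 7210,
                         body_weight_kg = 70,
                         time_points_h = c(3.7, 27.7, 103.1, 124.0)) {
  stopifnot(inherits(grid, "voxel_grid"))
  noise_model <- match.arg(noise_model)
  time_points_h <- as.numeric(time_points_h)
  if (length(time_points_h) < 2L || any(diff(time_points_h) <= 0) ||
      any(time_points_h <= 0))
    stop("time_points_h must be >= 2 strictly increasing positive times",
         call. = FALSE)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  if (injected_activity_MBq <= 0)
    stop("injected_activity_MBq must be > 0", call. = FALSE)
  nm <- vapply(organs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate organ names", call. = FALSE)
  structure(list(grid = grid, organs = organs, kinetics = kinetics,
                 psf_fwhm_mm = psf_fwhm_mm, noise_model = noise_model,
                 noise_scale = noise_scale, seed = as.integer(seed),
                 injected_activity_MBq = injected_activity_MBq,
                 body_weight_kg = body_weight_kg,
                 time_points_h = time_points_h),
            class = "phantom_spec")
}

#' Default abdominal phantom
#'
#' A 96^3, 4 mm isotropic abdomen with liver (two hot intra-hepatic
#' lesions), spleen, and two kidneys, each with a renal pelvis; the left
#' kidney carries an intraparenchymal cyst and the right an extraparenchymal
#' cyst. Acquisition protocol: four SPECT time points at 3.7, 27.7, 103.1
#' and 124.0 h after a 7210 MBq administration.
#'
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [phantom_spec()] (e.g.
#'   `noise_model`, `psf_fwhm_mm`).
#' @return A `phantom_spec`.
#' @examples
#' spec <- default_phantom_spec(seed = 7)
#' anat <- build_anatomy(spec)
#' table(anat$labels)[1:3]
#' @export
default_phantom_spec <- function(seed = 1L, ...) {
  grid <- voxel_grid(c(96, 96, 96), 4)
  organs <- list(
    phantom_organ("liver",               c(250, 160, 230), c(62, 48, 55)),
    phantom_organ("lesion_1",            c(262, 150, 250), 14),
    phantom_organ("lesion_2",            c(225, 178, 200), 9),
    phantom_organ("spleen",              c(105, 150, 255), c(26, 21, 36)),
    phantom_organ("kidney_parenchyma_R", c(140, 240, 160), c(32, 27, 48)),
    phantom_organ("kidney_parenchyma_L", c(255, 245, 160), c(32, 27, 48)),
    phantom_organ("renal_pelvis_R",      c(152, 240, 160), c(15, 13, 24)),
    phantom_organ("renal_pelvis_L",      c(243, 245, 160), c(15, 13, 24)),
    phantom_organ("cyst_intra_L",        c(268, 238, 140), 10),
    phantom_organ("cyst_extra_R",        c(116, 254, 190), 11)
  )
  phantom_spec(grid, organs, seed = seed, ...)
}

#' Rasterise phantom anatomy into a label volume
#'
#' Each organ is a sphere or ellipsoid; a voxel belongs to an organ iff its
#' centre lies inside the primitive. Organs are rasterised in declaration
#' order and later organs overwrite earlier ones, so substructures (renal
#' pelvis, cysts) carve their host parenchyma and all labels are disjoint.
#'
#' @param spec a [phantom_spec()].
#' @return A `label_volume`: `grid`, integer `labels` array (0 =
#'   background), and `legend` mapping label value to region name.
#' @export
build_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  lo <- grid$origin_mm
  hi <- grid$origin_mm + (grid$shape - 1) * grid$spacing_mm
  labels <- array(0L, dim = grid$shape)
  legend <- c(background = 0L)
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  for (i in seq_along(spec$organs)) {
    org <- spec$organs[[i]]
    if (any(org$center_mm - org$radii_mm < lo) ||
        any(org$center_mm + org$radii_mm > hi))
      stop(sprintf("organ '%s' extends outside the grid", org$name),
           call. = FALSE)
    a <- ((cx - org$center_mm[1]) / org$radii_mm[1])^2
    b <- ((cy - org$center_mm[2]) / org$radii_mm[2])^2
    d <- ((cz - org$center_mm[3]) / org$radii_mm[3])^2
    inside <- outer(outer(a, b, "+"), d, "+") <= 1
    if (!any(inside))
      stop(sprintf("region '%s' rasterises to zero voxels", org$name),
           call. = FALSE)
    labels[inside] <- i
    legend[org$name] <- i
  }
  # carving may have removed a region entirely
  present <- tabulate(labels, nbins = length(spec$organs))
  gone <- which(present == 0L)
  if (length(gone))
    stop(sprintf("region '%s' has zero voxels after carving",
                 names(legend)[match(gone[1], legend)]), call. = FALSE)
  structure(list(grid = grid, labels = labels, legend = legend),
            class = "label_volume")
}

region_mask <- function(anatomy, regions) {
  stopifnot(inherits(anatomy, "label_volume"))
  unknown <- setdiff(regions, names(anatomy$legend))
  if (length(unknown))
    stop(sprintf("unknown region(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (!length(regions)) return(array(FALSE, dim = anatomy$grid$shape))
  array(anatomy$labels %in% anatomy$legend[regions], dim = anatomy$grid$shape)
}

region_names <- function(anatomy, pattern) {
  grep(pattern, names(anatomy$legend), value = TRUE)
}

#' Reference VOI from true anatomy labels
#'
#' Builds the union mask of the named regions. Three predefined bundles
#' mirror the kidney VOI scenarios used in controlled segmentation analyses:
#' `"refined_reference"` (functional parenchyma only),
#' `"reference_plus_pelvis"` (parenchyma plus renal pelvis) and
#' `"reference_plus_cysts"` (parenchyma plus all cysts).
#'
#' @param anatomy a `label_volume` from [build_anatomy()].
#' @param region_set character vector of legend region names, or one bundle
#'   name.
#' @param side optional `"L"` or `"R"`: restrict a bundle to one kidney.
#' @return A [voi] with provenance `"manual/reference"`.
#' @export
true_voi <- function(anatomy, region_set, side = NULL) {
  stopifnot(inherits(anatomy, "label_volume"))
  bundles <- c("refined_reference", "reference_plus_pelvis",
               "reference_plus_cysts")
  if (length(region_set) == 1L && region_set %in% bundles) {
    par <- region_names(anatomy, "^kidney_parenchyma")
    pel <- region_names(anatomy, "^renal_pelvis")
    cys <- region_names(anatomy, "^cyst_")
    if (!is.null(side)) {
      sfx <- paste0("_", side, "$")
      par <- grep(sfx, par, value = TRUE)
      pel <- grep(sfx, pel, value = TRUE)
      cys <- grep(sfx, cys, value = TRUE)
    }
    region_set <- switch(region_set,
      refined_reference     = par,
      reference_plus_pelvis = c(par, pel),
      reference_plus_cysts  = c(par, cys))
  }
  new_voi(anatomy$grid, region_mask(anatomy, region_set),
          method = "manual/reference")
}

# --- Gaussian PSF ----------------------------------------------------------

# 1D convolution matrix (constant-zero padding): kernel normalised to sum 1,
# truncated at 4 sigma.
conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(0:r)^2 / (2 * sigma_vox^2))
  w <- c(rev(w[-1]), w)
  w <- w / sum(w)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- matrix(0, n, n)
  K[d <= r] <- w[d[d <= r] + r + 1]
  K
}

# Separable 3D Gaussian blur; sigma given per axis in voxels.
blur3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  if (sigma_vox[1] > 0) {
    vol <- array(conv_matrix(d[1], sigma_vox[1]) %*% matrix(vol, d[1]), d)
  }
  if (sigma_vox[2] > 0) {
    vol <- aperm(vol, c(2, 1, 3))
    vol <- array(conv_matrix(d[2], sigma_vox[2]) %*% matrix(vol, d[2]),
                 d[c(2, 1, 3)])
    vol <- aperm(vol, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    vol <- aperm(vol, c(3, 2, 1))
    vol <- array(conv_matrix(d[3], sigma_vox[3]) %*% matrix(vol, d[3]),
                 d[c(3, 2, 1)])
    vol <- aperm(vol, c(3, 2, 1))
  }
  vol
}

#' Simulate the multi-time-point activity-concentration series
#'
#' For each acquisition time, region concentrations are evaluated from their
#' kinetics (piecewise-constant over the anatomy), blurred with the isotropic
#' Gaussian PSF, and optionally degraded with seeded Poisson-like noise.
#' With `psf_fwhm_mm = 0` and noise off the volumes are exactly piecewise
#' constant.
#'
#' @param anatomy a `label_volume` from [build_anatomy()].
#' @param spec the [phantom_spec()] that produced it.
#' @return An `activity_series`: `grid`, `times_h`, and a list `volumes` of
#'   concentration arrays (MBq/mL), one per time point.
#' @export
make_activity_series <- function(anatomy, spec) {
  stopifnot(inherits(anatomy, "label_volume"), inherits(spec, "phantom_spec"))
  regions <- names(anatomy$legend)
  missing_kin <- setdiff(regions, names(spec$kinetics))
  if (length(missing_kin))
    stop(sprintf("missing kinetics for region(s): %s",
                 paste(missing_kin, collapse = ", ")), call. = FALSE)
  sigma_vox <- (spec$psf_fwhm_mm / 2.35482) / spec$grid$spacing_mm
  lab1 <- anatomy$labels + 1L  # 1-based lookup, background label 0 -> 1
  vols <- with_seed(spec$seed, {
    lapply(spec$time_points_h, function(t) {
      cvals <- vapply(regions, function(r)
        kinetic_value(spec$kinetics[[r]], t), numeric(1))
      # legend order == label order (background first)
      v <- array(cvals[order(anatomy$legend)][lab1], dim = spec$grid$shape)
      if (any(sigma_vox > 0)) v <- blur3d(v, sigma_vox)
      if (spec$noise_model == "poisson_like") {
        sd <- spec$noise_scale * sqrt(pmax(v, 0))
        v <- v + array(stats::rnorm(length(v), 0, 1), dim = dim(v)) * sd
        v[v < 0] <- 0
      }
      v
    })
  })
  structure(list(grid = spec$grid, times_h = spec$time_points_h,
                 volumes = vols),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %d time points (%s h), grid %s\n",
              length(x$times_h), paste(format(x$times_h), collapse = ", "),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}
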