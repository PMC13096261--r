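#' Volume of interest (VOI)
#'
#' A binary mask on a voxel grid with provenance: which segmentation method
#' produced it, at which threshold fraction, from which time point.
#'
#' @param grid a [voxel_grid()].
#' @param mask logical array matching `grid$shape`.
#' @param method one of `"manual/reference"`, `"threshold"`,
#'   `"threshold_propagated"`, `"sphere"`, `"scenario"`.
#' @param threshold_fraction optional fraction of maximum in (0,1).
#' @param source_time_index optional integer time index the mask was drawn on.
#' @return A `voi` object.
#' @name voi
#' @export
new_voi <- function(grid, mask,
                    method = c("manual/reference", "threshold",
                               "threshold_propagated", "sphere", "scenario"),
                    threshold_fraction = NULL, source_time_index = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  method <- match.arg(method)
  if (!identical(dim(mask), as.integer(grid$shape)))
    stop("mask dimensions do not match grid shape", call. = FALSE)
  storage.mode(mask) <- "logical"
  structure(list(grid = grid, mask = mask, method = method,
                 threshold_fraction = threshold_fraction,
                 source_time_index = source_time_index),
            class = "voi")
}

#' @rdname voi
#' @param voi a `voi`.
#' @export
voi_volume_ml <- function(voi) {
  stopifnot(inherits(voi, "voi"))
  sum(voi$mask) * voxel_volume_ml(voi$grid)
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> %d voxels (%.2f mL), method '%s'%s\n",
              sum(x$mask), voi_volume_ml(x), x$method,
              if (!is.null(x$threshold_fraction))
                sprintf(", threshold %.0f%%", 100 * x$threshold_fraction)
              else ""))
  invisible(x)
}

# --- connected components --------------------------------------------------

# 26-connected component of `mask` containing linear voxel index `seed_idx`.
# Breadth-first flood fill with vectorised neighbour expansion.
connected_component <- function(mask, seed_idx) {
  d <- dim(mask)
  stopifnot(mask[seed_idx])
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- array(FALSE, d)
  comp[seed_idx] <- TRUE
  frontier <- arrayInd(seed_idx, d)
  while (nrow(frontier)) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                   drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[keep, , drop = FALSE]
    if (!nrow(nb)) break
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    lin <- unique(lin[mask[lin] & !comp[lin]])
    if (!length(lin)) break
    comp[lin] <- TRUE
    frontier <- arrayInd(lin, d)
  }
  comp
}

#' Percentage-of-maximum threshold segmentation
#'
#' Emulates fixed-threshold SPECT segmentation: voxels at or above
#' `fraction` of the maximum voxel value, optionally restricted to a search
#' region, reduced to the 26-connected component containing the maximum
#' voxel (without the restriction a global threshold would merge organs of
#' similar uptake).
#'
#' @param volume nonnegative concentration array.
#' @param fraction threshold as a fraction of maximum, in (0,1).
#' @param grid the [voxel_grid()] the volume lives on.
#' @param search_region optional nonempty [voi]: both the maximum and the
#'   mask are taken inside it.
#' @param connected if `FALSE`, keep the full superlevel set (no
#'   connected-component restriction).
#' @return A `voi` with provenance `"threshold"` recording `fraction`.
#' @export
threshold_voi <- function(volume, fraction, grid, search_region = NULL,
                          connected = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0,1)", call. = FALSE)
  if (min(volume) < 0) stop("volume must be nonnegative", call. = FALSE)
  if (!is.null(search_region)) {
    stopifnot(inherits(search_region, "voi"))
    stop_if_grid_mismatch(grid, search_region$grid)
    if (!any(search_region$mask))
      stop("search_region is empty", call. = FALSE)
    vals <- ifelse(search_region$mask, volume, -Inf)
  } else {
    vals <- volume
  }
  M <- max(vals)
  if (M <= 0) stop("no signal: maximum voxel value is zero", call. = FALSE)
  mask <- array(vals >= fraction * M, dim = dim(volume))
  if (connected) {
    seed_idx <- which.max(vals)
    mask <- connected_component(mask, seed_idx)
  }
  new_voi(grid, mask, method = "threshold", threshold_fraction = fraction)
}

# Activity-weighted centroid (in voxel index units) of `mask` over `volume`.
mask_centroid <- function(mask, volume) {
  idx <- which(mask)
  w <- volume[idx]
  if (sum(w) <= 0) w <- rep(1, length(idx))
  ind <- arrayInd(idx, dim(mask))
  colSums(ind * w) / sum(w)
}

#' Propagate a VOI to another time point without reshaping
#'
#' Emulates threshold propagation: the source mask is translated by an
#' integer-voxel shift, chosen by local search within +/- `window` voxels per
#' axis around the rounded displacement of the activity-weighted centroid, to
#' maximise the activity enclosed in the target volume. The mask shape (and
#' hence voxel count) is preserved exactly; a shift that would push the mask
#' off the grid is an error.
#'
#' @param source a nonempty [voi].
#' @param source_volume,target_volume concentration arrays on the same grid.
#' @param window half-width of the integer shift search, voxels (default 5).
#' @return A `voi` with provenance `"threshold_propagated"`.
#' @export
propagate_voi <- function(source, source_volume, target_volume, window = 5L) {
  stopifnot(inherits(source, "voi"))
  if (!any(source$mask)) stop("source VOI is empty", call. = FALSE)
  d <- dim(source$mask)
  if (!identical(dim(source_volume), d) || !identical(dim(target_volume), d))
    stop("volumes do not share the source grid shape", call. = FALSE)
  ind <- arrayInd(which(source$mask), d)
  c_src <- mask_centroid(source$mask, source_volume)
  c_tgt0 <- round(mask_centroid(source$mask, target_volume) - c_src)
  shifts <- as.matrix(expand.grid(dx = -window:window, dy = -window:window,
                                  dz = -window:window))
  best <- NULL; best_sum <- -Inf
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ] + c_tgt0
    nb <- sweep(ind, 2, sh, "+")
    if (any(nb < 1L) || any(nb[, 1] > d[1]) || any(nb[, 2] > d[2]) ||
        any(nb[, 3] > d[3])) next
    tot <- sum(target_volume[nb])
    # deterministic tie-break: prefer the smaller shift
    if (tot > best_sum + 1e-12 ||
        (abs(tot - best_sum) <= 1e-12 && !is.null(best) &&
         sum(sh^2) < sum(best^2))) {
      best_sum <- tot; best <- sh
    }
  }
  if (is.null(best))
    stop("propagation out of bounds: every candidate shift clips the grid",
         call. = FALSE)
  nb <- sweep(ind, 2, best, "+")
  mask <- array(FALSE, d)
  mask[nb] <- TRUE
  new_voi(source$grid, mask, method = "threshold_propagated",
          threshold_fraction = source$threshold_fraction,
          source_time_index = source$source_time_index)
}

#' Spherical VOI
#'
#' Small spherical VOI placed within an organ: voxels whose centres lie
#' within `radius_mm` of `center_mm`.
#'
#' @param center_mm sphere centre, mm.
#' @param radius_mm sphere radius, mm, > 0.
#' @param grid a [voxel_grid()].
#' @return A `voi` with provenance `"sphere"`.
#' @export
sphere_voi <- function(center_mm, radius_mm, grid) {
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)
  a <- (axis_coords(grid, 1) - center_mm[1])^2
  b <- (axis_coords(grid, 2) - center_mm[2])^2
  d <- (axis_coords(grid, 3) - center_mm[3])^2
  mask <- outer(outer(a, b, "+"), d, "+") <= radius_mm^2
  if (!any(mask))
    stop("sphere contains no voxel centres (outside grid or too small)",
         call. = FALSE)
  new_voi(grid, mask, method = "sphere")
}

#' Combine two VOIs
#'
#' Voxelwise set union or difference of masks on the same grid; used to build
#' the VOI scenarios (reference plus pelvis, reference plus cysts).
#'
#' @param a,b [voi] objects on the same grid.
#' @param op `"union"` or `"difference"` (`a` minus `b`).
#' @return A `voi` with provenance `"scenario"`.
#' @export
combine_voi <- function(a, b, op = c("union", "difference")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "voi"), inherits(b, "voi"))
  stop_if_grid_mismatch(a$grid, b$grid)
  mask <- switch(op, union = a$mask | b$mask, difference = a$mask & !b$mask)
  new_voi(a$grid, mask, method = "scenario")
}

# 6-neighbourhood morphological dilation/erosion by one voxel (used by the
# cohort simulator's manual-contour emulator).
morph_voi <- function(voi, op = c("dilate", "erode")) {
  op <- match.arg(op)
  m <- voi$mask
  d <- dim(m)
  shift1 <- function(x, axis, by) {
    out <- array(if (op == "dilate") FALSE else TRUE, d)
    src <- lapply(d, seq_len); dst <- src
    n <- d[axis]
    if (by > 0) { dst[[axis]] <- 2:n;      src[[axis]] <- 1:(n - 1) }
    else        { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  acc <- m
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    s <- shift1(m, axis, by)
    acc <- if (op == "dilate") acc | s else acc & s
  }
  new_voi(voi$grid, acc, method = voi$method,
          threshold_fraction = voi$threshold_fraction,
          source_time_index = voi$source_time_index)
}

#' Lesion or organ mass from VOI volume
#'
#' Two strategies, both assuming uniform density: `"ct_constant"` takes a
#' single fixed mass from an anatomical reference VOI, unaffected by
#' threshold choice; `"spect_variable"` derives one mass per time point from
#' the SPECT VOI volumes (optionally averaged over time points, the
#' convention used for kidney scenario reporting).
#'
#' @param voi_per_time list of [voi] objects, one per time point (may be a
#'   single `voi` for a time-constant VOI).
#' @param strategy `"ct_constant"` or `"spect_variable"`.
#' @param density_g_per_ml tissue density, g/mL (default 1.0).
#' @param reference_voi anatomical reference [voi], required for
#'   `"ct_constant"`.
#' @param average if `TRUE` (and `"spect_variable"`), collapse the per-time
#'   masses to their mean.
#' @return A `mass_estimate`: `strategy`, `mass_g` (length 1 or one per
#'   time), `density_g_per_ml`.
#' @export
estimate_mass <- function(voi_per_time,
                          strategy = c("ct_constant", "spect_variable"),
                          density_g_per_ml = 1.0, reference_voi = NULL,
                          average = FALSE) {
  strategy <- match.arg(strategy)
  if (inherits(voi_per_time, "voi")) voi_per_time <- list(voi_per_time)
  if (density_g_per_ml <= 0)
    stop("density_g_per_ml must be > 0", call. = FALSE)
  if (strategy == "ct_constant") {
    if (is.null(reference_voi))
      stop("ct_constant requires a reference_voi", call. = FALSE)
    mass <- voi_volume_ml(reference_voi) * density_g_per_ml
    if (mass <= 0) stop("reference VOI is empty: zero mass", call. = FALSE)
  } else {
    if (!length(voi_per_time))
      stop("spect_variable requires at least one VOI", call. = FALSE)
    vols <- vapply(voi_per_time, voi_volume_ml, numeric(1))
    if (any(vols <= 0))
      stop("empty VOI under spect_variable: zero mass", call. = FALSE)
    mass <- vols * density_g_per_ml
    if (average) mass <- mean(mass)
  }
  structure(list(strategy = strategy, mass_g = unname(mass),
                 density_g_per_ml = density_g_per_ml),
            class = "mass_estimate")
}
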