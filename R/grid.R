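#' Axis-aligned voxel grid
#'
#' Defines the lattice shared by all volumes in an analysis: array shape,
#' voxel spacing in mm, and the physical coordinate (mm) of the centre of the
#' first voxel. All phantom, segmentation and dosimetry operations require
#' their inputs to live on the same grid.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing_mm numeric vector of length 3 (or 1, recycled), voxel edge
#'   lengths in mm; must be positive.
#' @param origin_mm numeric vector of length 3, mm coordinate of the centre of
#'   voxel (1,1,1). Default `c(0, 0, 0)`.
#' @return An object of class `voxel_grid` with fields `shape`, `spacing_mm`,
#'   `origin_mm`.
#' @examples
#' g <- voxel_grid(c(96, 96, 96), 4)
#' voxel_volume_ml(g)  # 0.064 mL
#' @export
voxel_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive reals", call. = FALSE)
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite reals", call. = FALSE)
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing_mm) / 1000
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm spacing, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("voxel grids do not match (shape/spacing/origin)", call. = FALSE)
  invisible(TRUE)
}

# mm coordinates of voxel centres along one axis
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing_mm[axis]
}

# n x 3 matrix of voxel-centre coordinates for given linear indices (or all)
voxel_centers <- function(grid, idx = NULL) {
  sh <- grid$shape
  if (is.null(idx)) idx <- seq_len(prod(sh))
  idx0 <- idx - 1L
  i <- idx0 %% sh[1]
  j <- (idx0 %/% sh[1]) %% sh[2]
  k <- idx0 %/% (sh[1] * sh[2])
  cbind(grid$origin_mm[1] + i * grid$spacing_mm[1],
        grid$origin_mm[2] + j * grid$spacing_mm[2],
        grid$origin_mm[3] + k * grid$spacing_mm[3])
}
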