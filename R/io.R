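#' Write / read an activity series as NIfTI plus a CSV manifest
#'
#' `write_activity_series()` stores one NIfTI volume per time point
#' (`activity_t<k>.nii.gz`, pixdim = grid spacing) and a manifest CSV with
#' columns `index, time_h, filename`. `read_activity_series()` rebuilds the
#' series, validating that all volumes share shape and spacing; unsorted
#' manifests are reordered with a warning and duplicate times rejected.
#'
#' @param series an `activity_series`.
#' @param dir output directory (created if needed).
#' @return `write_activity_series()`: the manifest path, invisibly.
#'   `read_activity_series()`: an `activity_series`.
#' @export
write_activity_series <- function(series, dir) {
  stopifnot(inherits(series, "activity_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("activity_t%d.nii.gz", seq_along(series$times_h))
  for (k in seq_along(series$times_h)) {
    img <- RNifti::asNifti(series$volumes[[k]])
    RNifti::pixdim(img) <- series$grid$spacing_mm
    RNifti::writeNifti(img, file.path(dir, files[k]))
  }
  manifest <- data.frame(index = seq_along(series$times_h),
                         time_h = series$times_h, filename = files)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_series
#' @param manifest_csv path to a manifest written by
#'   `write_activity_series()`.
#' @export
read_activity_series <- function(manifest_csv) {
  if (!file.exists(manifest_csv))
    stop(sprintf("manifest not found: %s", manifest_csv), call. = FALSE)
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  need <- c("index", "time_h", "filename")
  if (!all(need %in% names(man)))
    stop("manifest must have columns index, time_h, filename", call. = FALSE)
  if (anyDuplicated(man$time_h))
    stop("duplicate time stamps in manifest", call. = FALSE)
  if (is.unsorted(man$time_h)) {
    warning("manifest times unsorted; reordering", call. = FALSE)
    man <- man[order(man$time_h), ]
  }
  dir <- dirname(manifest_csv)
  vols <- list(); spacing <- NULL; shape <- NULL
  for (k in seq_len(nrow(man))) {
    f <- file.path(dir, man$filename[k])
    if (!file.exists(f))
      stop(sprintf("missing volume file: %s", f), call. = FALSE)
    img <- RNifti::readNifti(f)
    pd <- RNifti::pixdim(img)[1:3]
    if (is.null(shape)) { shape <- dim(img); spacing <- pd }
    else if (!identical(dim(img), shape) || any(abs(pd - spacing) > 1e-6))
      stop(sprintf("volume %s does not share the series grid", man$filename[k]),
           call. = FALSE)
    vols[[k]] <- array(as.numeric(img), dim = shape)
  }
  structure(list(grid = voxel_grid(shape, spacing),
                 times_h = man$time_h, volumes = vols),
            class = "activity_series")
}

#' Write / read phantom anatomy as integer NIfTI plus a legend CSV
#'
#' @param anatomy a `label_volume`.
#' @param dir output directory.
#' @return `write_anatomy()`: the label-volume path, invisibly;
#'   `read_anatomy()`: a `label_volume`.
#' @export
write_anatomy <- function(anatomy, dir) {
  stopifnot(inherits(anatomy, "label_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(anatomy$labels)
  RNifti::pixdim(img) <- anatomy$grid$spacing_mm
  path <- file.path(dir, "anatomy.nii.gz")
  RNifti::writeNifti(img, path, datatype = "int16")
  utils::write.csv(data.frame(label = unname(anatomy$legend),
                              region = names(anatomy$legend)),
                   file.path(dir, "legend.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_anatomy
#' @export
read_anatomy <- function(dir) {
  img <- RNifti::readNifti(file.path(dir, "anatomy.nii.gz"))
  leg <- utils::read.csv(file.path(dir, "legend.csv"),
                         stringsAsFactors = FALSE)
  labels <- array(as.integer(img), dim = dim(img))
  structure(list(grid = voxel_grid(dim(img), RNifti::pixdim(img)[1:3]),
                 labels = labels,
                 legend = stats::setNames(as.integer(leg$label), leg$region)),
            class = "label_volume")
}

#' Write a VOI as a binary NIfTI mask
#'
#' @param voi a [voi].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_voi <- function(voi, path) {
  stopifnot(inherits(voi, "voi"))
  img <- RNifti::asNifti(array(as.integer(voi$mask), dim = dim(voi$mask)))
  RNifti::pixdim(img) <- voi$grid$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_voi
#' @param grid optional [voxel_grid()] to validate against.
#' @export
read_voi <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  g <- voxel_grid(dim(img), RNifti::pixdim(img)[1:3])
  if (!is.null(grid)) {
    stop_if_grid_mismatch(voxel_grid(grid$shape, grid$spacing_mm), g)
    g <- grid
  }
  new_voi(g, array(as.numeric(img) > 0.5, dim = dim(img)),
          method = "manual/reference")
}

#' Write a set of report tables to CSV
#'
#' One CSV per named table, written with fixed column order and full
#' precision (15 significant digits), so that identical inputs yield
#' byte-identical files. Empty tables produce a header-only file with a
#' warning.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(tables, out_dir) {
  if (!length(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("`tables` must be a non-empty named list", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!nrow(tb))
      warning(sprintf("table '%s' is empty; writing header only", nm),
              call. = FALSE)
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], function(x) signif(x, 15))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
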