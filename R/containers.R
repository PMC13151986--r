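#' Masked 4D functional time-series container
#'
#' Stores one participant's functional data as a frames x voxels matrix over
#' the in-mask voxels of a regular 3D grid, together with the geometry
#' metadata needed to map columns back to voxel positions.
#'
#' @param data numeric matrix, frames (rows) x in-mask voxels (columns).
#' @param mask logical 3D array; `sum(mask)` must equal `ncol(data)`.
#'   Column `j` of `data` corresponds to the j-th `TRUE` voxel of `mask`
#'   in array (column-major) order.
#' @param voxel_size voxel edge length in mm (isotropic grid).
#' @param tr repetition time in seconds.
#' @param run integer vector, one run label per frame (default: single run).
#' @param participant_id optional identifier.
#'
#' @return An object of class `ts_image`.
#' @export
ts_image <- function(data, mask, voxel_size, tr,
                     run = rep(1L, nrow(data)), participant_id = NA) {
  stopifnot(is.matrix(data), is.array(mask), length(dim(mask)) == 3L)
  if (sum(mask) != ncol(data))
    stop("mask voxel count (", sum(mask), ") != data columns (", ncol(data), ")")
  if (length(run) != nrow(data))
    stop("run labels must have one entry per frame")
  structure(
    list(data = data, mask = mask, dims = dim(mask),
         voxel_size = voxel_size, tr = tr, run = as.integer(run),
         participant_id = participant_id),
    class = "ts_image")
}

#' @export
print.ts_image <- function(x, ...) {
  cat("<ts_image> participant:", x$participant_id,
      "| grid:", paste(x$dims, collapse = "x"),
      "| voxels:", ncol(x$data),
      "| frames:", nrow(x$data),
      sprintf("(%d run%s)", length(unique(x$run)),
              if (length(unique(x$run)) > 1) "s" else ""),
      "| TR:", x$tr, "s | voxel:", x$voxel_size, "mm\n")
  invisible(x)
}

#' Per-participant voxelwise statistic map
#'
#' @param values numeric vector, one value per in-mask voxel.
#' @param mask logical 3D array defining the voxel ordering.
#' @param voxel_size voxel edge length in mm.
#' @param metric metric label, e.g. "LCOR", "GCOR" or "seed-z".
#' @param participant_id optional identifier.
#'
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask, voxel_size, metric = "LCOR",
                       participant_id = NA) {
  stopifnot(length(values) == sum(mask))
  structure(
    list(values = as.numeric(values), mask = mask, dims = dim(mask),
         voxel_size = voxel_size, metric = metric,
         participant_id = participant_id),
    class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat("<scalar_map>", x$metric, "| participant:", x$participant_id,
      "| grid:", paste(x$dims, collapse = "x"),
      "| in-mask voxels:", length(x$values), "\n")
  invisible(x)
}

#' Expand in-mask values to a full 3D array
#'
#' @param map a `scalar_map`, or a numeric vector with `mask` supplied.
#' @param mask logical 3D array (ignored when `map` is a `scalar_map`).
#' @param fill value used outside the mask.
#' @return 3D numeric array.
#' @export
map_to_array <- function(map, mask = NULL, fill = NA_real_) {
  if (inherits(map, "scalar_map")) {
    mask <- map$mask
    map <- map$values
  }
  out <- array(fill, dim = dim(mask))
  out[mask] <- map
  out
}

#' Physical coordinates (mm) of in-mask voxels
#'
#' @param mask logical 3D array.
#' @param voxel_size voxel edge length in mm.
#' @return matrix with one row per in-mask voxel (array order) and columns
#'   x, y, z in mm.
#' @export
voxel_coords <- function(mask, voxel_size) {
  d <- dim(mask)
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  (ijk - 1) * voxel_size
}

# indices (within the in-mask ordering) of a sub-mask
mask_index <- function(mask, submask) {
  stopifnot(identical(dim(mask), dim(submask)))
  if (any(submask & !mask)) stop("submask extends outside the brain mask")
  match(which(submask), which(mask))
}
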