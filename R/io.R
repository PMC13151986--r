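#' Write cohort tables and ground truth to disk
#'
#' Tables go to CSV (one row per participant); the synthetic ground truth
#' (planted masks as linear voxel indices, true path sizes, latent
#' mediators) goes to a JSON sidecar.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(exposures = file.path(dir, "exposures.csv"),
             exposures_prepared = file.path(dir, "exposures_prepared.csv"),
             covariates = file.path(dir, "covariates.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$exposures, files["exposures"], row.names = FALSE)
  utils::write.csv(cohort$exposures_prepared, files["exposures_prepared"],
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, files["covariates"], row.names = FALSE)
  utils::write.csv(cohort$outcomes, files["outcomes"], row.names = FALSE)
  tr <- cohort$truth
  truth_json <- list(
    grid_shape = dim(tr$gcor_cluster_mask),
    gcor_cluster_voxels = which(tr$gcor_cluster_mask),
    lcor_cluster_voxels = which(tr$lcor_cluster_mask),
    pattern2_voxels = which(tr$pattern2_mask),
    true_a = tr$true_a, true_b = tr$true_b,
    true_c_prime = tr$true_c_prime, true_indirect = tr$true_indirect,
    true_a2 = tr$true_a2, true_b2 = tr$true_b2,
    mediators = tr$mediators)
  jsonlite::write_json(truth_json, files["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}

#' Write a time-series image as a NIfTI-1 volume
#'
#' One 4D file per run, with voxel size (mm) and TR (s) in the header, plus
#' a 6-column motion CSV per run when motion is supplied.
#'
#' @param img a [ts_image()].
#' @param prefix path prefix; files are `<prefix>_run<r>.nii` and
#'   `<prefix>_run<r>_motion.csv`.
#' @param motion optional frames x 6 motion matrix.
#' @return character vector of files written, invisibly.
#' @export
write_timeseries_nifti <- function(img, prefix, motion = NULL) {
  files <- character(0)
  for (r in unique(img$run)) {
    ix <- which(img$run == r)
    arr <- array(0, dim = c(img$dims, length(ix)))
    flat <- matrix(0, prod(img$dims), length(ix))
    flat[which(img$mask), ] <- t(img$data[ix, , drop = FALSE])
    arr[] <- flat
    nii <- RNifti::asNifti(arr)
    nii <- RNifti::`pixdim<-`(nii, c(rep(img$voxel_size, 3), img$tr))
    f <- sprintf("%s_run%d.nii", prefix, r)
    RNifti::writeNifti(nii, f)
    files <- c(files, f)
    if (!is.null(motion)) {
      mf <- sprintf("%s_run%d_motion.csv", prefix, r)
      mot <- as.data.frame(motion[ix, , drop = FALSE])
      names(mot) <- c("trans_x", "trans_y", "trans_z",
                      "rot_pitch", "rot_roll", "rot_yaw")
      utils::write.csv(mot, mf, row.names = FALSE)
      files <- c(files, mf)
    }
  }
  invisible(files)
}

#' Read a 4D NIfTI volume (plus mask) into a [ts_image()]
#'
#' @param paths one or more NIfTI files (one per run, concatenated in
#'   order).
#' @param mask logical 3D array selecting in-mask voxels.
#' @param participant_id optional identifier.
#' @return a [ts_image()]; voxel size and TR are taken from the header.
#' @export
read_timeseries_nifti <- function(paths, mask, participant_id = NA) {
  dats <- list(); runs <- integer(0); vox <- NA; tr <- NA
  for (r in seq_along(paths)) {
    nii <- RNifti::readNifti(paths[r])
    arr <- as.array(nii)
    stopifnot(length(dim(arr)) == 4L, identical(dim(arr)[1:3], dim(mask)))
    pd <- RNifti::pixdim(nii)
    vox <- pd[1]; tr <- if (length(pd) >= 4) pd[4] else NA
    flat <- matrix(arr, prod(dim(mask)), dim(arr)[4])
    dats[[r]] <- t(flat[which(mask), , drop = FALSE])
    runs <- c(runs, rep(r, dim(arr)[4]))
  }
  ts_image(do.call(rbind, dats), mask, voxel_size = vox, tr = tr,
           run = runs, participant_id = participant_id)
}

#' Write a scalar map as a 3D NIfTI volume
#'
#' @param map a [scalar_map()]; out-of-mask voxels are written as 0.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  arr <- map_to_array(map, fill = 0)
  nii <- RNifti::asNifti(arr)
  nii <- RNifti::`pixdim<-`(nii, rep(map$voxel_size, 3))
  RNifti::writeNifti(nii, path)
  invisible(path)
}
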