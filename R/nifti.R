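#' Extract trial-wise ROI patterns from volumetric data
#'
#' Optional volumetric entry point: pulls a trials-by-voxels matrix out of a
#' 4D stack of trial-wise beta volumes using a binary 3D mask. Volumes and
#' mask may be NIfTI file paths (read with RNifti) or plain arrays. Columns
#' follow the ascending linear index of the mask array in storage
#' (column-major) order, a stable convention recorded in the column names
#' (`vox<linear index>`).
#'
#' @param beta_volumes 4D numeric array (x, y, z, trial) or NIfTI path.
#' @param mask 3D binary array or NIfTI path on the same grid.
#' @param trial_ids Trial ids, one per volume.
#' @return Trials-by-voxels matrix with `trial_ids` as row names.
#' @export
extract_roi_patterns <- function(beta_volumes, mask, trial_ids) {
  as_vol <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("reading NIfTI paths requires the RNifti package")
      }
      x <- RNifti::readNifti(x)
    }
    unclass(as.array(x))
  }
  vols <- as_vol(beta_volumes)
  msk <- as_vol(mask)
  if (length(dim(vols)) != 4) stop("beta_volumes must be a 4D volume")
  if (length(dim(msk)) != 3) stop("mask must be a 3D volume")
  if (!identical(dim(vols)[1:3], dim(msk))) {
    stop("grid mismatch: volumes are ",
         paste(dim(vols)[1:3], collapse = "x"), ", mask is ",
         paste(dim(msk), collapse = "x"))
  }
  if (dim(vols)[4] != length(trial_ids)) {
    stop("number of volumes (", dim(vols)[4],
         ") != number of trial ids (", length(trial_ids), ")")
  }
  vals <- unique(as.vector(msk))
  if (!all(vals %in% c(0, 1))) {
    stop("mask must be binary (0/1); found values: ",
         paste(utils::head(setdiff(vals, c(0, 1)), 5), collapse = ", "))
  }
  idx <- which(as.vector(msk) == 1)
  if (!length(idx)) stop("mask is empty (no nonzero voxels)")
  n_trial <- dim(vols)[4]
  flat <- matrix(as.vector(vols), ncol = n_trial)
  out <- t(flat[idx, , drop = FALSE])
  dimnames(out) <- list(as.character(trial_ids), paste0("vox", idx))
  out
}
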