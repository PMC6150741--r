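#' Write a study (volume + mask) as NIfTI
#'
#' Writes `<subject>_d<day>_r<reader>_{vol,mask}.nii.gz` into `dir` and
#' appends a row to the manifest CSV (columns `subject_id, day, volume_path,
#' mask_path, reader_id`).
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param dir output directory.
#' @param subject_id,day,reader_id manifest fields.
#' @param manifest path of the manifest CSV to append to (created with a
#'   header if absent); `NULL` skips the manifest.
#' @return invisibly, a named list with the two file paths.
#' @export
write_study <- function(volume, mask, dir, subject_id, day, reader_id = 1L,
                        manifest = file.path(dir, "manifest.csv")) {
  check_same_grid(volume, mask)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- sprintf("%s_d%d_r%d", subject_id, as.integer(day),
                  as.integer(reader_id))
  vol_path <- file.path(dir, paste0(stem, "_vol.nii.gz"))
  mask_path <- file.path(dir, paste0(stem, "_mask.nii.gz"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, vol_path)
  msk <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(msk) <- volume$voxel_size
  RNifti::writeNifti(msk, mask_path)
  if (!is.null(manifest)) {
    row <- data.frame(subject_id = subject_id, day = as.integer(day),
                      volume_path = vol_path, mask_path = mask_path,
                      reader_id = as.integer(reader_id))
    utils::write.table(row, manifest, sep = ",", row.names = FALSE,
                       col.names = !file.exists(manifest), append = file.exists(manifest))
  }
  invisible(list(volume_path = vol_path, mask_path = mask_path))
}

#' Read a study written by [write_study()]
#'
#' @param volume_path,mask_path NIfTI file paths.
#' @return list with `volume` ([image_volume()]) and `mask` ([roi_mask()]).
#' @export
read_study <- function(volume_path, mask_path) {
  if (!file.exists(volume_path)) stop("volume file not found: ", volume_path)
  if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
  img <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  vs <- RNifti::pixdim(img)[1:3]
  vol <- image_volume(array(as.numeric(img), dim = dim(img)[1:3]), vs)
  mask <- roi_mask(array(as.numeric(msk), dim = dim(msk)[1:3]) > 0.5)
  check_same_grid(vol, mask)
  list(volume = vol, mask = mask)
}

#' Read a cohort manifest
#'
#' @param path manifest CSV produced by [simulate_cohort()]/[write_study()].
#' @return data.frame with columns subject_id, day, volume_path, mask_path,
#'   reader_id.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "day", "volume_path", "mask_path", "reader_id")
  if (!all(need %in% names(m))) {
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  }
  m
}
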