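#' Read a CT slice from a NIfTI file
#'
#' Reads a single-slice (2-D, or 3-D with a singleton third dimension)
#' NIfTI image of calibrated Hounsfield units. Pixel spacing is taken from
#' the NIfTI header; any scale slope/intercept declared in the header is
#' applied by the reader, so the returned values are calibrated HU.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param roi Optional logical matrix ROI (see [ct_slice()]).
#' @return A [ct_slice()].
#' @export
read_ct_nifti <- function(path, roi = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1) arr <- arr[, , 1]
  if (length(dim(arr)) != 2)
    stop("expected a single axial slice (2-D NIfTI, or 3-D with one slice)")
  sp <- RNifti::pixdim(img)[1:2]
  ct_slice(matrix(as.numeric(arr), nrow(arr), ncol(arr)), sp, roi = roi,
           source = path)
}

#' Write a CT slice (or phantom) to NIfTI with a ground-truth sidecar
#'
#' HU values are stored as signed 16-bit integers with the pixel spacing
#' in the NIfTI header. When phantom ground truth is supplied it is
#' written alongside as a JSON sidecar (`<path>.json`, label matrix
#' omitted).
#'
#' @param slice A [ct_slice()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param truth Optional ground-truth list from [generate_l3_phantom()].
#' @return `path`, invisibly.
#' @export
write_ct_nifti <- function(slice, path, truth = NULL) {
  stopifnot(inherits(slice, "ct_slice"))
  img <- RNifti::asNifti(round(slice$hu))
  RNifti::pixdim(img) <- slice$spacing_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  if (!is.null(truth)) {
    side <- truth[setdiff(names(truth), "labels")]
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a PET volume from a NIfTI file
#'
#' The voxel values are interpreted as activity concentration in kBq/ml;
#' spacing comes from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [pet_volume()].
#' @export
read_pet_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3-D PET volume")
  pet_volume(array(as.numeric(arr), dim(arr)), RNifti::pixdim(img)[1:3])
}

#' Write a PET volume to NIfTI
#'
#' @param volume A [pet_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pet_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated cohort to CSV
#'
#' Column layout: `patient_id, sex, age, height_cm, weight_kg,
#' injected_mbq, uptake_min, true_sma_cm2, true_fat_cm2` (plus `bmi`).
#'
#' @param cohort A data frame from [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV path with the [write_cohort_csv()] column layout.
#' @return Data frame of class `cohort`.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "height_cm", "weight_kg")
  if (!all(need %in% names(out)))
    stop("cohort CSV missing required columns: ",
         paste(setdiff(need, names(out)), collapse = ", "))
  class(out) <- c("cohort", "data.frame")
  out
}
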