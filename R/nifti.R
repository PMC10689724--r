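# NIfTI I/O for multi-modal volumes and masks (via RNifti).

#' Write a multi-modal volume (and optional mask) as NIfTI
#'
#' One `.nii.gz` per modality (`<prefix>_<modality>.nii.gz`) plus
#' `<prefix>_mask.nii.gz`; a JSON sidecar `<prefix>_spec.json` records
#' `meta` (e.g. the phantom spec).
#'
#' @param vol A [multimodal_volume()].
#' @param prefix Output path prefix.
#' @param mask Optional binary 3D array.
#' @param meta Optional list serialized to the JSON sidecar.
#' @return The written file paths, invisibly.
#' @export
write_volume_nifti <- function(vol, prefix, mask = NULL, meta = NULL) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (mod in names(vol$data)) {
    path <- paste0(prefix, "_", mod, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(vol$data[[mod]],
                                       pixdim = vol$spacing), path)
    paths <- c(paths, path)
  }
  if (!is.null(mask)) {
    path <- paste0(prefix, "_mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask)),
                                       pixdim = vol$spacing), path)
    paths <- c(paths, path)
  }
  if (!is.null(meta)) {
    path <- paste0(prefix, "_spec.json")
    jsonlite::write_json(meta, path, auto_unbox = TRUE, null = "null")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a multi-modal volume from NIfTI files
#'
#' @param paths Named character vector or list mapping modality names
#'   (`FLAIR`, `T1w`, `T2w`) to `.nii/.nii.gz` files.
#' @return A [multimodal_volume()].
#' @export
read_volume_nifti <- function(paths) {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  data <- lapply(paths, function(p) {
    a <- RNifti::readNifti(p)
    array(as.numeric(a), dim(a))
  })
  spacing <- RNifti::pixdim(RNifti::readNifti(paths[[1]]))[1:3]
  multimodal_volume(data, spacing = spacing)
}

#' Read a binary mask from NIfTI
#'
#' @param path A `.nii/.nii.gz` file.
#' @export
read_mask_nifti <- function(path) {
  a <- RNifti::readNifti(path)
  m <- array(as.integer(as.numeric(a) > 0.5), dim(a))
  m
}
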