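# Standard-format I/O: labeled volumes as paired NIfTI files (4-D float64
# image with a trailing channel axis + 3-D integer label map) with a JSON
# sidecar recording provenance, and probability maps as 3-D NIfTI.

#' Write a labeled volume as paired NIfTI files
#'
#' The image is stored as a 4-D float64 volume `(X, Y, Z, channel)` (channel
#' on the 4th axis, the in-memory layout being channel-first), labels as a
#' 3-D integer volume on the same grid. A JSON sidecar
#' (`<image>.json`) records the seed and any generation config supplied.
#' Files are written uncompressed so re-writes of identical data are
#' byte-identical.
#'
#' @param volume a [labeled_volume()].
#' @param image_path path for the intensity image (`.nii`).
#' @param label_path path for the label map (`.nii`).
#' @param config optional generation config stored in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_volume <- function(volume, image_path, label_path, config = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  img <- RNifti::asNifti(aperm(volume$intensities, c(2, 3, 4, 1)))
  RNifti::pixdim(img) <- c(volume$spacing, 1)
  RNifti::writeNifti(img, image_path, datatype = "double")
  lab <- RNifti::asNifti(volume$labels)
  RNifti::pixdim(lab) <- volume$spacing
  RNifti::writeNifti(lab, label_path, datatype = "int16")
  sidecar <- paste0(image_path, ".json")
  meta <- list(seed = volume$seed, spacing = volume$spacing,
               labels = c("background", "parenchyma", "viable", "necrosis"))
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read a labeled volume from paired NIfTI files
#'
#' @param image_path 4-D (or 3-D single-channel) intensity NIfTI.
#' @param label_path 3-D integer label NIfTI on the same grid.
#' @return A [labeled_volume()].
#' @export
read_volume <- function(image_path, label_path) {
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(label_path)
  ai <- as.array(img)
  if (length(dim(ai)) == 3L) dim(ai) <- c(dim(ai), 1L)
  al <- as.array(lab)
  if (!identical(dim(ai)[1:3], dim(al)))
    stopf("image grid %s does not match label grid %s",
          paste(dim(ai)[1:3], collapse = "x"), paste(dim(al), collapse = "x"))
  if (max(abs(al - round(al))) > 1e-6) stopf("label volume is not integer-valued")
  pix <- attr(img, "pixdim") %||% c(1, 1, 1)
  seed <- NA_integer_
  sidecar <- paste0(image_path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    seed <- meta$seed %||% NA_integer_
  }
  labeled_volume(aperm(ai, c(4, 1, 2, 3)), array(as.integer(round(al)), dim(al)),
                 spacing = as.numeric(pix[1:3]), seed = seed)
}

#' Write a probability map as NIfTI
#'
#' @param map a [probability_map()].
#' @param path output path (`.nii` / `.nii.gz`).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(map, "probability_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a probability map from NIfTI
#'
#' @param path NIfTI file of scores in `[0, 1]`.
#' @param semantics semantics tag for the map.
#' @export
read_map <- function(path, semantics = "fcn_output") {
  a <- as.array(RNifti::readNifti(path))
  probability_map(array(as.numeric(a), dim(a)), semantics = semantics)
}
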