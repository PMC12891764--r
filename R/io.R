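# File interfaces: volumes as NIfTI with correct voxel spacing, ground
# truth and ROI/landmark sets as JSON sidecars, cohorts as CSV.

# Ground-truth elements that are cheap enough to serialize to JSON.
.gtForSidecar <- function(gt) {
  drop <- c("lumenMask", "trueVelocityCms")
  gt[setdiff(names(gt), drop)]
}

#' Write / read a Volume3D as NIfTI with a JSON ground-truth sidecar
#'
#' @param volume a \code{Volume3D}
#' @param path output path ending in \code{.nii} or \code{.nii.gz}; the
#'   sidecar replaces that suffix with \code{.json}
#' @return \code{writeVolume}: the path, invisibly. \code{readVolume}: a
#'   \code{Volume3D} (ground truth restored from the sidecar when present,
#'   with data.frames/matrices as plain lists).
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume3D"))
  img <- RNifti::asNifti(volData(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, path)
  gt <- groundTruth(volume)
  if (length(gt)) {
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(.gtForSidecar(gt), side, digits = NA,
                         auto_unbox = TRUE, dataframe = "columns")
  }
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  gt <- list()
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(side)) gt <- jsonlite::read_json(side, simplifyVector = TRUE)
  dat <- array(as.numeric(img), dim = dim(img))
  new("Volume3D", data = dat, spacingMm = as.numeric(sp[1:3]),
      groundTruth = as.list(gt))
}

#' Write / read a cine phase-contrast series
#'
#' The magnitude and velocity stacks are written as two 3D NIfTI files
#' (\code{<prefix>_mag.nii.gz}, \code{<prefix>_vel.nii.gz}) with a JSON
#' metadata sidecar (\code{<prefix>_meta.json}) holding VENC, cycle
#' duration, pixel area, direction label and serializable ground truth.
#'
#' @param series a \code{CinePCSeries}
#' @param prefix path prefix
#' @return \code{writeCineSeries}: the prefix, invisibly;
#'   \code{readCineSeries}: a \code{CinePCSeries}
#' @export
writeCineSeries <- function(series, prefix) {
  stopifnot(is(series, "CinePCSeries"))
  sp <- c(voxelSpacing(series), 1)
  for (part in c("mag", "vel")) {
    arr <- if (part == "mag") series@magnitude else series@velocityCms
    attributes(arr)[setdiff(names(attributes(arr)), "dim")] <- NULL
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, paste0(prefix, "_", part, ".nii.gz"))
  }
  meta <- list(vencCms = series@vencCms, cycleMs = series@cycleMs,
               pixelAreaMm2 = series@pixelAreaMm2,
               spacingMm = voxelSpacing(series),
               positiveDirection = series@positiveDirection,
               groundTruth = .gtForSidecar(groundTruth(series)))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(prefix)
}

#' @rdname writeCineSeries
#' @export
readCineSeries <- function(prefix) {
  mag <- RNifti::readNifti(paste0(prefix, "_mag.nii.gz"))
  vel <- RNifti::readNifti(paste0(prefix, "_vel.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  new("CinePCSeries",
      magnitude = array(as.numeric(mag), dim = dim(mag)),
      velocityCms = array(as.numeric(vel), dim = dim(vel)),
      vencCms = meta$vencCms, cycleMs = meta$cycleMs,
      pixelAreaMm2 = meta$pixelAreaMm2,
      spacingMm = as.numeric(meta$spacingMm),
      positiveDirection = meta$positiveDirection,
      groundTruth = as.list(meta$groundTruth))
}

#' Write / read ROI polygons and landmarks as JSON
#'
#' Stores a named list whose elements are polygons/points (matrices or
#' numeric vectors of 0-based pixel coordinates) or nested lists thereof.
#'
#' @param rois named list
#' @param path JSON path
#' @return \code{writeRois}: the path invisibly; \code{readRois}: the list
#'   with matrices restored
#' @export
writeRois <- function(rois, path) {
  jsonlite::write_json(rois, path, digits = NA)
  invisible(path)
}

#' @rdname writeRois
#' @export
readRois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) if (is.data.frame(x)) as.matrix(x) else x)
}
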