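#' @include utils.R
NULL

#' Write a 3D array as a multi-page TIFF with a JSON sidecar
#'
#' Values are affinely mapped to `[0, 1]` for storage; the mapping
#' (`min`, `max`), array dimensions and any extra metadata are recorded
#' in `<path>.json` so [readVolumeTIFF()] restores the original values.
#' Slices along the third dimension become TIFF pages.
#'
#' @param arr 3D numeric or integer array.
#' @param path output TIFF path.
#' @param bitsPerSample 16 (labels/masks) or 32 (float data).
#' @param meta named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
writeVolumeTIFF <- function(arr, path, bitsPerSample = 32, meta = list()) {
  d <- dim(arr)
  stopifnot(length(d) == 3)
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample,
                  compression = "none")
  side <- c(list(min = lo, max = hi, dim = d,
                 storage = storage.mode(arr)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [writeVolumeTIFF()]
#'
#' @param path TIFF path (expects `<path>.json` beside it).
#' @return list with `data` (3D array, original values restored) and
#'   `meta` (sidecar contents).
#' @export
readVolumeTIFF <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(side$dim)
  arr <- array(0, d)
  for (k in seq_len(d[3])) arr[, , k] <- pages[[k]]
  arr <- arr * (side$max - side$min) + side$min
  if (identical(side$storage, "integer")) {
    arr <- round(arr)
    storage.mode(arr) <- "integer"
  }
  list(data = arr, meta = side)
}

#' Write a phantom to disk
#'
#' One multi-page TIFF per field (delta, beta, labels, thrombus) plus a
#' JSON sidecar with voxel size, grade, seed and optical constants.
#'
#' @param phantom a [Phantom-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(voxel_size_um = phantom@voxelSize, grade = phantom@grade,
               seed = phantom@seed, optical = phantom@optical)
  writeVolumeTIFF(phantom@delta, file.path(dir, "delta.tif"), meta = meta)
  writeVolumeTIFF(phantom@beta, file.path(dir, "beta.tif"), meta = meta)
  writeVolumeTIFF(phantom@labels, file.path(dir, "labels.tif"),
                  bitsPerSample = 16, meta = meta)
  writeVolumeTIFF(phantom@thrombus + 0L, file.path(dir, "thrombus.tif"),
                  bitsPerSample = 16, meta = meta)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a projection set to disk
#'
#' TIFF stacks for projections, flats and darks plus a JSON sidecar
#' describing the acquisition geometry and angles.
#'
#' @param ps a [ProjectionSet-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeProjectionSet <- function(ps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- ps@geometry
  meta <- list(energy_keV = g@energy, pixel_size_um = g@pixelSize,
               sdd_m = g@sdd, n_angles = g@nAngles,
               angular_range_deg = g@angularRange,
               flat_counts = g@flatCounts, dark_offset = g@darkOffset,
               n_flats = g@nFlats, n_darks = g@nDarks, seed = g@seed,
               angles_deg = ps@angles)
  writeVolumeTIFF(ps@projections, file.path(dir, "projections.tif"),
                  meta = meta["n_angles"])
  writeVolumeTIFF(ps@flats, file.path(dir, "flats.tif"))
  writeVolumeTIFF(ps@darks, file.path(dir, "darks.tif"))
  jsonlite::write_json(meta, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
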