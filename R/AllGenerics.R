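#' @include AllClasses.R
NULL

#' X-ray wavelength of a geometry
#'
#' Converts the beam energy to wavelength via lambda = hc/E
#' (12.398419 keV Angstrom), returned in metres.
#'
#' @param object an [AcquisitionGeometry-class].
#' @return wavelength in metres.
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname wavelength
setMethod("wavelength", "AcquisitionGeometry", function(object) {
  (12.398419 / object@energy) * 1e-10
})

#' Voxel edge length accessor
#' @param object a Phantom, ReconVolume or LabelVolume.
#' @return voxel size in micrometres.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname voxelSize
setMethod("voxelSize", "Phantom", function(object) object@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "ReconVolume", function(object) object@voxelSize)
#' @rdname voxelSize
setMethod("voxelSize", "LabelVolume", function(object) object@voxelSize)

#' Label array accessor
#' @param object a Phantom or LabelVolume.
#' @return 3D integer array of lumen ids (0 = background).
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))
#' @rdname labelArray
setMethod("labelArray", "Phantom", function(object) object@labels)
#' @rdname labelArray
setMethod("labelArray", "LabelVolume", function(object) object@labels)

#' Thrombus mask accessor
#' @param object a Phantom or LabelVolume.
#' @return 3D logical array.
#' @export
setGeneric("thrombusMask", function(object) standardGeneric("thrombusMask"))
#' @rdname thrombusMask
setMethod("thrombusMask", "Phantom", function(object) object@thrombus)
#' @rdname thrombusMask
setMethod("thrombusMask", "LabelVolume", function(object) object@thrombus)

#' Number of labelled lumina
#' @param object a Phantom or LabelVolume.
#' @return integer count of distinct lumen labels.
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))
#' @rdname nLabels
setMethod("nLabels", "Phantom", function(object) max(0L, max(object@labels)))
#' @rdname nLabels
setMethod("nLabels", "LabelVolume", function(object) max(0L, max(object@labels)))

#' Projection angles accessor
#' @param object a ProjectionSet or NormalizedSinograms.
#' @return numeric vector of angles in degrees.
#' @export
setGeneric("projectionAngles", function(object) standardGeneric("projectionAngles"))
#' @rdname projectionAngles
setMethod("projectionAngles", "ProjectionSet", function(object) object@angles)
#' @rdname projectionAngles
setMethod("projectionAngles", "NormalizedSinograms", function(object) object@angles)

#' Raw data array accessor
#' @param object a NormalizedSinograms or ReconVolume.
#' @return the underlying numeric array.
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname imageData
setMethod("imageData", "NormalizedSinograms", function(object) object@data)
#' @rdname imageData
setMethod("imageData", "ReconVolume", function(object) object@data)

setMethod("show", "AcquisitionGeometry", function(object) {
  cat("AcquisitionGeometry:", object@energy, "keV (lambda =",
      format(wavelength(object) * 1e10, digits = 5), "Angstrom),",
      object@pixelSize, "um pixels, SDD", object@sdd, "m\n")
  cat(" ", object@nAngles, "angles over", object@angularRange,
      "deg;", object@nFlats, "flats,", object@nDarks, "darks;",
      "flatCounts", object@flatCounts, "\n")
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@delta)
  cat("Phantom", paste(d, collapse = " x "), "voxels @",
      object@voxelSize, "um,", object@grade, "grade\n")
  cat(" ", nLabels(object), "sinusoid lumina;",
      sum(object@thrombus), "thrombus voxels; lumen fraction",
      format(mean(object@labels > 0), digits = 3), "\n")
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@projections)
  cat("ProjectionSet:", d[3], "projections of", d[1], "x", d[2],
      "pixels;", dim(object@flats)[3], "flats,", dim(object@darks)[3],
      "darks\n")
})

setMethod("show", "NormalizedSinograms", function(object) {
  d <- dim(object@data)
  cat("NormalizedSinograms:", d[3], "frames of", d[1], "x", d[2],
      "pixels; transmission range",
      paste(format(range(object@data), digits = 4), collapse = " .. "), "\n")
})

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@data)
  cat("ReconVolume", paste(d, collapse = " x "), "voxels @",
      object@voxelSize, "um\n")
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume", paste(dim(object@labels), collapse = " x "),
      "voxels @", object@voxelSize, "um;", nLabels(object),
      "lumina,", sum(object@thrombus), "thrombus voxels\n")
})
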