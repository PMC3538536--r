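#' @include sinusoidCT-package.R
NULL

#' Acquisition geometry of the virtual beamline
#'
#' Describes the monochromatic parallel-beam setup used for virtual CT
#' acquisition: beam energy, detector pitch, sample-to-detector
#' (propagation) distance, angular sampling and the flat/dark-field
#' protocol. Defaults mirror a synchrotron micro-CT protocol for soft
#' tissue: 16 keV, 9 um pixels, 1 m propagation distance, 1200
#' projections over 180 degrees, 20 flat and 10 dark fields.
#'
#' @slot energy beam energy, keV.
#' @slot pixelSize detector pixel pitch, micrometres.
#' @slot sdd sample-to-detector distance, metres.
#' @slot nAngles number of projection angles.
#' @slot angularRange total angular range, degrees.
#' @slot flatCounts expected photons per detector pixel in the open beam.
#' @slot darkOffset detector dark-current offset, counts.
#' @slot nFlats,nDarks number of flat- and dark-field frames.
#' @slot readNoiseSD Gaussian read-noise standard deviation, counts.
#' @slot gainVariation peak-to-mean relative amplitude of the smooth
#'   detector gain map (0 = uniform gain).
#' @slot seed RNG seed for noise realisations.
#' @exportClass AcquisitionGeometry
setClass("AcquisitionGeometry",
  representation(
    energy = "numeric", pixelSize = "numeric", sdd = "numeric",
    nAngles = "integer", angularRange = "numeric",
    flatCounts = "numeric", darkOffset = "numeric",
    nFlats = "integer", nDarks = "integer",
    readNoiseSD = "numeric", gainVariation = "numeric", seed = "integer"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  if (object@energy <= 0) msg <- c(msg, "energy must be > 0 keV")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@sdd < 0) msg <- c(msg, "sdd must be >= 0")
  if (object@nAngles < 1L) msg <- c(msg, "nAngles must be >= 1")
  if (object@angularRange <= 0 || object@angularRange > 360)
    msg <- c(msg, "angularRange must be in (0, 360]")
  if (object@nFlats < 0L || object@nDarks < 0L)
    msg <- c(msg, "nFlats/nDarks must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionGeometry
#'
#' @param energy beam energy in keV.
#' @param pixelSize detector pixel pitch in micrometres.
#' @param sdd sample-to-detector distance in metres.
#' @param nAngles number of projections over `angularRange`.
#' @param angularRange angular range in degrees (angles are uniformly
#'   spaced in `[0, angularRange)`).
#' @param flatCounts expected open-beam photons per pixel.
#' @param darkOffset dark-current offset in counts.
#' @param nFlats,nDarks number of flat/dark frames.
#' @param readNoiseSD Gaussian read noise SD in counts.
#' @param gainVariation relative amplitude of the smooth gain map.
#' @param seed RNG seed for the noise realisation.
#' @return An [AcquisitionGeometry-class] object.
#' @examples
#' g <- acquisitionGeometry(nAngles = 90)
#' wavelength(g)  # metres
#' @export
acquisitionGeometry <- function(energy = 16, pixelSize = 9, sdd = 1,
                                nAngles = 1200L, angularRange = 180,
                                flatCounts = 5000, darkOffset = 20,
                                nFlats = 20L, nDarks = 10L,
                                readNoiseSD = 2, gainVariation = 0,
                                seed = 1L) {
  new("AcquisitionGeometry",
    energy = energy, pixelSize = pixelSize, sdd = sdd,
    nAngles = as.integer(nAngles), angularRange = angularRange,
    flatCounts = flatCounts, darkOffset = darkOffset,
    nFlats = as.integer(nFlats), nDarks = as.integer(nDarks),
    readNoiseSD = readNoiseSD, gainVariation = gainVariation,
    seed = as.integer(seed))
}

#' Synthetic CHL tissue phantom
#'
#' Paired 3D fields of the x-ray refractive decrement delta and
#' absorption index beta (complex refractive index n = 1 - delta + i
#' beta), together with ground-truth integer labels for sinusoid lumina
#' and a boolean thrombus mask. Grades follow the pathology convention:
#' mild (isolated lacunae), moderate (partly conglutinated), severe
#' (lacunae dominate the tissue).
#'
#' @slot delta,beta 3D numeric arrays (dimensionless; delta ~ 1e-7,
#'   beta ~ 1e-10 for soft tissue at 16 keV).
#' @slot labels 3D integer array, 0 = parenchyma/background, k > 0 =
#'   sinusoid lumen id (26-connected components, consecutive).
#' @slot thrombus 3D logical array, subset of labelled voxels.
#' @slot voxelSize voxel edge length, micrometres.
#' @slot grade "mild", "moderate" or "severe".
#' @slot seed generator seed.
#' @slot optical named list of the optical constants used.
#' @exportClass Phantom
setClass("Phantom",
  representation(
    delta = "array", beta = "array", labels = "array",
    thrombus = "array", voxelSize = "numeric", grade = "character",
    seed = "integer", optical = "list"
  )
)

setValidity("Phantom", function(object) {
  msg <- character()
  d <- dim(object@delta)
  if (!identical(d, dim(object@beta)) || !identical(d, dim(object@labels)) ||
      !identical(d, dim(object@thrombus)))
    msg <- c(msg, "delta, beta, labels and thrombus must share one shape")
  if (any(object@delta < 0) || any(object@beta < 0))
    msg <- c(msg, "delta and beta must be non-negative")
  if (any(object@thrombus & object@labels == 0L))
    msg <- c(msg, "every thrombus voxel must lie inside a labelled lumen")
  if (!object@grade %in% c("mild", "moderate", "severe"))
    msg <- c(msg, "grade must be mild, moderate or severe")
  k <- max(object@labels)
  if (k > 0 && !setequal(setdiff(unique(as.integer(object@labels)), 0L), seq_len(k)))
    msg <- c(msg, "labels must be consecutive 1..K")
  if (length(msg)) msg else TRUE
})

#' Exit wave behind the sample
#'
#' Attenuation line-integral map B(x, y) = (2 pi / lambda) integral of
#' beta along the beam (dimensionless, >= 0) and phase-shift map
#' phi(x, y) = -(2 pi / lambda) integral of delta (radians, <= 0 for
#' positive delta), on the detector grid.
#'
#' @slot B,phi 2D numeric matrices of equal shape.
#' @slot pixelSize grid pitch, micrometres.
#' @exportClass ExitWave
setClass("ExitWave",
  representation(B = "matrix", phi = "matrix", pixelSize = "numeric"))

setValidity("ExitWave", function(object) {
  msg <- character()
  if (!identical(dim(object@B), dim(object@phi)))
    msg <- c(msg, "B and phi must have equal shape")
  if (any(!is.finite(object@B)) || any(!is.finite(object@phi)))
    msg <- c(msg, "B and phi must be finite")
  if (any(object@B < 0)) msg <- c(msg, "B must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Raw detector data of one CT scan
#'
#' Projection, flat-field and dark-field count images plus the
#' projection angles and the geometry that produced them. Frames are
#' stored with detector rows x columns in the first two dimensions and
#' the frame index last.
#'
#' @slot projections array `[rows, cols, nAngles]` of detector counts.
#' @slot flats array `[rows, cols, nFlats]`.
#' @slot darks array `[rows, cols, nDarks]`.
#' @slot angles projection angles, degrees.
#' @slot geometry the [AcquisitionGeometry-class].
#' @exportClass ProjectionSet
setClass("ProjectionSet",
  representation(projections = "array", flats = "array", darks = "array",
                 angles = "numeric", geometry = "AcquisitionGeometry"))

setValidity("ProjectionSet", function(object) {
  msg <- character()
  dp <- dim(object@projections)
  if (length(dp) != 3) msg <- c(msg, "projections must be a 3D array")
  if (dp[3] != length(object@angles))
    msg <- c(msg, "number of projection frames must match angles")
  if (!identical(dim(object@flats)[1:2], dp[1:2]) ||
      !identical(dim(object@darks)[1:2], dp[1:2]))
    msg <- c(msg, "flat/dark frame shape must match projections")
  if (any(object@projections < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Flat/dark-corrected sinogram stack
#'
#' Relative transmission values (open beam = 1); phase fringes may
#' locally exceed 1. Same frame layout as [ProjectionSet-class].
#'
#' @slot data array `[rows, cols, nAngles]`.
#' @slot angles projection angles, degrees.
#' @slot pixelSize detector pitch, micrometres.
#' @exportClass NormalizedSinograms
setClass("NormalizedSinograms",
  representation(data = "array", angles = "numeric", pixelSize = "numeric"))

setValidity("NormalizedSinograms", function(object) {
  if (any(!is.finite(object@data))) return("data must be finite")
  if (dim(object@data)[3] != length(object@angles))
    return("frame count must match angles")
  TRUE
})

#' Reconstructed 3D volume
#'
#' Filtered-back-projection output: a linear-attenuation-like scalar
#' field (per micrometre of path, arbitrary offset where phase fringes
#' contribute) with isotropic voxels.
#'
#' @slot data 3D numeric array `(N, N, nSlices)`.
#' @slot voxelSize voxel edge length, micrometres.
#' @exportClass ReconVolume
setClass("ReconVolume",
  representation(data = "array", voxelSize = "numeric"))

setValidity("ReconVolume", function(object) {
  if (any(!is.finite(object@data))) return("data must be finite")
  if (length(dim(object@data)) != 3) return("data must be a 3D array")
  TRUE
})

#' Segmented sinusoid label volume
#'
#' 26-connected sinusoid lumina numbered consecutively (largest first)
#' plus a thrombus mask restricted to labelled voxels.
#'
#' @slot labels 3D integer array (0 = background).
#' @slot thrombus 3D logical array, subset of `labels > 0`.
#' @slot voxelSize voxel edge length, micrometres.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", thrombus = "array", voxelSize = "numeric"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), dim(object@thrombus)))
    msg <- c(msg, "labels and thrombus must share one shape")
  if (any(object@thrombus & object@labels == 0L))
    msg <- c(msg, "thrombus mask must be a subset of labelled voxels")
  if (length(msg)) msg else TRUE
})
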