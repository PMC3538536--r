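#' @include utils.R
NULL

#' Project a phantom to an exit wave
#'
#' Parallel-beam line integrals of the absorption index and refractive
#' decrement over the phantom rotated about its z axis:
#' `B = (2 pi / lambda) * integral(beta dz)` and
#' `phi = -(2 pi / lambda) * integral(delta dz)` (phi <= 0 for positive
#' delta). The detector grid matches the phantom grid: one column per x
#' voxel, one row per z slice.
#'
#' @param phantom a [Phantom-class].
#' @param angle rotation angle in degrees.
#' @param geometry an [AcquisitionGeometry-class]; its `pixelSize` must
#'   equal the phantom's voxel size (no resampling is performed).
#' @return An [ExitWave-class].
#' @export
projectRefraction <- function(phantom, angle, geometry) {
  if (!isTRUE(all.equal(geometry@pixelSize, phantom@voxelSize)))
    stop("geometry pixelSize (", geometry@pixelSize,
         " um) must match phantom voxelSize (", phantom@voxelSize,
         " um); resampling is not supported")
  stopifnot(is.finite(angle))
  d <- dim(phantom@delta)
  lam <- wavelength(geometry)
  pathScale <- phantom@voxelSize * 1e-6  # voxel edge in metres
  pr <- cpp_forward_project2(phantom@beta, phantom@delta, d, deg2rad(angle))
  k <- 2 * pi / lam * pathScale
  # cpp output is [cols x rows(z) x 1]; store as rows x cols
  B <- t(matrix(pr$a, d[1], d[3])) * k
  phi <- -t(matrix(pr$b, d[1], d[3])) * k
  new("ExitWave", B = B, phi = phi, pixelSize = phantom@voxelSize)
}

# Squared spatial-frequency grid (cycles per metre) for an n1 x n2 FFT
# grid with the given pitch in metres.
freqSqGrid <- function(n1, n2, pitch) {
  f1 <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1] / (n1 * pitch)
  f2 <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2] / (n2 * pitch)
  outer(f1^2, f2^2, "+")
}

#' Fresnel free-space propagation of an exit wave
#'
#' Propagates the complex exit wave `psi = exp(-B + i phi)` over the
#' sample-to-detector distance with the angular-spectrum Fresnel kernel
#' `H(u, v) = exp(-i pi lambda z (u^2 + v^2))` and returns the detected
#' intensity `|psi_z|^2` in relative units (unit incident beam). At
#' `z = 0` this is exactly the contact image `exp(-2B)`. The wave is
#' symmetrically zero-padded (in B and phi, i.e. unit amplitude) before
#' the frequency-domain product to suppress wrap-around.
#'
#' @param wave an [ExitWave-class].
#' @param geometry an [AcquisitionGeometry-class] supplying wavelength
#'   and propagation distance.
#' @param pad padding factor (>= 1); 2 doubles each grid side.
#' @return numeric matrix of relative intensities (>= 0).
#' @export
fresnelPropagate <- function(wave, geometry, pad = 2) {
  if (any(!is.finite(wave@B)) || any(!is.finite(wave@phi)))
    stop("non-finite exit wave")
  d <- dim(wave@B)
  n1 <- ceiling(d[1] * pad); n2 <- ceiling(d[2] * pad)
  psi <- matrix(complex(real = 1), n1, n2)
  psi[seq_len(d[1]), seq_len(d[2])] <- exp(complex(real = -wave@B,
                                                   imaginary = wave@phi))
  z <- geometry@sdd
  if (z == 0) return(Mod(psi[seq_len(d[1]), seq_len(d[2])])^2)
  lam <- wavelength(geometry)
  H <- exp(complex(imaginary = -pi * lam * z *
                     freqSqGrid(n1, n2, wave@pixelSize * 1e-6)))
  out <- fft(fft(psi) * H, inverse = TRUE) / (n1 * n2)
  Mod(out[seq_len(d[1]), seq_len(d[2])])^2
}

# Linearised (weak-object) single-distance intensity: the Fourier-space
# transfer form I_z^hat = delta_D - 2 B^hat cos(pi lambda z f^2)
# - 2 phi^hat sin(pi lambda z f^2), kept as an independent oracle for
# the full propagator in the weak-phase limit.
weakObjectIntensity <- function(wave, geometry, pad = 2) {
  d <- dim(wave@B)
  n1 <- ceiling(d[1] * pad); n2 <- ceiling(d[2] * pad)
  B <- matrix(0, n1, n2); P <- matrix(0, n1, n2)
  B[seq_len(d[1]), seq_len(d[2])] <- wave@B
  P[seq_len(d[1]), seq_len(d[2])] <- wave@phi
  chi <- pi * wavelength(geometry) * geometry@sdd *
    freqSqGrid(n1, n2, wave@pixelSize * 1e-6)
  Ih <- -2 * fft(B) * cos(chi) - 2 * fft(P) * sin(chi)
  out <- 1 + Re(fft(Ih, inverse = TRUE)) / (n1 * n2)
  out[seq_len(d[1]), seq_len(d[2])]
}

#' Transport-of-intensity (TIE) near-field intensity
#'
#' Weak-absorption near-field approximation
#' `I_z = exp(-2B) * (1 - (lambda z / 2 pi) Laplacian(phi))`: the
#' phase-contrast signal is proportional to the Laplacian of the phase
#' shift, which is what produces the characteristic edge enhancement at
#' tissue interfaces. The Laplacian uses 5-point finite differences at
#' the detector pitch with replicated edges.
#'
#' @inheritParams fresnelPropagate
#' @return numeric matrix of relative intensities.
#' @export
tieIntensity <- function(wave, geometry) {
  if (any(!is.finite(wave@B)) || any(!is.finite(wave@phi)))
    stop("non-finite exit wave")
  h <- wave@pixelSize * 1e-6
  p <- wave@phi
  n1 <- nrow(p); n2 <- ncol(p)
  up <- p[c(1, seq_len(n1 - 1)), ]; dn <- p[c(seq_len(n1 - 1) + 1, n1), ]
  lf <- p[, c(1, seq_len(n2 - 1))]; rt <- p[, c(seq_len(n2 - 1) + 1, n2)]
  lap <- (up + dn + lf + rt - 4 * p) / h^2
  exp(-2 * wave@B) * (1 - wavelength(geometry) * geometry@sdd / (2 * pi) * lap)
}

# Smooth multiplicative detector gain map (deterministic in the
# geometry seed): low-frequency Gaussian random field scaled to the
# requested peak relative amplitude around 1.
gainMap <- function(rows, cols, variation, seed) {
  if (variation <= 0) return(matrix(1, rows, cols))
  withSeed(seed + 101L, {
    g <- matrix(rnorm(rows * cols), rows, cols)
    g <- gaussianSmooth(g, sigma = max(rows, cols) / 8)
    g <- g - mean(g)
    m <- max(abs(g))
    1 + if (m > 0) variation * g / m else 0
  })
}

#' Simulate a complete CT acquisition
#'
#' For each of `nAngles` angles uniformly spaced over the angular range,
#' forms the exit wave, Fresnel-propagates it to the detector, scales by
#' the open-beam photon count and the detector gain map, adds the
#' dark-current offset and (optionally) Poisson counting noise plus
#' Gaussian read noise. Flat fields are beam-only frames; dark fields
#' are offset plus read noise only. Deterministic per geometry seed.
#'
#' @param phantom a [Phantom-class].
#' @param geometry an [AcquisitionGeometry-class].
#' @param noise logical; simulate counting/read noise.
#' @param verbose print progress every 100 angles.
#' @return A [ProjectionSet-class].
#' @export
acquireDataset <- function(phantom, geometry, noise = TRUE, verbose = FALSE) {
  validObject(geometry)
  if (noise && geometry@flatCounts <= 0)
    stop("flatCounts must be > 0 when noise is enabled")
  d <- dim(phantom@delta)
  rows <- d[3]; cols <- d[1]
  angles <- (seq_len(geometry@nAngles) - 1) * geometry@angularRange /
    geometry@nAngles
  gain <- gainMap(rows, cols, geometry@gainVariation, geometry@seed)
  proj <- array(0, c(rows, cols, geometry@nAngles))
  withSeed(geometry@seed, {
    for (a in seq_along(angles)) {
      wave <- projectRefraction(phantom, angles[a], geometry)
      I <- fresnelPropagate(wave, geometry)
      expected <- gain * geometry@flatCounts * I
      if (noise) {
        proj[, , a] <- rpois(length(expected), expected) +
          pmax(0, round(geometry@darkOffset +
                          rnorm(length(expected), 0, geometry@readNoiseSD)))
      } else {
        proj[, , a] <- expected + geometry@darkOffset
      }
      if (verbose && a %% 100 == 0)
        message("  projection ", a, "/", length(angles))
    }
    flats <- array(0, c(rows, cols, max(1L, geometry@nFlats)))
    for (f in seq_len(dim(flats)[3])) {
      expected <- gain * geometry@flatCounts
      flats[, , f] <- if (noise) {
        rpois(length(expected), expected) +
          pmax(0, round(geometry@darkOffset +
                          rnorm(length(expected), 0, geometry@readNoiseSD)))
      } else expected + geometry@darkOffset
    }
    darks <- array(0, c(rows, cols, max(1L, geometry@nDarks)))
    for (f in seq_len(dim(darks)[3])) {
      darks[, , f] <- if (noise) {
        pmax(0, round(geometry@darkOffset +
                        rnorm(rows * cols, 0, geometry@readNoiseSD)))
      } else geometry@darkOffset
    }
    new("ProjectionSet", projections = proj, flats = flats, darks = darks,
        angles = angles, geometry = geometry)
  })
}
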