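#' @include utils.R
NULL

#' Flat- and dark-field correction
#'
#' Converts raw counts to relative transmission
#' `T = (P - Dbar) / (Fbar - Dbar)` with `Dbar`, `Fbar` the pixelwise
#' means over the dark and flat frames. Dead pixels (flat-minus-dark
#' below `epsFrac` of its dynamic range) are replaced per frame by the
#' median of their valid 3x3 neighbourhood and reported via a message.
#'
#' @param raw a [ProjectionSet-class] with at least one flat and dark.
#' @param epsFrac dead-pixel threshold as a fraction of the
#'   flat-minus-dark dynamic range.
#' @return A [NormalizedSinograms-class].
#' @export
flatDarkCorrect <- function(raw, epsFrac = 1e-6) {
  stopifnot(dim(raw@flats)[3] >= 1, dim(raw@darks)[3] >= 1)
  Fbar <- apply(raw@flats, c(1, 2), mean)
  Dbar <- apply(raw@darks, c(1, 2), mean)
  denom <- Fbar - Dbar
  rngd <- max(denom) - min(denom)
  eps <- epsFrac * max(abs(denom), rngd)
  dead <- denom <= eps
  if (all(dead)) stop("correction impossible: all detector pixels are dead")
  d <- dim(raw@projections)
  out <- array(0, d)
  for (a in seq_len(d[3])) {
    out[, , a] <- (raw@projections[, , a] - Dbar) / ifelse(dead, 1, denom)
  }
  if (any(dead)) {
    message(sum(dead), " dead detector pixel(s) filled from neighbours")
    idx <- which(dead, arr.ind = TRUE)
    for (a in seq_len(d[3])) {
      fr <- out[, , a]
      for (p in seq_len(nrow(idx))) {
        i <- idx[p, 1]; j <- idx[p, 2]
        ii <- max(1, i - 1):min(d[1], i + 1)
        jj <- max(1, j - 1):min(d[2], j + 1)
        nb <- fr[ii, jj][!dead[ii, jj]]
        fr[i, j] <- if (length(nb)) median(nb) else 0
      }
      out[, , a] <- fr
    }
  }
  new("NormalizedSinograms", data = out, angles = raw@angles,
      pixelSize = raw@geometry@pixelSize)
}

#' Gaussian smoothing of each projection
#'
#' Suppresses counting noise by 2D Gaussian filtering within each
#' projection frame (never across angles). `strength` is the kernel
#' standard deviation in pixels; 0 returns the input bit-identically.
#'
#' @param sinograms a [NormalizedSinograms-class].
#' @param strength Gaussian sigma in pixels, >= 0.
#' @return A [NormalizedSinograms-class].
#' @export
smoothSinograms <- function(sinograms, strength) {
  stopifnot(strength >= 0)
  if (strength == 0) return(sinograms)
  sinograms@data <- gaussianSmooth(sinograms@data, strength, axes = c(1, 2))
  sinograms
}

#' Ring-artifact suppression by column-bias removal
#'
#' Stationary per-detector-pixel offsets survive flat correction and
#' backproject into concentric rings. For each detector pixel the mean
#' over all angles is computed; a running-median trend across detector
#' columns separates genuine object structure (smooth across columns)
#' from single-column biases, and the bias (centred so each frame's
#' mean is preserved) is subtracted from every angle.
#'
#' @param sinograms a [NormalizedSinograms-class].
#' @param window odd trend window in columns, >= 3.
#' @return A [NormalizedSinograms-class].
#' @export
ringCorrect <- function(sinograms, window = 9L) {
  window <- as.integer(window)
  stopifnot(window >= 3L, window %% 2L == 1L)
  d <- dim(sinograms@data)
  m <- apply(sinograms@data, c(1, 2), mean)
  w <- min(window, if (d[2] %% 2L == 0L) d[2] - 1L else d[2])
  trend <- t(apply(m, 1, function(r) stats::runmed(r, w, endrule = "median")))
  bias <- m - trend
  bias <- bias - mean(bias)
  sinograms@data <- sweep(sinograms@data, c(1, 2), bias, "-")
  sinograms
}

#' Unsharp-mask edge enhancement
#'
#' `out = in + amount * (in - Gaussian(in, radius))`, used after
#' reconstruction to highlight sinusoid boundaries; `amount = 0` is the
#' identity.
#'
#' @param sliceImage 2D numeric matrix (a reconstructed slice).
#' @param amount enhancement strength, >= 0.
#' @param radius Gaussian sigma of the low-pass, pixels.
#' @return matrix of the same shape.
#' @export
edgeEnhance <- function(sliceImage, amount, radius = 2) {
  stopifnot(amount >= 0)
  if (amount == 0) return(sliceImage)
  sliceImage + amount * (sliceImage - gaussianSmooth(sliceImage, radius))
}
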