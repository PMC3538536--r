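#' @include AllClasses.R
NULL

deg2rad <- function(x) x * pi / 180

# Discrete 1D Gaussian kernel, truncated at 4 sigma, normalised to sum 1.
gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing of a 2D or 3D array
#'
#' Applies a 1D Gaussian kernel (truncated at 4 sigma, reflected
#' borders) along the requested axes. `sigma = 0` returns the input
#' unchanged.
#'
#' @param x numeric array (2D matrices are treated as single-slice 3D).
#' @param sigma kernel standard deviation in pixels/voxels.
#' @param axes integer axes (1-based) to smooth along; default all.
#' @return array of the same shape as `x`.
#' @export
gaussianSmooth <- function(x, sigma, axes = seq_along(dim(x))) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  was2d <- length(d) == 2
  if (was2d) { dim(x) <- c(d, 1L); d <- dim(x) }
  k <- gaussianKernel1d(sigma)
  for (ax in axes) {
    if (d[ax] > 1) x <- cpp_convolve_axis(x, as.integer(d), k, as.integer(ax - 1))
  }
  dim(x) <- d
  if (was2d) dim(x) <- d[1:2]
  x
}

#' Otsu threshold of a numeric sample
#'
#' Classic between-class-variance-maximising threshold on a fixed-bin
#' histogram. Returns a value separating the two classes; values
#' strictly below the threshold fall in the lower class.
#'
#' @param x numeric vector or array.
#' @param nbins number of histogram bins.
#' @return the threshold value.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  if (!is.finite(r[1]) || r[1] == r[2])
    stop("no contrast: input is constant, cannot threshold")
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]; mtot <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  valid <- w0 > 0 & w0 < n
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mtot * w0[valid] - n * m0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  br[which.max(bcv) + 1L]
}

# Dice coefficient of two logical masks.
diceCoefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Sarle's bimodality coefficient of a sample (uniform ~ 5/9 = 0.555;
# larger values suggest bimodality).
bimodalityCoefficient <- function(x) {
  n <- length(x)
  if (n < 4) return(0)
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  z <- (x - m) / s
  g1 <- mean(z^3)
  g2 <- mean(z^4) - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# Cylinder mask of the tissue/reconstruction field of view (axis z);
# `shrink` subtracts an absolute number of voxels from the radius.
cylinderMask <- function(d, radiusFrac = 0.48, shrink = 0) {
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  r <- max(radiusFrac * min(d[1], d[2]) - shrink, 1)
  inPlane <- outer((seq_len(d[1]) - 1 - cx)^2, (seq_len(d[2]) - 1 - cy)^2, "+") <= r^2
  array(rep(inPlane, d[3]), dim = d)
}
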