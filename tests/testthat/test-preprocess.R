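makeProjSet <- function(proj, flats, darks, angles = NULL,
                        geometry = acquisitionGeometry(nAngles = dim(proj)[3])) {
  if (is.null(angles))
    angles <- (seq_len(dim(proj)[3]) - 1) * 180 / dim(proj)[3]
  new("ProjectionSet", projections = proj, flats = flats, darks = darks,
      angles = angles, geometry = geometry)
}

test_that("flat/dark correction maps P=F to 1 and P=D to 0", {
  set.seed(1)
  d <- c(16, 20, 5)
  Fl <- array(rep(900 + 100 * runif(prod(d[1:2])), 2), c(d[1:2], 2))
  Dk <- array(rep(30 + 5 * runif(prod(d[1:2])), 2), c(d[1:2], 2))
  projF <- array(Fl[, , 1], d)
  projD <- array(Dk[, , 1], d)
  tF <- flatDarkCorrect(makeProjSet(projF, Fl, Dk))
  expect_equal(max(abs(tF@data - 1)), 0, tolerance = 1e-12)
  tD <- flatDarkCorrect(makeProjSet(projD, Fl, Dk))
  expect_equal(max(abs(tD@data)), 0, tolerance = 1e-12)
})

test_that("flat/dark correction is invariant to a common count gain", {
  set.seed(2)
  d <- c(12, 12, 3)
  Fl <- array(1000 + 50 * runif(prod(c(d[1:2], 2))), c(d[1:2], 2))
  Dk <- array(20 + runif(prod(c(d[1:2], 2))), c(d[1:2], 2))
  P <- array(500 + 100 * runif(prod(d)), d)
  t1 <- flatDarkCorrect(makeProjSet(P, Fl, Dk))
  t2 <- flatDarkCorrect(makeProjSet(P * 3.7, Fl * 3.7, Dk * 3.7))
  expect_lt(max(abs(t1@data - t2@data)), 1e-10)
})

test_that("a fully dead detector raises a correction error", {
  d <- c(8, 8, 2)
  Fl <- array(50, c(d[1:2], 1)); Dk <- array(50, c(d[1:2], 1))
  expect_error(flatDarkCorrect(makeProjSet(array(50, d), Fl, Dk)),
               "dead")
})

test_that("gain-map variation is removed down to the Poisson floor", {
  # known smooth +-5% gain; after correction the background CV should
  # approach the Poisson-only prediction
  ph <- makeSinusoidPhantom(c(24, 24, 24), 9, "mild", 0,
                            diameterRange = c(60, 90), seed = 1)
  ph@delta[] <- 0; ph@beta[] <- 0  # open beam everywhere
  g <- acquisitionGeometry(nAngles = 6L, flatCounts = 5000, darkOffset = 20,
                           gainVariation = 0.05, readNoiseSD = 0, seed = 3)
  ps <- acquireDataset(ph, g, noise = TRUE)
  tcor <- flatDarkCorrect(ps)
  cv <- sd(tcor@data) / mean(tcor@data)
  cvPred <- sqrt(1 / 5000 * (1 + 1 / 20))
  expect_lt(abs(cv - cvPred) / cvPred, 0.2)
  # without correction the gain variation dominates the raw CV
  rawCV <- sd(ps@projections - 20) / mean(ps@projections - 20)
  expect_gt(rawCV, 1.2 * cvPred)
})

test_that("smoothing strength 0 is the identity and reduces noise as", {
  set.seed(3)
  d <- c(160, 160, 2)
  sino <- new("NormalizedSinograms",
              data = array(rnorm(prod(d)), d),
              angles = c(0, 90), pixelSize = 9)
  expect_identical(smoothSinograms(sino, 0)@data, sino@data)
  sm <- smoothSinograms(sino, 1)
  ratio <- var(as.numeric(sm@data)) / var(as.numeric(sino@data))
  # white-noise variance is reduced by the kernel's energy ~ 1/(4 pi s^2)
  expect_lt(abs(ratio - 1 / (4 * pi)) / (1 / (4 * pi)), 0.1)
  # a constant image is untouched
  cst <- new("NormalizedSinograms", data = array(0.7, d),
             angles = c(0, 90), pixelSize = 9)
  expect_lt(max(abs(smoothSinograms(cst, 1)@data - 0.7)), 1e-12)
})

test_that("ring correction removes single-column bias, keeps clean data", {
  set.seed(4)
  d <- c(6, 64, 40)  # rows x cols x angles
  base <- array(0.8, d)
  # genuine object structure varies across angles; add some
  for (a in seq_len(d[3]))
    base[, , a] <- base[, , a] + 0.05 * sin(2 * pi * a / d[3])
  biased <- base
  biased[, 20, ] <- biased[, 20, ] + 0.05
  sino <- new("NormalizedSinograms", data = biased,
              angles = (0:(d[3] - 1)) * 180 / d[3], pixelSize = 9)
  fixed <- ringCorrect(sino, 9L)
  resid <- fixed@data[, 20, ] - base[, 20, ]
  expect_lt(max(abs(resid)), 0.005)
  # each frame's mean is preserved
  mB <- apply(biased, 3, mean); mF <- apply(fixed@data, 3, mean)
  expect_lt(max(abs(mB - mF)), 1e-6)
  # ring-free input passes through nearly unchanged
  clean <- new("NormalizedSinograms", data = base,
               angles = sino@angles, pixelSize = 9)
  out <- ringCorrect(clean, 9L)
  dr <- max(base) - min(base)
  expect_lt(max(abs(out@data - base)), 0.01 * dr)
  # zero sinogram stays zero
  z <- new("NormalizedSinograms", data = array(0, d),
           angles = sino@angles, pixelSize = 9)
  expect_true(all(ringCorrect(z, 9L)@data == 0))
})

test_that("unsharp masking sharpens edges and fixes constants", {
  step <- matrix(rep(c(0, 1), each = 32), 64, 16)
  expect_identical(edgeEnhance(step, 0), step)
  enh <- edgeEnhance(step, 1.5, radius = 2)
  gIn <- max(abs(diff(step[, 8])))
  gOut <- max(abs(diff(enh[, 8])))
  expect_gt(gOut, gIn)
  cst <- matrix(0.4, 32, 32)
  expect_lt(max(abs(edgeEnhance(cst, 2, 3) - 0.4)), 1e-12)
})
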