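# Build a ReconVolume holding a synthetic two-valued "reconstruction":
# parenchyma at `hi`, lumina at `lo`, air outside the tissue cylinder.
twoValuedVolume <- function(lumenMask, lo = 1e-4, hi = 4e-4, air = -1e-4,
                            voxelSize = 9) {
  d <- dim(lumenMask)
  cyl <- sinusoidCT:::cylinderMask(d, 0.45)
  v <- array(air, d)
  v[cyl] <- hi
  v[lumenMask] <- lo
  new("ReconVolume", data = v, voxelSize = voxelSize)
}

cuboidMask <- function(d, lo, hi) {
  m <- array(FALSE, d)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

test_that("noise-free lumina are recovered exactly", {
  d <- c(64, 64, 64)
  lum <- cuboidMask(d, c(20, 20, 16), c(35, 33, 34)) |
    cuboidMask(d, c(38, 36, 38), c(49, 47, 52))
  vol <- twoValuedVolume(lum)
  lv <- segmentSinusoids(vol, presmoothSigma = 0)
  expect_equal(nLabels(lv), 2L)
  expect_identical(lv@labels > 0L, lum)
  # per-component Dice is exactly 1
  for (id in 1:2) {
    comp <- lv@labels == id
    expect_true(all(lum[comp]))
  }
})

test_that("ball lumina are recovered almost exactly despite staircasing", {
  d <- c(64, 64, 64)
  c1 <- digitalBall(10, 64)
  lum <- c1 & sinusoidCT:::cylinderMask(d, 0.45)
  vol <- twoValuedVolume(lum)
  lv <- segmentSinusoids(vol, presmoothSigma = 0)
  expect_equal(nLabels(lv), 1L)
  dice <- 2 * sum(lv@labels > 0 & lum) / (sum(lv@labels > 0) + sum(lum))
  expect_gt(dice, 0.99)
})

test_that("a constant volume raises a no-contrast error", {
  vol <- new("ReconVolume", data = array(0.5, c(24, 24, 24)), voxelSize = 9)
  expect_error(segmentSinusoids(vol), "no contrast")
})

test_that("a lumen-free tissue volume yields no labels", {
  d <- c(48, 48, 48)
  vol <- twoValuedVolume(array(FALSE, d))
  lv <- segmentSinusoids(vol, presmoothSigma = 0)
  expect_equal(nLabels(lv), 0L)
})

test_that("segmentation is idempotent on its own output", {
  d <- c(64, 64, 64)
  lum <- cuboidMask(d, c(22, 20, 18), c(40, 38, 36))
  vol <- twoValuedVolume(lum)
  lv1 <- segmentSinusoids(vol, presmoothSigma = 0)
  again <- twoValuedVolume(lv1@labels > 0L)
  lv2 <- segmentSinusoids(again, presmoothSigma = 0)
  expect_identical(lv1@labels, lv2@labels)
})

test_that("thrombi are segmented inside lumina only where bimodal", {
  d <- c(56, 56, 56)
  lum <- digitalBall(14, 56) & sinusoidCT:::cylinderMask(d, 0.45)
  thr <- digitalBall(7, 56)
  v <- twoValuedVolume(lum)
  v@data[thr] <- 5e-4  # denser thrombus core
  lv <- segmentSinusoids(v, presmoothSigma = 0)
  expect_equal(nLabels(lv), 1L)
  lv <- segmentThrombus(v, lv)
  dice <- 2 * sum(lv@thrombus & thr) / (sum(lv@thrombus) + sum(thr))
  expect_gt(dice, 0.95)
  # thrombus fraction close to (7/14)^3
  expect_lt(abs(thrombusFraction(lv, 1) - 12.5), 1.5)
  # containment invariant
  expect_true(all(lv@labels[lv@thrombus] > 0L))

  # uniform lumen interior -> empty mask
  v2 <- twoValuedVolume(lum)
  lv2 <- segmentSinusoids(v2, presmoothSigma = 0)
  lv2 <- segmentThrombus(v2, lv2)
  expect_equal(sum(lv2@thrombus), 0L)

  # empty label volume -> empty mask
  lv3 <- maskToLabelVolume(array(FALSE, d), 9)
  out <- segmentThrombus(v2, lv3)
  expect_equal(sum(out@thrombus), 0L)
})

test_that("labels are numbered consecutively by decreasing size", {
  d <- c(64, 64, 64)
  lum <- cuboidMask(d, c(16, 16, 16), c(25, 25, 25)) |      # small
    cuboidMask(d, c(32, 32, 32), c(47, 45, 44))             # large
  vol <- twoValuedVolume(lum)
  lv <- segmentSinusoids(vol, presmoothSigma = 0)
  m <- measureAllSinusoids(lv)
  expect_equal(m$label_id, c(1L, 2L))
  expect_true(m$volume[1] > m$volume[2])
})

test_that("the histogram threshold agrees with an independent Otsu", {
  set.seed(9)
  # overlapping modes give the objective a unique maximum (a gap with
  # no samples makes every threshold inside it optimal)
  img <- matrix(pmin(pmax(c(rnorm(3000, 0.35, 0.07),
                            rnorm(3000, 0.65, 0.07)), 0), 1), 60, 100)
  tOwn <- otsuThreshold(img, nbins = 256)
  tEb <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  expect_lt(abs(tOwn - tEb), 0.03)
  # both land in the gap between the modes
  expect_true(tOwn > 0.4 && tOwn < 0.6)
  expect_true(tEb > 0.4 && tEb < 0.6)
})
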