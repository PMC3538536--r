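test_that("a digital ball is measured to analytic accuracy", {
  lv <- maskToLabelVolume(digitalBall(20, 49), voxelSize = 9)
  m <- measureSinusoid(lv, 1)
  trueV <- 4 / 3 * pi * 180^3
  trueA <- 4 * pi * 180^2
  expect_lt(abs(m$volume - trueV) / trueV, 0.02)
  expect_lt(abs(m$surface_area - trueA) / trueA, 0.03)
  expect_lt(abs(m$min_diameter - 360) / 360, 0.05)
  expect_lt(abs(m$max_diameter - 360) / 360, 0.05)
  expect_true(m$min_diameter <= m$max_diameter)
  expect_error(measureSinusoid(lv, 3), "unknown label")
})

test_that("a single-voxel component has the exact voxel volume", {
  mask <- array(FALSE, c(7, 7, 7)); mask[4, 4, 4] <- TRUE
  lv <- maskToLabelVolume(mask, voxelSize = 9)
  m <- measureSinusoid(lv, 1)
  expect_identical(m$volume, 729)
  expect_true(m$min_diameter <= m$max_diameter)
})

test_that("a 3:1 prolate ellipsoid has a 3:1 diameter ratio", {
  lv <- maskToLabelVolume(digitalEllipsoid(9, 9, 27, 63), voxelSize = 9)
  m <- measureSinusoid(lv, 1)
  expect_lt(abs(m$max_diameter / m$min_diameter - 3) / 3, 0.1)
})

test_that("surface area obeys the isoperimetric inequality", {
  shapes <- list(digitalBall(12, 33), digitalEllipsoid(6, 10, 16, 41))
  for (s in shapes) {
    m <- measureSinusoid(maskToLabelVolume(s, 9), 1)
    expect_gt(m$surface_area^3, 36 * pi * m$volume^2 * 0.95)
  }
})

test_that("descriptors scale correctly with voxel size", {
  mask <- digitalEllipsoid(5, 7, 9, 27)
  m1 <- measureSinusoid(maskToLabelVolume(mask, 9), 1)
  m2 <- measureSinusoid(maskToLabelVolume(mask, 18), 1)
  expect_equal(m2$min_diameter, 2 * m1$min_diameter)
  expect_equal(m2$max_diameter, 2 * m1$max_diameter)
  expect_equal(m2$surface_area, 4 * m1$surface_area)
  expect_equal(m2$volume, 8 * m1$volume)
})

test_that("nested-sphere thrombus fraction recovers (1/2)^3", {
  outer <- digitalBall(16, 41)
  inner <- digitalBall(8, 41)
  lv <- maskToLabelVolume(outer, 9, thrombus = inner)
  tf <- thrombusFraction(lv, 1)
  expect_lt(abs(tf - 12.5), 0.5)
  expect_equal(measureSinusoid(lv, 1)$thrombus_fraction, tf)
  # no thrombus -> 0 %
  lv0 <- maskToLabelVolume(outer, 9)
  expect_identical(thrombusFraction(lv0, 1), 0)
  expect_error(thrombusFraction(lv0, 2), "unknown label")
})

test_that("thrombus fraction is invariant under 90-degree rotations", {
  outer <- digitalEllipsoid(6, 9, 12, 31)
  inner <- digitalEllipsoid(4, 5, 6, 31)
  lv <- maskToLabelVolume(outer, 9, thrombus = inner)
  tf0 <- thrombusFraction(lv, 1)
  rot <- function(a) aperm(a[, , dim(a)[3]:1], c(1, 3, 2))  # 90 deg about x
  lvr <- maskToLabelVolume(rot(outer), 9, thrombus = rot(inner))
  expect_identical(thrombusFraction(lvr, 1), tf0)
})

test_that("cohort summaries use sample SD and render as mean+-SD", {
  r <- data.frame(label_id = 1:3, min_diameter = c(1, 2, 3),
                  max_diameter = c(2, 4, 6), surface_area = c(1, 1, 1),
                  volume = c(10, 20, 30), thrombus_fraction = c(0, 0, 0))
  s <- summarizeMorphometry(r)
  expect_equal(s$mean[s$descriptor == "min_diameter"], 2)
  expect_equal(s$sd[s$descriptor == "min_diameter"], 1)
  expect_equal(s$formatted[s$descriptor == "min_diameter"], "2.00±1.00")
  expect_equal(attr(s, "n"), 3L)
  # single record: SD = 0 everywhere
  s1 <- summarizeMorphometry(r[1, ])
  expect_true(all(s1$sd == 0))
  expect_error(summarizeMorphometry(r[0, ]), "at least one")

  # independent two-pass oracle on simulated records
  set.seed(8)
  r20 <- data.frame(label_id = 1:20,
                    min_diameter = runif(20, 100, 300),
                    max_diameter = runif(20, 300, 900),
                    surface_area = runif(20, 1e5, 9e5),
                    volume = runif(20, 1e6, 4e7),
                    thrombus_fraction = runif(20, 0, 30))
  s20 <- summarizeMorphometry(r20)
  for (dsc in s20$descriptor) {
    x <- r20[[dsc]]
    mu <- sum(x) / length(x)
    sg <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    expect_lt(abs(s20$mean[s20$descriptor == dsc] - mu), 1e-10 * abs(mu))
    expect_lt(abs(s20$sd[s20$descriptor == dsc] - sg), 1e-10 * abs(sg))
  }
})

test_that("percent formatting matches the reporting convention", {
  expect_identical(formatPercent(0.1686), "16.86%")
  expect_identical(formatPercent(0), "0.00%")
})
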