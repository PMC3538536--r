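test_that("mild phantoms contain the requested number of isolated lumina", {
  ph <- makeSinusoidPhantom(c(128, 128, 128), 9, "mild", 5,
                            diameterRange = c(120, 400), seed = 42)
  expect_equal(nLabels(ph), 5L)
  d <- dim(ph@labels)
  # pairwise non-adjacency: dilating any one lumen must not touch another
  for (id in 1:5) {
    dil <- array(sinusoidCT:::cpp_morph_box3(ph@labels == id, d, TRUE), d)
    others <- ph@labels[dil]
    expect_true(all(others %in% c(0L, id)))
  }
  # independent flood-fill oracle on a smaller instance
  ph2 <- makeSinusoidPhantom(c(48, 48, 48), 9, "mild", 2,
                             diameterRange = c(60, 110), seed = 3)
  fc <- floodCount(ph2@labels > 0L)
  expect_equal(fc$count, 2L)
  expect_equal(nLabels(ph2), 2L)
})

test_that("an empty phantom is uniform parenchyma", {
  ph <- makeSinusoidPhantom(c(64, 64, 64), 9, "mild", 0,
                            diameterRange = c(120, 400), seed = 0)
  expect_true(all(ph@labels == 0L))
  inTissue <- ph@delta[ph@delta > 0]
  expect_true(all(inTissue == defaultOpticalConstants()$parenchyma$delta))
})

test_that("lumen volume fraction increases with grade at fixed seed and n", {
  fr <- sapply(c("mild", "moderate", "severe"), function(g) {
    ph <- makeSinusoidPhantom(c(72, 72, 72), 9, g, 4,
                              diameterRange = c(90, 200), seed = 11)
    mean(ph@labels > 0L)
  })
  expect_lt(fr["mild"], fr["moderate"])
  expect_lt(fr["moderate"], fr["severe"])
  # severe lacunae dominate the tissue cylinder
  phs <- makeSinusoidPhantom(c(72, 72, 72), 9, "severe", 4,
                             diameterRange = c(90, 200), seed = 11)
  cyl <- sinusoidCT:::cylinderMask(dim(phs@labels), 0.45)
  expect_gt(sum(phs@labels > 0L & cyl) / sum(cyl), 0.5)
})

test_that("phantom generation is bit-identical given the same seed", {
  a <- makeSinusoidPhantom(c(48, 48, 48), 9, "moderate", 3,
                           diameterRange = c(60, 120), seed = 99)
  b <- makeSinusoidPhantom(c(48, 48, 48), 9, "moderate", 3,
                           diameterRange = c(60, 120), seed = 99)
  expect_identical(a@delta, b@delta)
  expect_identical(a@labels, b@labels)
  c <- makeSinusoidPhantom(c(48, 48, 48), 9, "moderate", 3,
                           diameterRange = c(60, 120), seed = 100)
  expect_false(identical(a@labels, c@labels))
})

test_that("infeasible packing raises a placement-failure error", {
  expect_error(
    makeSinusoidPhantom(c(40, 40, 40), 9, "mild", 60,
                        diameterRange = c(90, 160), seed = 1,
                        maxRetries = 200),
    "placement failure")
})

test_that("thrombus construction is concentric with the requested fraction", {
  ph <- ballPhantom(16, n = 48)
  ph0 <- addThrombus(ph, 1, 0)
  expect_identical(ph0@thrombus, ph@thrombus)  # fraction 0 is a no-op

  ph1 <- addThrombus(ph, 1, 0.125)
  n <- sum(ph@labels == 1L)
  expect_lt(abs(sum(ph1@thrombus) / n - 0.125), 0.01)
  # concentric: thrombus of a ball at fraction (1/2)^3 is the ball of
  # half the radius
  expected <- digitalBall(8, 48)
  dice <- 2 * sum(ph1@thrombus & expected) / (sum(ph1@thrombus) + sum(expected))
  expect_gt(dice, 0.9)
  # containment invariant
  expect_true(all(ph1@labels[ph1@thrombus] > 0L))

  ph2 <- addThrombus(ph, 1, 0.1686)
  expect_lt(abs(sum(ph2@thrombus) / n - 0.1686), 0.01)
  expect_error(addThrombus(ph, 7, 0.1), "unknown label")
})

test_that("ground-truth morphometry matches analytic shapes", {
  ball <- digitalBall(20, 49)
  ph <- ballPhantom(20, n = 49)
  gt <- groundTruthMorphometry(ph)
  expect_equal(nrow(gt), 1L)
  expect_lt(abs(gt$true_volume - 4 / 3 * pi * 180^3) / (4 / 3 * pi * 180^3),
            0.02)
  # empty phantom gives an empty table
  ph0 <- makeSinusoidPhantom(c(32, 32, 32), 9, "mild", 0,
                             diameterRange = c(60, 90), seed = 1)
  expect_equal(nrow(groundTruthMorphometry(ph0)), 0L)
  # 3:1 prolate ellipsoid: axis ratio recovered within 10%
  ell <- digitalEllipsoid(8, 8, 24, 57)
  lab <- array(0L, dim(ell)); lab[ell] <- 1L
  phe <- new("Phantom", delta = ell * 1e-7, beta = ell * 1e-10,
             labels = lab, thrombus = array(FALSE, dim(ell)),
             voxelSize = 9, grade = "mild", seed = 0L,
             optical = defaultOpticalConstants())
  gte <- groundTruthMorphometry(phe)
  expect_lt(abs(gte$true_max_diameter / gte$true_min_diameter - 3) / 3, 0.1)
})
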