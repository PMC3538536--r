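test_that("energy-to-wavelength conversion matches hc/E", {
  g <- acquisitionGeometry(energy = 16)
  expect_lt(abs(wavelength(g) - 0.7749e-10) / 0.7749e-10, 1e-4)
})

test_that("default acquisition protocol matches the beamline settings", {
  g <- acquisitionGeometry()
  expect_equal(g@energy, 16)
  expect_equal(g@pixelSize, 9)
  expect_equal(g@sdd, 1)
  expect_equal(g@nAngles, 1200L)
  expect_equal(g@angularRange, 180)
  expect_equal(g@nFlats, 20L)
  expect_equal(g@nDarks, 10L)
})

test_that("projection line integrals follow the analytic chord length", {
  # beta = 0 everywhere -> B identically zero at every angle
  ph <- ballPhantom(12, n = 40, betaLumen = 0)
  g <- acquisitionGeometry(pixelSize = 9)
  for (a in c(0, 33.5, 90)) {
    w <- projectRefraction(ph, a, g)
    expect_true(all(w@B == 0))
    # rays missing the ball see nothing
    expect_equal(w@phi[1, 1], 0)
    expect_equal(w@phi[nrow(w@phi), ncol(w@phi)], 0)
  }
  # central ray through a uniform ball: phi = -(2 pi/lambda) delta 2R
  r <- 32
  ph2 <- ballPhantom(r, n = 72, deltaLumen = 3e-7)
  w <- projectRefraction(ph2, 0, g)
  centre <- ceiling((dim(ph2@delta) + 1) / 2)
  got <- w@phi[centre[3], centre[1]]
  expected <- -(2 * pi / wavelength(g)) * 3e-7 * (2 * r * 9e-6)
  expect_lt(abs(got - expected) / abs(expected), 0.01)
  expect_true(all(w@phi <= 0))
})

test_that("pixel/voxel size mismatch raises a geometry error", {
  ph <- ballPhantom(6, n = 20)
  g <- acquisitionGeometry(pixelSize = 5)
  expect_error(projectRefraction(ph, 0, g), "voxelSize")
})

test_that("Fresnel propagation at z = 0 is exactly the contact image", {
  w <- gaussianPhaseWave(64, phiPeak = -0.4, B0 = 0.02)
  g0 <- acquisitionGeometry(sdd = 0, pixelSize = 9)
  expect_equal(fresnelPropagate(w, g0), exp(-2 * w@B), tolerance = 1e-12)
})

test_that("constant exit waves propagate to uniform exp(-2B)", {
  n <- 48
  w <- new("ExitWave", B = matrix(0.05, n, n), phi = matrix(-0.3, n, n),
           pixelSize = 9)
  g <- acquisitionGeometry(sdd = 1, pixelSize = 9)
  # periodic (pad = 1) domain: zero spatial frequency only
  I <- fresnelPropagate(w, g, pad = 1)
  expect_equal(max(abs(I - exp(-0.1))), 0, tolerance = 1e-10)
})

test_that("free-space propagation preserves mean intensity", {
  w <- gaussianPhaseWave(96, phiPeak = -0.05, sigmaPx = 6, B0 = 0.01)
  g <- acquisitionGeometry(sdd = 1, pixelSize = 9)
  # |H| = 1: flux over the propagation domain is conserved exactly
  I <- fresnelPropagate(w, g, pad = 1)
  expect_lt(abs(mean(I) - mean(exp(-2 * w@B))) / mean(exp(-2 * w@B)), 1e-6)
  # with padding, a small leak past the crop is the only loss
  Ip <- fresnelPropagate(w, g)
  expect_lt(abs(mean(Ip) - mean(exp(-2 * w@B))) / mean(exp(-2 * w@B)), 1e-4)
})

test_that("full propagation agrees with the weak-object transfer form", {
  # independent linearised oracle, valid for |phi| << 1
  w <- gaussianPhaseWave(96, phiPeak = -0.02, sigmaPx = 6, B0 = 0.005)
  g <- acquisitionGeometry(sdd = 0.5, pixelSize = 9)
  full <- fresnelPropagate(w, g)
  lin <- sinusoidCT:::weakObjectIntensity(w, g)
  expect_lt(max(abs(full - lin)), 5e-4)
})

test_that("TIE intensity follows its closed forms", {
  n <- 64
  g <- acquisitionGeometry(sdd = 1, pixelSize = 9)
  # constant phase -> exp(-2B)
  w <- new("ExitWave", B = matrix(0.03, n, n), phi = matrix(-1, n, n),
           pixelSize = 9)
  expect_equal(tieIntensity(w, g), exp(-2 * w@B), tolerance = 1e-12)
  # quadratic phase a(x^2+y^2) -> uniform 1 - (lambda z / 2 pi) 4 a
  h <- 9e-6
  a <- 1e4  # rad / m^2
  x <- ((1:n) - (n + 1) / 2) * h
  phi <- outer(x^2, x^2, "+") * a
  w2 <- new("ExitWave", B = matrix(0, n, n), phi = phi, pixelSize = 9)
  I <- tieIntensity(w2, g)
  inner <- I[4:(n - 3), 4:(n - 3)]  # away from replicated edges
  expect_equal(mean(inner), 1 - wavelength(g) * 1 / (2 * pi) * 4 * a,
               tolerance = 1e-6)
})

test_that("acquisition is deterministic per seed and obeys count models", {
  ph <- ballPhantom(8, n = 28, deltaLumen = 1e-8, betaLumen = 1e-10)
  g <- acquisitionGeometry(nAngles = 4L, seed = 5, flatCounts = 3000,
                           darkOffset = 20)
  a <- acquireDataset(ph, g, noise = TRUE)
  b <- acquireDataset(ph, g, noise = TRUE)
  expect_identical(a@projections, b@projections)
  expect_identical(a@flats, b@flats)
  expect_true(all(a@projections == round(a@projections)))
  expect_true(all(a@projections >= 0))

  # flatCounts = 0 with noise off: every projection equals the offset
  g0 <- acquisitionGeometry(nAngles = 3L, flatCounts = 0, darkOffset = 7)
  p0 <- acquireDataset(ph, g0, noise = FALSE)
  expect_true(all(p0@projections == 7))
  # but flatCounts = 0 with noise on is a configuration error
  expect_error(acquireDataset(ph, g0, noise = TRUE), "flatCounts")

  # mean over the flats matches gain * flatCounts + offset within 3 SE
  flatMean <- mean(a@flats)
  se <- sqrt(3000 / (prod(dim(a@flats))))
  expect_lt(abs(flatMean - (3000 + 20)), 3 * se + 1)  # +1 for rounding bias
})

test_that("TIE converges to the Fresnel intensity at second order in z", {
  # fine pixels keep the finite-difference Laplacian error below the
  # genuine O(z^2) near-field term whose decay is being measured
  w <- gaussianPhaseWave(128, phiPeak = -0.1, sigmaPx = 12, B0 = 0,
                         pixelSize = 2)
  z1 <- 1
  err <- sapply(c(z1, z1 / 2), function(z) {
    g <- acquisitionGeometry(sdd = z, pixelSize = 2)
    max(abs(tieIntensity(w, g) - fresnelPropagate(w, g)))
  })
  expect_gt(err[1] / err[2], 3.8)
})
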