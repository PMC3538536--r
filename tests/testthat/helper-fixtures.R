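# Fixtures shared across test files. All fixtures are built in code.

# Logical 3D array containing a digital ball of radius r (in voxels)
# centred in a cube of side n.
digitalBall <- function(r, n = 2 * r + 9) {
  c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2, c(n, n, n))
}

# Axis-aligned digital ellipsoid with semi-axes (a, b, c) voxels.
digitalEllipsoid <- function(a, b, c, n = 2 * max(a, b, c) + 9) {
  c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array(((g$x - c0) / a)^2 + ((g$y - c0) / b)^2 + ((g$z - c0) / c)^2 <= 1,
        c(n, n, n))
}

# Wrap a logical mask as a LabelVolume with a single label.
maskToLabelVolume <- function(mask, voxelSize = 9, thrombus = NULL) {
  lab <- array(0L, dim(mask))
  lab[mask] <- 1L
  if (is.null(thrombus)) thrombus <- array(FALSE, dim(mask))
  new("LabelVolume", labels = lab, thrombus = thrombus,
      voxelSize = voxelSize)
}

# Phantom with a single centred ball lumen (for projection oracles).
ballPhantom <- function(r, n = 2 * r + 9, voxelSize = 9,
                        deltaLumen = 3e-7, betaLumen = 1.5e-10,
                        deltaBg = 0, betaBg = 0) {
  ball <- digitalBall(r, n)
  delta <- array(deltaBg, dim(ball)); beta <- array(betaBg, dim(ball))
  delta[ball] <- deltaLumen; beta[ball] <- betaLumen
  lab <- array(0L, dim(ball)); lab[ball] <- 1L
  new("Phantom", delta = delta, beta = beta, labels = lab,
      thrombus = array(FALSE, dim(ball)), voxelSize = voxelSize,
      grade = "mild", seed = 0L, optical = defaultOpticalConstants())
}

# Smooth weak exit wave: Gaussian phase blob (peak phiPeak radians) and
# optional constant absorption, on an n x n grid.
gaussianPhaseWave <- function(n = 128, phiPeak = -0.1, sigmaPx = 8,
                              B0 = 0, pixelSize = 9) {
  c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n)
  phi <- phiPeak * exp(-((g$x - c0)^2 + (g$y - c0)^2) / (2 * sigmaPx^2))
  new("ExitWave", B = matrix(B0, n, n), phi = matrix(phi, n, n),
      pixelSize = pixelSize)
}

# Analytic parallel-beam sinogram of a centred uniform disc:
# chord length 2*sqrt(R^2 - t^2) times mu, detector pitch 1 pixel.
discSinogram <- function(nAngles = 360, cols = 256, R = 60, mu = 0.01,
                         range = 180) {
  ang <- (0:(nAngles - 1)) * range / nAngles
  tt <- (0:(cols - 1)) - (cols - 1) / 2
  ch <- ifelse(abs(tt) <= R, 2 * sqrt(pmax(R^2 - tt^2, 0)), 0) * mu
  list(sino = matrix(rep(ch, each = nAngles), nAngles, cols), angles = ang,
       R = R, mu = mu, cols = cols)
}

# Independent flood-fill component count (6/26-connectivity), pure R;
# oracle for the compiled labeling. Intended for small masks only.
floodCount <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0 & nb$dz == 0), ]
  if (connectivity == 6) nb <- nb[abs(nb$dx) + abs(nb$dy) + abs(nb$dz) == 1, ]
  count <- 0L
  for (w in which(mask)) {
    if (lab[w] > 0L) next
    count <- count + 1L
    queue <- w
    lab[w] <- count
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      k <- (p - 1) %/% (d[1] * d[2])
      r <- (p - 1) %% (d[1] * d[2])
      j <- r %/% d[1]; i <- r %% d[1]
      for (q in seq_len(nrow(nb))) {
        ii <- i + nb$dx[q]; jj <- j + nb$dy[q]; kk <- k + nb$dz[q]
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[1] || jj >= d[2] ||
            kk >= d[3]) next
        pp <- 1 + ii + d[1] * (jj + d[2] * kk)
        if (mask[pp] && lab[pp] == 0L) { lab[pp] <- count; queue <- c(queue, pp) }
      }
    }
  }
  list(count = count, labels = lab)
}
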