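#' @include utils.R
NULL

# Extract the tissue support. Samples are scanned in cylindrical
# holders, so the support is modelled as a cylinder: the parenchyma is
# found by an Otsu split of a heavily smoothed copy (phase-rim dipoles
# integrate to zero under smoothing), and the cylinder axis/radius and
# z-extent are fitted to its largest connected component. This is
# robust to wall fringe halos that would break a purely topological
# (hole-filling) support estimate. `core` is the same cylinder drawn
# `edgeErode` voxels smaller, used for parenchyma statistics.
tissueSupport <- function(v, d, fovFrac, supportSigma = 3, edgeErode = 3L) {
  fov <- cylinderMask(d, fovFrac)
  vs <- if (supportSigma > 0) gaussianSmooth(v, supportSigma) else v
  t1 <- otsuThreshold(vs[fov])
  par <- vs >= t1 & fov
  tl <- array(cpp_label26(par, d), d)
  if (max(tl) == 0L) stop("no contrast: no tissue found in the field of view")
  par <- tl == which.max(tabulate(tl[tl > 0L]))
  ai <- arrayInd(which(par), d)
  cx <- mean(ai[, 1]); cy <- mean(ai[, 2])
  rr <- sqrt((ai[, 1] - cx)^2 + (ai[, 2] - cy)^2)
  R <- unname(quantile(rr, 0.995)) + 1
  zr <- range(ai[, 3])
  cylAt <- function(radius, zpad = 0L) {
    inPlane <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2,
                     "+") <= radius^2
    m <- array(FALSE, d)
    zs <- max(zr[1] + zpad, 1L):min(zr[2] - zpad, d[3])
    if (length(zs) < 1) stop("tissue support too small to segment")
    m[, , zs] <- inPlane
    m
  }
  list(cylAt = cylAt, R = R,
       tissue = cylAt(R), core = cylAt(max(R - edgeErode, 2), edgeErode))
}

#' Segment sinusoid lumina from a reconstructed volume
#'
#' Deterministic replacement for interactive segmentation, designed for
#' edge-enhanced (no phase retrieval) reconstructions where lumen
#' boundaries carry strong bright/dark phase rims but interior
#' absorption contrast is weak. The procedure is seeded and local:
#'
#' 1. optional 3D Gaussian presmoothing and 3^3 median filtering;
#' 2. tissue support extraction (Otsu against air, hole filling);
#' 3. seed detection on an additionally smoothed copy: voxels more than
#'    `detectK` robust standard deviations below the tissue median
#'    (quartile-based spread from the deeply eroded core, so the
#'    parenchyma mode sets the scale), followed by a morphological
#'    opening of depth 2 that removes thin phase-rim shells, edge
#'    halos and noise filaments, and a seed size filter; lumen-free
#'    noise-free volumes therefore yield no seeds;
#' 4. per-seed refinement: a local threshold halfway between the lumen
#'    (seed median) and parenchyma (local background median) levels,
#'    applied by conditional dilation from the seed with an opening to
#'    suppress noise leakage, then closing and per-component hole
#'    filling (intraluminal thrombi remain part of the cavity);
#' 5. 26-connected labeling, `minVoxels` filtering, labels numbered by
#'    decreasing size.
#'
#' On noise-free two-valued volumes the procedure reduces to exact
#' threshold recovery of the lumina.
#'
#' @param volume a [ReconVolume-class].
#' @param minVoxels smallest lumen kept, voxels (default 27 = 3^3).
#' @param presmoothSigma 3D Gaussian sigma (voxels) applied to the
#'   working copy; 1 voxel suits noisy reconstructions, 0 disables.
#' @param detectSigma extra Gaussian sigma for the seed-detection copy.
#' @param growIterations conditional-dilation iterations for boundary
#'   recovery (bounds how far a region may extend beyond its seed).
#' @param medianFilter apply a 3^3 median to the working copy (slightly
#'   erodes staircase voxels on clean data; off by default).
#' @param fovFrac radius of the valid reconstruction cylinder as a
#'   fraction of the slice width.
#' @param detectK seed threshold depth in robust parenchyma standard
#'   deviations below the tissue median.
#' @return A [LabelVolume-class] (empty thrombus mask).
#' @export
segmentSinusoids <- function(volume, minVoxels = 27L, presmoothSigma = 1,
                             detectSigma = 2.5, growIterations = 24L,
                             medianFilter = FALSE, fovFrac = 0.48,
                             detectK = 2.5) {
  d <- dim(volume@data)
  v <- volume@data
  if (any(!is.finite(v))) stop("volume must be finite")
  if (presmoothSigma > 0) v <- gaussianSmooth(v, presmoothSigma)
  if (medianFilter) v <- array(cpp_median3(v, d), d)
  # erode past the smoothed edge-fringe halo of the sample boundary so
  # tail statistics see parenchyma and lumina only (capped so small
  # test volumes keep a usable core)
  edgeErode <- max(3L, as.integer(ceiling(2 + presmoothSigma + 2 * detectSigma)))
  edgeErode <- min(edgeErode, max(3L, min(d) %/% 10L))
  ts <- tissueSupport(v, d, fovFrac, edgeErode = edgeErode)
  tissue <- ts$tissue; core <- ts$core
  emptyResult <- function() new("LabelVolume", labels = array(0L, d),
                                thrombus = array(FALSE, d),
                                voxelSize = volume@voxelSize)

  vd <- if (detectSigma > 0) gaussianSmooth(v, detectSigma) else v
  x <- vd[core]
  if (length(x) < 100) stop("tissue support too small to segment")
  med <- median(x)
  # robust parenchyma spread from the deep core, estimated from the
  # upper half of the histogram only: the dark lumen mass cannot
  # contaminate it even when lumina are large
  sdR <- (unname(quantile(x, 0.75)) - med) / 0.6745
  if (sdR <= 0) sdR <- .Machine$double.eps * max(1, abs(med))
  tdet <- med - detectK * sdR
  seedMin <- max(4L * minVoxels, minVoxels)
  # seed search stays inside the deep core: the Gibbs/fringe rings that
  # hug the sample wall never seed, while wall-adjacent lumina still
  # seed through their interior part
  dark <- vd < tdet & core
  # opening of depth 2: thin phase-rim shells, edge halos and noise
  # filaments vanish, solid lumen cores survive
  for (i in 1:2) dark <- array(cpp_morph_box3(dark, d, FALSE), d)
  for (i in 1:2) dark <- array(cpp_morph_box3(dark, d, TRUE), d)
  seeds <- array(cpp_label26(dark, d), d)
  if (max(seeds) == 0L) return(emptyResult())
  seedSizes <- tabulate(seeds[seeds > 0L])
  keep <- which(seedSizes >= seedMin)
  if (!length(keep)) return(emptyResult())
  # depth-adaptive seed shrinking: keep each component interior beyond
  # the detection blur (or its deepest 40% where the component is too
  # small), so seeds cannot overshoot the true boundary; refinement
  # re-grows them on the sharper working copy
  seedEDT <- array(cpp_edt3d(dark, d), d)

  # exclusion zone for the local background estimate
  excl <- seeds > 0L
  for (i in 1:3) excl <- array(cpp_morph_box3(excl, d, TRUE), d)

  # growth region: keep clear of the dark fringe halo lining the wall
  haloGuard <- 3L
  allowSupport <- ts$cylAt(max(ts$R - haloGuard, 2), haloGuard)

  # per-seed local midpoint thresholds assembled into one global allow
  # mask, then one synchronous competitive growth so nearby lumina
  # contest bridge voxels instead of engulfing each other
  allowGlobal <- array(FALSE, d)
  seedLab <- array(0L, d)
  margin <- growIterations + 6L
  for (id in keep) {
    w <- which(seeds == id)
    w <- w[seedEDT[w] >= min(detectSigma + 1, 0.6 * max(seedEDT[w]))]
    ai <- arrayInd(w, d)
    lo <- pmax(apply(ai, 2, min) - margin, 1L)
    hi <- pmin(apply(ai, 2, max) + margin, d)
    bx1 <- lo[1]:hi[1]; bx2 <- lo[2]:hi[2]; bx3 <- lo[3]:hi[3]
    sub <- v[bx1, bx2, bx3, drop = FALSE]
    sd3 <- dim(sub)
    seedSub <- array(FALSE, sd3)
    seedSub[cbind(ai[, 1] - lo[1] + 1L, ai[, 2] - lo[2] + 1L,
                  ai[, 3] - lo[3] + 1L)] <- TRUE
    tisSub <- array(allowSupport[bx1, bx2, bx3], sd3)
    exclSub <- array(excl[bx1, bx2, bx3], sd3)
    inMu <- median(sub[seedSub])
    bg <- sub[tisSub & !exclSub]
    if (length(bg) < 50) bg <- sub[tisSub & !seedSub]
    outMu <- median(bg)
    tc <- (inMu + outMu) / 2
    allow <- array(sub < tc & tisSub, sd3)
    allow <- array(cpp_morph_box3(allow, sd3, FALSE), sd3)
    allow <- array(cpp_morph_box3(allow, sd3, TRUE), sd3)
    allowGlobal[bx1, bx2, bx3] <- allowGlobal[bx1, bx2, bx3] | allow
    seedLab[w] <- id
  }
  # re-split seeds on the refined walls: a seed merged across a thin
  # parenchyma septum by the detection blur separates again once the
  # sharper local thresholds carve the septum out of the allow mask
  seedLab[!allowGlobal] <- 0L
  seedLab <- array(cpp_label26(seedLab > 0L, d), d)
  if (max(seedLab) == 0L) return(emptyResult())
  grown <- array(cpp_multilabel_grow(seedLab, allowGlobal, d,
                                     as.integer(growIterations)), d)
  # per-label closing and hole filling; contested voxels stay with the
  # first (larger-seed) label
  lab <- array(0L, d)
  for (id in sort(unique(grown[grown > 0L]))) {
    w <- which(grown == id)
    ai <- arrayInd(w, d)
    # pad beyond the closing depth so the dilated mask never touches
    # the working box faces (erosion could not retract it there)
    lo <- pmax(apply(ai, 2, min) - 5L, 1L)
    hi <- pmin(apply(ai, 2, max) + 5L, d)
    bx1 <- lo[1]:hi[1]; bx2 <- lo[2]:hi[2]; bx3 <- lo[3]:hi[3]
    sd3 <- c(length(bx1), length(bx2), length(bx3))
    reg <- array(grown[bx1, bx2, bx3] == id, sd3)
    # closing of depth 3 seals gaps in the captured shell so hole
    # filling recovers sparse interiors of large low-contrast lumina
    # and fully enclosed bright thrombi
    for (i in 1:3) reg <- array(cpp_morph_box3(reg, sd3, TRUE), sd3)
    reg <- array(cpp_fill_holes(reg, sd3), sd3)
    for (i in 1:3) reg <- array(cpp_morph_box3(reg, sd3, FALSE), sd3)
    tgt <- lab[bx1, bx2, bx3]
    tgt[reg & tgt == 0L] <- id
    lab[bx1, bx2, bx3] <- tgt
  }
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(sizes < minVoxels)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabelBySize(lab)
  }
  new("LabelVolume", labels = lab, thrombus = array(FALSE, d),
      voxelSize = volume@voxelSize)
}

#' Segment intraluminal thrombi
#'
#' Thrombi reconstruct denser (brighter) than the plasma-filled cavity.
#' Within each labelled lumen the same detect-then-refine strategy as
#' [segmentSinusoids()] runs with inverted polarity: candidate voxels
#' more than `detectK` robust standard deviations above the cavity
#' median on a smoothed copy, a depth-1 opening and size filter for
#' seeds, then a local threshold halfway between the thrombus and
#' cavity levels applied by bounded conditional dilation, closing and
#' hole filling. Lumina without a sufficiently large coherent bright
#' region receive an empty mask.
#'
#' @param volume the [ReconVolume-class] the labels were derived from.
#' @param labels a [LabelVolume-class].
#' @param detectK seed threshold height in robust cavity standard
#'   deviations above the cavity median.
#' @param detectSigma Gaussian sigma (voxels) of the detection copy.
#' @param minVoxels smallest thrombus accepted, voxels.
#' @param growIterations conditional-dilation iterations.
#' @return the [LabelVolume-class] with `thrombus` populated.
#' @export
segmentThrombus <- function(volume, labels, detectK = 2.5,
                            detectSigma = 1.5, minVoxels = 27L,
                            growIterations = 12L) {
  d <- dim(labels@labels)
  stopifnot(identical(dim(volume@data), d))
  v <- volume@data
  th <- array(FALSE, d)
  for (id in seq_len(nLabels(labels))) {
    w <- which(labels@labels == id)
    if (length(w) < 200) next
    ai <- arrayInd(w, d)
    lo <- pmax(apply(ai, 2, min) - 4L, 1L)
    hi <- pmin(apply(ai, 2, max) + 4L, d)
    bx1 <- lo[1]:hi[1]; bx2 <- lo[2]:hi[2]; bx3 <- lo[3]:hi[3]
    sub <- v[bx1, bx2, bx3, drop = FALSE]
    sd3 <- dim(sub)
    comp <- array(labels@labels[bx1, bx2, bx3] == id, sd3)
    core <- comp
    for (i in 1:2) core <- array(cpp_morph_box3(core, sd3, FALSE), sd3)
    if (sum(core) < 50) next
    # masked (normalised) smoothing: only cavity voxels contribute, so
    # the bright parenchyma beyond the wall cannot leak into the
    # cavity statistics
    vds <- if (detectSigma > 0) {
      den <- gaussianSmooth(comp * 1.0, detectSigma)
      gaussianSmooth(sub * comp, detectSigma) / pmax(den, 0.05)
    } else sub
    x <- vds[core]
    med <- median(x)
    # lower-half spread: the bright thrombus mass cannot contaminate it
    sdR <- (med - unname(quantile(x, 0.10))) / 1.2816
    if (sdR <= 0) sdR <- .Machine$double.eps * max(1, abs(med))
    bright <- vds > med + detectK * sdR & core
    bright <- array(cpp_morph_box3(bright, sd3, FALSE), sd3)
    bright <- array(cpp_morph_box3(bright, sd3, TRUE), sd3)
    seeds <- array(cpp_label26(bright, sd3), sd3)
    if (max(seeds) == 0L) next
    sizes <- tabulate(seeds[seeds > 0L])
    keep <- which(sizes >= minVoxels)
    if (!length(keep)) next
    seedMask <- array(seeds %in% keep, sd3)
    dil <- seedMask
    for (i in 1:2) dil <- array(cpp_morph_box3(dil, sd3, TRUE), sd3)
    seedCore <- array(cpp_morph_box3(seedMask, sd3, FALSE), sd3)
    if (!any(seedCore)) seedCore <- seedMask
    # adaptive refinement field: the raw copy localises the boundary
    # exactly on clean data; when the thrombus contrast is near the
    # raw noise floor the smoothed copy must carry the boundary
    madRaw <- mad(sub[core])
    inRaw <- median(sub[seedCore])
    bgSel <- core & !dil
    if (sum(bgSel) < 30) next
    useRaw <- madRaw == 0 || (inRaw - median(sub[bgSel])) > 4 * madRaw
    f <- if (useRaw) sub else vds
    inner <- array(cpp_morph_box3(comp, sd3, FALSE), sd3)
    inReg <- seedCore
    outReg <- bgSel
    reg <- seedMask
    # two refinement passes: the seed-based interior estimate is
    # selection-biased high (seeds are the extreme tail), so the first
    # pass undersizes the region; the second pass re-estimates the
    # levels from the recovered region, which is unbiased
    for (pass in 1:2) {
      inMu <- median(f[inReg])
      outMu <- median(f[outReg])
      if (!(inMu > outMu)) break
      tc <- (inMu + outMu) / 2
      allow <- array(f > tc & inner, sd3)
      allow <- array(cpp_morph_box3(allow, sd3, FALSE), sd3)
      allow <- array(cpp_morph_box3(allow, sd3, TRUE), sd3)
      # detection blur lets seeds overshoot the boundary; growth must
      # start inside the thresholded region
      reg <- seedMask & allow
      if (!any(reg)) break
      for (i in seq_len(growIterations)) {
        reg2 <- array(cpp_morph_box3(reg, sd3, TRUE), sd3) & (allow | reg)
        if (identical(reg2, reg)) break
        reg <- reg2
      }
      # noisy captures need their shell sealed before filling; the
      # clean-data path skips it (box closing inflates small digital
      # solids at staircase concavities)
      closeDepth <- if (useRaw) 0L else 2L
      for (i in seq_len(closeDepth)) reg <- array(cpp_morph_box3(reg, sd3, TRUE), sd3)
      reg <- array(cpp_fill_holes(reg, sd3), sd3)
      for (i in seq_len(closeDepth)) reg <- array(cpp_morph_box3(reg, sd3, FALSE), sd3)
      reg <- reg & comp
      if (sum(reg) < minVoxels) break
      inCand <- array(cpp_morph_box3(reg, sd3, FALSE), sd3)
      if (!any(inCand)) break
      dil2 <- reg
      for (i in 1:2) dil2 <- array(cpp_morph_box3(dil2, sd3, TRUE), sd3)
      outCand <- core & !dil2
      if (sum(outCand) < 30) break
      inReg <- inCand
      outReg <- outCand
    }
    if (sum(reg) < minVoxels) next
    tb <- array(FALSE, d)
    tb[bx1, bx2, bx3] <- reg
    th <- th | tb
  }
  labels@thrombus <- th
  validObject(labels)
  labels
}
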