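#' @include utils.R
NULL

# Grade-dependent generator settings: elongation of the secondary axes /
# capsule length relative to the minimum-axis diameter, whether lumina
# may touch, and the target lumen fraction of the tissue cylinder that
# the severe grade must reach (lacunae dominate the tumour).
gradeParams <- function(grade) {
  switch(grade,
    mild = list(elong = c(1.2, 2.0), touching = FALSE, targetFraction = NA),
    moderate = list(elong = c(1.6, 3.0), touching = TRUE, targetFraction = NA),
    severe = list(elong = c(2.5, 5.0), touching = TRUE, targetFraction = 0.55),
    stop("unknown grade: ", grade)
  )
}

# Voxelise one random ellipsoid or capsule into a logical array the size
# of the grid. Centre and orientation are drawn here; `minAxisVox` is
# the semi-minor *diameter* in voxels.
voxelizePrimitive <- function(d, centre, minAxisVox, elong, type) {
  a <- minAxisVox / 2
  if (type == "ellipsoid") {
    semi <- c(a, a * runif(1, elong[1], elong[2]), a * runif(1, elong[1], elong[2]))
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    ext <- ceiling(max(semi)) + 1L
  } else { # capsule: cylinder of radius a capped with hemispheres
    len <- minAxisVox * runif(1, elong[1], elong[2])
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ext <- ceiling(len / 2 + a) + 1L
  }
  lo <- pmax(floor(centre - ext), 1)
  hi <- pmin(ceiling(centre + ext), d)
  if (any(lo > hi)) return(NULL)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  p <- t(cbind(g$x - centre[1], g$y - centre[2], g$z - centre[3]))
  if (type == "ellipsoid") {
    q <- rot %*% p
    inside <- colSums((q / semi)^2) <= 1
  } else {
    t0 <- pmin(pmax(colSums(p * axis), -len / 2), len / 2)
    dv <- p - outer(axis, t0)
    inside <- colSums(dv^2) <= a^2
  }
  if (!any(inside)) return(NULL)
  cbind(g$x[inside], g$y[inside], g$z[inside])
}

#' Generate a synthetic CHL phantom
#'
#' Places `nSinusoids` randomly oriented ellipsoids and capsule segments
#' (the canaliform class) inside a tissue cylinder, producing paired
#' delta/beta volumes with ground-truth lumen labels. Dilated sinusoid
#' lacunae have lower delta and beta than the surrounding parenchyma
#' (formalin/plasma-filled cavities); the region outside the tissue
#' cylinder is air. Grade controls dilation and contact: mild lumina are
#' pairwise non-adjacent; moderate lumina may conglutinate; severe
#' lacunae are grown until they occupy more than half of the tissue
#' cylinder.
#'
#' @param gridShape integer vector of 3 voxel counts.
#' @param voxelSize voxel edge length in micrometres.
#' @param grade "mild", "moderate" or "severe".
#' @param nSinusoids number of lumina to place.
#' @param diameterRange minimum-axis diameter range in micrometres
#'   (dilated CHL sinusoids measure roughly 118-877 um).
#' @param seed RNG seed; the phantom is bit-identical given identical
#'   arguments and seed.
#' @param optical named list of optical constants (delta/beta for
#'   parenchyma, lumen, thrombus) at the working energy.
#' @param maxRetries placement retry cap before a placement-failure
#'   error is raised.
#' @return A [Phantom-class] object.
#' @examples
#' ph <- makeSinusoidPhantom(c(48, 48, 48), 9, "mild", 2,
#'                           diameterRange = c(90, 140), seed = 1)
#' nLabels(ph)
#' @export
makeSinusoidPhantom <- function(gridShape, voxelSize = 9,
                                grade = c("mild", "moderate", "severe"),
                                nSinusoids = 5L,
                                diameterRange = c(120, 400), seed = 1L,
                                optical = defaultOpticalConstants(),
                                maxRetries = 1000L) {
  grade <- match.arg(grade)
  d <- as.integer(gridShape)
  stopifnot(length(d) == 3, all(d >= 8), nSinusoids >= 0,
            diameterRange[1] <= diameterRange[2])
  dVox <- diameterRange / voxelSize
  if (nSinusoids > 0 && (dVox[1] < 2 || dVox[2] > min(d)))
    stop("diameterRange must lie within (2 voxels, minimum grid extent)")
  gp <- gradeParams(grade)
  cyl <- cylinderMask(d, radiusFrac = 0.45)
  cylN <- sum(cyl)
  # lacunae stay clear of the sample wall: placement uses a cylinder
  # two voxels inside the tissue surface
  cylPlace <- cylinderMask(d, radiusFrac = 0.45, shrink = 2)

  withSeed(seed, {
    labels <- array(0L, d)
    lumenAny <- array(FALSE, d)
    placed <- 0L
    tries <- 0L
    cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
    rmax <- 0.45 * min(d[1], d[2])
    while (placed < nSinusoids) {
      tries <- tries + 1L
      if (tries > maxRetries)
        stop("placement failure: could not place ", nSinusoids,
             " lumina under grade '", grade, "' constraints within ",
             maxRetries, " retries")
      minAx <- runif(1, dVox[1], dVox[2])
      zl <- 3 + minAx / 2; zh <- d[3] - 2 - minAx / 2
      if (zl >= zh) next
      rho <- sqrt(runif(1)) * max(rmax - 2 - minAx / 2, 1)
      th <- runif(1, 0, 2 * pi)
      centre <- c(cx + rho * cos(th), cy + rho * sin(th), runif(1, zl, zh))
      type <- if (runif(1) < 0.5) "ellipsoid" else "capsule"
      vox <- voxelizePrimitive(d, centre, minAx, gp$elong, type)
      if (is.null(vox)) next
      idx <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
      # must stay clear of the sample wall and the z faces
      if (any(!cylPlace[idx]) || any(vox[, 3] <= 2 | vox[, 3] >= d[3] - 1))
        next
      if (!gp$touching) {
        # non-adjacent: reject if any candidate voxel has a labelled
        # voxel within its 26-neighbourhood
        near <- FALSE
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
          sh <- idx + dx + d[1] * dy + d[1] * d[2] * dz
          sh <- sh[sh >= 1 & sh <= length(lumenAny)]
          if (any(lumenAny[sh])) { near <- TRUE; break }
        }
        if (near) next
      }
      placed <- placed + 1L
      lumenAny[idx] <- TRUE
      labels[idx] <- placed
    }

    if (!is.na(gp$targetFraction) && nSinusoids > 0) {
      grow <- 0L
      while (sum(lumenAny & cyl) / cylN < gp$targetFraction && grow < 64L) {
        lumenAny <- array(cpp_morph_box3(lumenAny, d, TRUE), d) & cyl
        grow <- grow + 1L
      }
    }

    # conglutinated grades: components may have merged; relabel as
    # 26-connected components, numbered by decreasing size
    if (gp$touching && any(lumenAny)) {
      labels <- array(cpp_label26(lumenAny, d), d)
    }
    labels <- relabelBySize(labels)

    delta <- array(0, d); beta <- array(0, d)
    delta[cyl] <- optical$parenchyma$delta
    beta[cyl] <- optical$parenchyma$beta
    lum <- labels > 0L
    delta[lum] <- optical$lumen$delta
    beta[lum] <- optical$lumen$beta

    new("Phantom", delta = delta, beta = beta, labels = labels,
        thrombus = array(FALSE, d), voxelSize = voxelSize, grade = grade,
        seed = as.integer(seed), optical = optical)
  })
}

#' Default optical constants at 16 keV
#'
#' Plausible soft-tissue-scale refractive decrements and absorption
#' indices for formalin-fixed tissue; the pipeline only relies on the
#' contrast existing, not on the absolute values.
#'
#' @return named list with `parenchyma`, `lumen` and `thrombus` entries,
#'   each a list of `delta` and `beta`.
#' @export
defaultOpticalConstants <- function() {
  list(parenchyma = list(delta = 4.0e-7, beta = 2.0e-10),
       lumen = list(delta = 3.0e-7, beta = 1.5e-10),
       thrombus = list(delta = 4.5e-7, beta = 2.5e-10))
}

# Renumber labels 1..K by decreasing voxel count (ties: original order).
relabelBySize <- function(labels) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (!length(ids)) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = max(ids))[ids]
  ord <- ids[order(-sizes, ids)]
  map <- integer(max(ids))
  map[ord] <- seq_along(ord)
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  storage.mode(out) <- "integer"
  out
}

#' Add a concentric thrombus to one lumen
#'
#' Marks the innermost `volumeFraction` of the lumen's voxels (by
#' distance from the lumen boundary) as thrombus and assigns the
#' denser thrombus optical constants there. For a spherical lumen this
#' yields the concentric sphere of relative radius
#' `volumeFraction^(1/3)`.
#'
#' @param phantom a [Phantom-class].
#' @param labelId lumen id to receive the thrombus.
#' @param volumeFraction thrombus volume / lumen volume, in `[0, 1)`.
#' @param seed unused placeholder for API symmetry (the construction is
#'   deterministic); kept so pipeline configs can carry one seed per
#'   stage.
#' @return the modified [Phantom-class].
#' @export
addThrombus <- function(phantom, labelId, volumeFraction, seed = 1L) {
  stopifnot(volumeFraction >= 0, volumeFraction < 1)
  d <- dim(phantom@labels)
  comp <- phantom@labels == as.integer(labelId)
  n <- sum(comp)
  if (n == 0) stop("unknown label: ", labelId)
  if (volumeFraction == 0) return(phantom)
  edt <- array(cpp_edt3d(comp, d), d)
  k <- round(volumeFraction * n)
  if (k < 1) return(phantom)
  idx <- which(comp)
  ord <- idx[order(-edt[idx], idx)]
  sel <- ord[seq_len(k)]
  phantom@thrombus[sel] <- TRUE
  phantom@delta[sel] <- phantom@optical$thrombus$delta
  phantom@beta[sel] <- phantom@optical$thrombus$beta
  validObject(phantom)
  phantom
}

#' Ground-truth morphometry of a phantom
#'
#' Computes the same per-lumen descriptors as [measureAllSinusoids()]
#' directly on the noise-free label volume, providing the recovery
#' targets for end-to-end tests. Measures are the voxel-oracle values
#' (voxel-count volume, isosurface area, inscribed-ball and maximum
#' Feret diameters).
#'
#' @param phantom a [Phantom-class].
#' @return data.frame with columns `label_id`, `true_min_diameter`,
#'   `true_max_diameter`, `true_surface_area`, `true_volume`,
#'   `true_thrombus_fraction` (fraction in `[0, 1]`).
#' @export
groundTruthMorphometry <- function(phantom) {
  m <- measureComponents(phantom@labels, phantom@thrombus, phantom@voxelSize)
  data.frame(label_id = m$label_id,
             true_min_diameter = m$min_diameter,
             true_max_diameter = m$max_diameter,
             true_surface_area = m$surface_area,
             true_volume = m$volume,
             true_thrombus_fraction = m$thrombus_fraction / 100)
}
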