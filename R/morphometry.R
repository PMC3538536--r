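#' @include utils.R
NULL

# Shared measurement core: one row per label with the voxel-based
# descriptors. Diameter conventions: min = largest inscribed ball
# (twice the maximum of the Euclidean distance transform), max =
# maximum Feret (largest pairwise distance between surface voxel
# centres). Surface area from the 0.5-level isosurface of the
# (optionally 1-voxel-Gaussian-smoothed) binary mask, triangulated by
# marching tetrahedra; smoothing avoids staircase overestimation.
measureComponents <- function(labels, thrombus, voxelSize,
                              surfaceMode = c("smooth", "raw")) {
  surfaceMode <- match.arg(surfaceMode)
  d <- dim(labels)
  K <- if (length(labels)) max(labels) else 0L
  empty <- data.frame(label_id = integer(), min_diameter = numeric(),
                      max_diameter = numeric(), surface_area = numeric(),
                      volume = numeric(), thrombus_fraction = numeric())
  if (K < 1L) return(empty)
  out <- vector("list", K)
  for (id in seq_len(K)) {
    w <- which(labels == id)
    if (!length(w)) next
    ai <- arrayInd(w, d)
    lo <- pmax(apply(ai, 2, min) - 4L, 1L)
    hi <- pmin(apply(ai, 2, max) + 4L, d)
    sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == id
    sd3 <- dim(sub)
    nvox <- sum(sub)
    edt <- cpp_edt3d(sub, sd3)
    minD <- 2 * max(edt) * voxelSize
    field <- sub * 1.0
    if (surfaceMode == "smooth") {
      sm <- gaussianSmooth(field, 1)
      if (max(sm) > 0.5) field <- sm
    }
    sa <- cpp_surface_area(field, sd3, 0.5, voxelSize)
    er <- array(cpp_morph_box3(sub, sd3, FALSE), sd3)
    bnd <- which(sub & !er)
    pts <- arrayInd(bnd, sd3) * voxelSize
    maxD <- max(cpp_max_pairwise_dist(pts), minD)
    tf <- if (is.null(thrombus)) 0 else {
      100 * sum(thrombus[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] & sub) / nvox
    }
    out[[id]] <- data.frame(label_id = id,
                            min_diameter = minD, max_diameter = maxD,
                            surface_area = sa,
                            volume = nvox * voxelSize^3,
                            thrombus_fraction = tf)
  }
  do.call(rbind, c(list(empty), out))
}

#' Measure one sinusoid
#'
#' Per-lumen descriptors: `volume` (voxel count x voxel volume, um^3),
#' `surface_area` (triangulated 0.5-level isosurface of the smoothed
#' binary mask, um^2), `min_diameter` (largest inscribed ball, um),
#' `max_diameter` (maximum Feret across surface voxels, um) and
#' `thrombus_fraction` (percent of cavity voxels flagged as thrombus;
#' the thrombus counts as part of the sinusoid interior).
#'
#' @param labels a [LabelVolume-class] (or [Phantom-class]).
#' @param labelId lumen id to measure.
#' @param surfaceMode "smooth" (default) or "raw" isosurface.
#' @return one-row data.frame (a sinusoid record).
#' @export
measureSinusoid <- function(labels, labelId, surfaceMode = "smooth") {
  la <- labelArray(labels)
  if (!any(la == as.integer(labelId))) stop("unknown label: ", labelId)
  one <- la
  one[la != as.integer(labelId)] <- 0L
  m <- measureComponents(one, thrombusMask(labels), voxelSize(labels),
                         surfaceMode)
  m <- m[m$volume > 0, , drop = FALSE]
  m$label_id <- as.integer(labelId)
  rownames(m) <- NULL
  m
}

#' Measure every labelled sinusoid
#'
#' @param labels a [LabelVolume-class] or [Phantom-class].
#' @param surfaceMode "smooth" or "raw" isosurface area.
#' @return data.frame with one row per lumen (see [measureSinusoid()]).
#' @export
measureAllSinusoids <- function(labels, surfaceMode = "smooth") {
  measureComponents(labelArray(labels), thrombusMask(labels),
                    voxelSize(labels), surfaceMode)
}

#' Thrombus volume fraction of one sinusoid
#'
#' `100 * thrombus voxels / cavity voxels` for the given lumen; the
#' thrombus is counted as part of the sinusoid interior.
#'
#' @param labels a [LabelVolume-class] or [Phantom-class].
#' @param labelId lumen id.
#' @return percentage in `[0, 100]`.
#' @export
thrombusFraction <- function(labels, labelId) {
  la <- labelArray(labels)
  comp <- la == as.integer(labelId)
  n <- sum(comp)
  if (n == 0) stop("unknown label: ", labelId)
  100 * sum(thrombusMask(labels) & comp) / n
}

#' Cohort summary of sinusoid morphometry
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator)
#' of each descriptor, plus a "mean+-SD" rendering with two decimals.
#'
#' @param records data.frame from [measureAllSinusoids()], >= 1 row.
#' @return data.frame with columns `descriptor`, `mean`, `sd`,
#'   `formatted` and attribute `n`.
#' @export
summarizeMorphometry <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 1)
    stop("at least one sinusoid record is required")
  desc <- c("min_diameter", "max_diameter", "surface_area", "volume",
            "thrombus_fraction")
  desc <- intersect(desc, names(records))
  mu <- vapply(records[desc], mean, numeric(1))
  sg <- vapply(records[desc], function(x) if (length(x) > 1) sd(x) else 0,
               numeric(1))
  out <- data.frame(descriptor = desc, mean = unname(mu), sd = unname(sg),
                    formatted = formatMeanSD(unname(mu), unname(sg)))
  attr(out, "n") <- nrow(records)
  out
}

#' Format mean +- SD with two decimals
#' @param mean,sd numeric vectors.
#' @return character vector like `"205.66±60.10"`.
#' @export
formatMeanSD <- function(mean, sd) {
  sprintf("%.2f±%.2f", mean, sd)
}

#' Render a fraction as a percentage string
#' @param fraction value in `[0, 1]`.
#' @param digits decimals (default 2).
#' @return character, e.g. `formatPercent(0.1686)` is `"16.86%"`.
#' @export
formatPercent <- function(fraction, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), 100 * fraction)
}
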