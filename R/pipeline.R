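#' @include utils.R
NULL

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config schema: phantom parameters,
#' acquisition geometry, preprocessing switches, reconstruction filter,
#' segmentation thresholds and the global seed. The defaults describe a
#' small noiseless demonstration run; production-style runs raise
#' `nAngles`, grid size and enable noise.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    phantom = list(gridShape = c(64L, 64L, 64L), voxelSize = 9,
                   grade = "mild", nSinusoids = 3L,
                   diameterRange = c(100, 250),
                   thrombi = list()),  # e.g. list(list(label=1, fraction=0.17))
    geometry = list(energy = 16, pixelSize = 9, sdd = 1, nAngles = 90L,
                    angularRange = 180, flatCounts = 5000, darkOffset = 20,
                    nFlats = 20L, nDarks = 10L, readNoiseSD = 2,
                    gainVariation = 0),
    noise = FALSE,
    preprocess = list(smoothStrength = 1.5, ringCorrect = TRUE,
                      ringWindow = 9L),
    recon = list(filterName = "ramlak", volumeSmoothSigma = 0,
                 edgeEnhanceAmount = 0, edgeEnhanceRadius = 2),
    segment = list(minVoxels = 27L, presmoothSigma = 1,
                   detectSigma = 2.5, growIterations = 24L,
                   medianFilter = FALSE, fovFrac = 0.48,
                   detectK = 2.5,
                   thrombus = TRUE, thrombusDetectK = 2.5),
    output = list(writeProjections = FALSE, writeVolumes = TRUE)
  )
}

#' Read a YAML pipeline configuration
#'
#' Keys present in the file override [defaultRunConfig()]; missing keys
#' keep their defaults (recursive merge).
#'
#' @param path YAML file.
#' @return nested named list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeConfig(defaultRunConfig(), user)
}

mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])) && k != "thrombi") {
      base[[k]] <- mergeConfig(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full pipeline
#'
#' Executes phantom generation, virtual acquisition, detector
#' corrections, reconstruction, segmentation and morphometry in order,
#' writing every artifact, a per-stage log, a manifest with parameter
#' echoes and file hashes, and the morphometry CSVs (one row per
#' sinusoid plus a cohort summary). Reruns with the same config and
#' seed reproduce byte-identical CSVs.
#'
#' @param config nested list (see [defaultRunConfig()]) or a YAML path.
#' @param outputDir run directory (created; default a fresh tempdir).
#' @param verbose log to console as well as to `log.txt`.
#' @return invisible list with all intermediate objects (`phantom`,
#'   `projections`, `sinograms`, `volume`, `labels`, `records`,
#'   `summary`, `comparison`) and `dir`.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        outputDir = tempfile("sinusoidct_run_"),
                        verbose = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- mergeConfig(defaultRunConfig(), config)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outputDir, "log.txt")
  manifest <- list()
  logLine <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(line, "\n", file = logPath, append = TRUE)
    if (verbose) message(line)
  }
  finishStage <- function(stage, params, files = character()) {
    manifest[[stage]] <<- list(
      stage = stage, parameters = params,
      files = if (length(files))
        as.list(tools::md5sum(files)) else list())
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  runStage <- function(stage, expr) {
    logLine("stage ", stage, " started")
    r <- tryCatch(expr, error = function(e) {
      logLine("stage ", stage, " FAILED: ", conditionMessage(e))
      finishStage(stage, list(error = conditionMessage(e)))
      stop("pipeline aborted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    logLine("stage ", stage, " done")
    r
  }
  yaml::write_yaml(config, file.path(outputDir, "config.yaml"))
  set.seed(config$seed)

  phc <- config$phantom
  phantom <- runStage("phantom", {
    ph <- makeSinusoidPhantom(phc$gridShape, phc$voxelSize, phc$grade,
                              phc$nSinusoids, phc$diameterRange,
                              seed = config$seed)
    for (tspec in phc$thrombi)
      ph <- addThrombus(ph, tspec$label, tspec$fraction, seed = config$seed)
    if (isTRUE(config$output$writeVolumes))
      writePhantom(ph, file.path(outputDir, "phantom"))
    ph
  })
  finishStage("phantom", phc,
              list.files(file.path(outputDir, "phantom"), full.names = TRUE))

  gc0 <- config$geometry
  geometry <- acquisitionGeometry(
    energy = gc0$energy, pixelSize = gc0$pixelSize, sdd = gc0$sdd,
    nAngles = gc0$nAngles, angularRange = gc0$angularRange,
    flatCounts = gc0$flatCounts, darkOffset = gc0$darkOffset,
    nFlats = gc0$nFlats, nDarks = gc0$nDarks,
    readNoiseSD = gc0$readNoiseSD, gainVariation = gc0$gainVariation,
    seed = config$seed)
  projections <- runStage("acquire", {
    ps <- acquireDataset(phantom, geometry, noise = isTRUE(config$noise))
    if (isTRUE(config$output$writeProjections))
      writeProjectionSet(ps, file.path(outputDir, "projections"))
    ps
  })
  finishStage("acquire", c(gc0, list(noise = isTRUE(config$noise))))

  pc <- config$preprocess
  sinograms <- runStage("preprocess", {
    sg <- flatDarkCorrect(projections)
    # ring correction first: detector column bias is a single-column
    # defect and must be removed before smoothing smears it
    if (isTRUE(pc$ringCorrect)) sg <- ringCorrect(sg, pc$ringWindow)
    sg <- smoothSinograms(sg, pc$smoothStrength)
    sg
  })
  finishStage("preprocess", pc)

  rc <- config$recon
  volume <- runStage("recon", {
    v <- reconstructVolume(sinograms, rc$filterName)
    v <- smoothVolume(v, rc$volumeSmoothSigma)
    if (rc$edgeEnhanceAmount > 0) {
      for (k in seq_len(dim(v@data)[3]))
        v@data[, , k] <- edgeEnhance(v@data[, , k], rc$edgeEnhanceAmount,
                                     rc$edgeEnhanceRadius)
    }
    if (isTRUE(config$output$writeVolumes))
      writeVolumeTIFF(v@data, file.path(outputDir, "recon.tif"),
                      meta = list(voxel_size_um = v@voxelSize))
    v
  })
  finishStage("recon", rc, file.path(outputDir,
    if (isTRUE(config$output$writeVolumes)) "recon.tif" else character()))

  sc <- config$segment
  labels <- runStage("segment", {
    lv <- segmentSinusoids(volume, minVoxels = sc$minVoxels,
                           presmoothSigma = sc$presmoothSigma,
                           detectSigma = sc$detectSigma,
                           growIterations = sc$growIterations,
                           medianFilter = isTRUE(sc$medianFilter),
                           fovFrac = sc$fovFrac,
                           detectK = sc$detectK)
    if (isTRUE(sc$thrombus))
      lv <- segmentThrombus(volume, lv, detectK = sc$thrombusDetectK)
    if (isTRUE(config$output$writeVolumes)) {
      writeVolumeTIFF(lv@labels, file.path(outputDir, "labels.tif"),
                      bitsPerSample = 16,
                      meta = list(voxel_size_um = lv@voxelSize))
      writeVolumeTIFF(lv@thrombus + 0L, file.path(outputDir, "thrombus.tif"),
                      bitsPerSample = 16,
                      meta = list(voxel_size_um = lv@voxelSize))
    }
    lv
  })
  finishStage("segment", sc)

  res <- runStage("measure", {
    records <- measureAllSinusoids(labels)
    write.csv(records, file.path(outputDir, "morphometry.csv"),
              row.names = FALSE)
    if (nrow(records) >= 1) {
      sm <- summarizeMorphometry(records)
      write.csv(sm, file.path(outputDir, "summary.csv"), row.names = FALSE)
    } else {
      sm <- NULL
      logLine("measure: no records (no lumina segmented)")
      cat("descriptor,mean,sd,formatted\n",
          file = file.path(outputDir, "summary.csv"))
    }
    list(records = records, summary = sm)
  })
  finishStage("measure", list(),
              file.path(outputDir, c("morphometry.csv", "summary.csv")))

  comparison <- runStage("compare", {
    if (nLabels(phantom) > 0 && nLabels(labels) > 0) {
      cmp <- compareToTruth(labels, phantom)
      jsonlite::write_json(cmp, file.path(outputDir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      cmp
    } else NULL
  })
  finishStage("compare", list())
  logLine("pipeline complete")

  invisible(list(phantom = phantom, projections = projections,
                 sinograms = sinograms, volume = volume, labels = labels,
                 records = res$records, summary = res$summary,
                 comparison = comparison, dir = outputDir))
}

#' Compare a segmentation against phantom ground truth
#'
#' Matches segmented labels to true lumina by maximal voxel overlap
#' (id-agnostic), computes per-lumen Dice coefficients and the relative
#' errors of every morphometric descriptor, and summarises with the
#' median absolute relative error per descriptor.
#'
#' @param labels a [LabelVolume-class] from the pipeline.
#' @param phantom the generating [Phantom-class].
#' @param surfaceMode isosurface mode for the measurements.
#' @return list with `perLumen` (data.frame: `true_label`,
#'   `matched_label`, `dice`, `rel_err_*`) and `medianAbsRelErr`
#'   (named list).
#' @export
compareToTruth <- function(labels, phantom, surfaceMode = "smooth") {
  gt <- groundTruthMorphometry(phantom)
  if (nrow(gt) == 0) stop("phantom has no labelled lumina")
  meas <- measureAllSinusoids(labels, surfaceMode)
  la <- labels@labels
  pa <- phantom@labels
  rows <- vector("list", nrow(gt))
  anyOverlap <- FALSE
  for (i in seq_len(nrow(gt))) {
    id <- gt$label_id[i]
    w <- which(pa == id)
    seg <- la[w]
    seg <- seg[seg > 0L]
    if (!length(seg)) {
      rows[[i]] <- data.frame(true_label = id, matched_label = NA_integer_,
                              dice = 0, rel_err_volume = NA_real_,
                              rel_err_min_diameter = NA_real_,
                              rel_err_max_diameter = NA_real_,
                              rel_err_surface_area = NA_real_)
      next
    }
    anyOverlap <- TRUE
    tb <- tabulate(seg)
    match <- which.max(tb)
    inter <- tb[match]
    dice <- 2 * inter / (length(w) + sum(la == match))
    m <- meas[meas$label_id == match, ]
    rel <- function(a, b) (a - b) / b
    rows[[i]] <- data.frame(
      true_label = id, matched_label = match, dice = dice,
      rel_err_volume = rel(m$volume, gt$true_volume[i]),
      rel_err_min_diameter = rel(m$min_diameter, gt$true_min_diameter[i]),
      rel_err_max_diameter = rel(m$max_diameter, gt$true_max_diameter[i]),
      rel_err_surface_area = rel(m$surface_area, gt$true_surface_area[i]))
  }
  if (!anyOverlap)
    stop("matching failure: no segmented label overlaps any true lumen")
  per <- do.call(rbind, rows)
  med <- lapply(per[, grep("^rel_err_", names(per))],
                function(x) median(abs(x), na.rm = TRUE))
  list(perLumen = per, medianAbsRelErr = med,
       medianDice = median(per$dice))
}
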