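#' Default pipeline configuration
#'
#' All physical units are spelled out in the key names; unknown keys are
#' rejected at validation time (unit mistakes are the dominant failure mode
#' for this kind of tool). Calibration keys left NULL are taken from the
#' OPD stack's metadata sidecar.
#'
#' @return named list of configuration defaults
#' @export
defaultConfig <- function() {
  list(
    pixel_size_um = NULL,
    frame_interval_min = NULL,
    refractive_increment_um3_per_pg = 0.18,
    window_size_px = 32,
    window_overlap = 0.75,
    search_radius_px = 8,
    min_density_pg_per_um2 = 0.05,
    outlier_zmax = 3,
    peak_quality_min = 1.2,
    highpass_sigma_px = 4,
    piv_baseline_frames = "auto",
    deform_passes = 1,
    cv_area_um2 = 0.7,
    window_min = 30,
    step_min = NULL,
    segmentation_threshold_pg_per_um2 = 0.05,
    segmentation_sigma_px = 1,
    puncta_threshold_pg_per_h = NULL,
    puncta_min_area_um2 = 0.5,
    advection_scheme = "euler",
    integration_method = "exact",
    resolution_um = 0.48,
    mitosis_frac = 0.2,
    seed = 1
  )
}

#' Validate and complete a pipeline configuration
#'
#' @param config named list (possibly partial), or a path to a YAML/JSON
#'   config file
#' @return the full configuration with defaults filled in
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  pos <- c("pixel_size_um", "frame_interval_min",
           "refractive_increment_um3_per_pg", "window_size_px",
           "search_radius_px", "cv_area_um2", "window_min",
           "segmentation_threshold_pg_per_um2", "resolution_um")
  for (k in pos)
    if (!is.null(cfg[[k]]) && (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0))
      stop("configuration key '", k, "' must be a positive number")
  if (cfg$window_overlap < 0 || cfg$window_overlap >= 1)
    stop("'window_overlap' must be in [0, 1)")
  if (!cfg$advection_scheme %in% c("euler", "rk2"))
    stop("'advection_scheme' must be 'euler' or 'rk2'")
  if (!cfg$integration_method %in% c("exact", "supersample"))
    stop("'integration_method' must be 'exact' or 'supersample'")
  bl <- cfg$piv_baseline_frames
  if (!identical(bl, "auto") && (!is.numeric(bl) || bl < 1))
    stop("'piv_baseline_frames' must be \"auto\" or a positive number")
  if (is.null(cfg$step_min)) cfg$step_min <- cfg$window_min
  cfg
}

pivConfigFromConfig <- function(cfg) {
  pivConfig(windowSize = cfg$window_size_px,
            windowOverlap = cfg$window_overlap,
            searchRadius = cfg$search_radius_px,
            minDensity = cfg$min_density_pg_per_um2,
            outlierZmax = cfg$outlier_zmax,
            peakQualityMin = cfg$peak_quality_min,
            highpassSigma = cfg$highpass_sigma_px,
            deformPasses = cfg$deform_passes)
}

canonicalJSON <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full growth-mapping pipeline
#'
#' Reads an OPD stack and its metadata, background-corrects and converts
#' to dry mass, segments the cell, estimates velocity fields, tracks
#' control volumes over sliding windows, fits growth rates, and writes the
#' full artifact tree: mass stack, velocity CSVs, track CSVs, growth-map
#' TIFFs, region/puncta tables, a per-movie summary JSON and a run
#' manifest (software version, configuration, input checksums). The
#' pipeline is deterministic: rerunning with identical inputs reproduces
#' identical outputs.
#'
#' @param opdPath path to the multi-page float OPD TIFF (µm)
#' @param outDir output directory (created if needed)
#' @param configPath optional YAML/JSON configuration file
#' @param cellMaskPath,nucleusMaskPath optional mask images (TIFF/PNG,
#'   nonzero = inside); without a cell mask the cell is re-segmented from
#'   the data
#' @param config optional named list of configuration overrides (applied
#'   after the file)
#' @return invisibly, a list with the per-window results, the summary and
#'   the manifest
#' @export
runPipeline <- function(opdPath, outDir, configPath = NULL,
                        cellMaskPath = NULL, nucleusMaskPath = NULL,
                        config = list()) {
  cfg <- validateConfig(configPath %||% list())
  cfg <- validateConfig(utils::modifyList(cfg, config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  stack <- readOPDStack(opdPath)
  cal <- stack$calibration
  if (!is.null(cfg$pixel_size_um) && !is.null(cfg$frame_interval_min))
    cal <- Calibration(cfg$pixel_size_um, cfg$frame_interval_min,
                       cfg$refractive_increment_um3_per_pg)
  px <- pixelSize(cal)
  alpha <- refractiveIncrement(cal)

  userMask <- if (!is.null(cellMaskPath)) readMask(cellMaskPath, "cell") else NULL
  nucMask <- if (!is.null(nucleusMaskPath)) readMask(nucleusMaskPath, "nucleus")
             else NULL

  message("stage mass_imaging: ", length(stack$frames), " frames")
  massFrames <- lapply(stack$frames, function(fr) {
    prov <- if (!is.null(userMask)) userMask else {
      sm <- EBImage::gblur(opd(fr), sigma = max(cfg$segmentation_sigma_px, 1))
      cellMask(sm > cfg$segmentation_threshold_pg_per_um2 * alpha, "cell")
    }
    corr <- backgroundCorrect(fr, prov)
    phaseToMass(corr, cal)
  })
  writeMassStack(massFrames, file.path(outDir, "mass_stack.tif"))

  message("stage velocimetry: ", length(massFrames) - 1, " frame pairs")
  piv <- pivConfigFromConfig(cfg)
  velDir <- file.path(outDir, "velocity"); dir.create(velDir, showWarnings = FALSE)
  fields <- computeVelocityFields(massFrames, cfg = piv,
                                  baseline = cfg$piv_baseline_frames,
                                  resolution = cfg$resolution_um)
  for (k in seq_along(fields))
    writeVelocityCSV(fields[[k]],
                     file.path(velDir, sprintf("velocity_%04d.csv", k)))

  message("stage growth: windows of ", cfg$window_min, " min, step ",
          cfg$step_min, " min")
  windows <- windowedGrowth(
    massFrames, fields, windowLen = cfg$window_min,
    windowStep = cfg$step_min, cvArea = cfg$cv_area_um2, mask = userMask,
    segThreshold = cfg$segmentation_threshold_pg_per_um2,
    segSigma = cfg$segmentation_sigma_px, mitosisFrac = cfg$mitosis_frac,
    method = cfg$integration_method, scheme = cfg$advection_scheme)

  allEst <- list(); allRegions <- list(); allPuncta <- list()
  for (w in seq_along(windows)) {
    res <- windows[[w]]
    if (is.null(res)) next
    writeGrowthMapTIFF(res$map,
                       file.path(outDir, sprintf("growthmap_%04d.tif", w)))
    writeTracksCSV(res$tracks,
                   file.path(outDir, sprintf("tracks_%04d.csv", w)))
    est <- res$estimates
    est$window <- w
    allEst[[w]] <- est
    startFrame <- massFrames[[which.min(abs(
      vapply(massFrames, timestamp, numeric(1)) - res$window[1]))]]
    regions <- list(regionGrowth(est, res$cvs, res$mask, startFrame))
    if (!is.null(nucMask)) {
      regions <- c(regions,
                   list(regionGrowth(est, res$cvs, nucMask, startFrame)),
                   list(regionGrowth(est, res$cvs,
                                     cytoplasmMask(res$mask, nucMask),
                                     startFrame)))
    }
    reg <- do.call(rbind, regions)
    reg$window <- w
    allRegions[[w]] <- reg
    pct <- detectPuncta(res$map, thresholdRate = cfg$puncta_threshold_pg_per_h,
                        minArea = cfg$puncta_min_area_um2)
    if (nrow(pct) > 0) { pct$window <- w; allPuncta[[w]] <- pct }
  }
  estTab <- do.call(rbind, allEst)
  regTab <- do.call(rbind, allRegions)
  punctaTab <- if (length(allPuncta) > 0) do.call(rbind, allPuncta) else
    data.frame()
  utils::write.csv(estTab, file.path(outDir, "growth_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(regTab, file.path(outDir, "region_growth.csv"),
                   row.names = FALSE)
  utils::write.csv(punctaTab, file.path(outDir, "puncta.csv"),
                   row.names = FALSE)

  summary <- list(
    n_frames = length(massFrames),
    n_windows = length(windows),
    n_windows_used = sum(!vapply(windows, is.null, logical(1))),
    regions = regTab)
  writeLines(canonicalJSON(summary), file.path(outDir, "summary.json"))

  inputs <- c(opd = opdPath, cell_mask = cellMaskPath,
              nucleus_mask = nucleusMaskPath, config = configPath)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  md5s <- unname(tools::md5sum(unlist(inputs)))
  manifest <- list(
    software = "qpigrowth",
    version = as.character(utils::packageVersion("qpigrowth")),
    config = cfg,
    inputs = stats::setNames(as.list(md5s), names(inputs)))
  writeLines(canonicalJSON(manifest), file.path(outDir, "manifest.json"))

  invisible(list(windows = windows, estimates = estTab, regions = regTab,
                 puncta = punctaTab, summary = summary, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sceneFromConfig <- function(cfg) {
  known <- c("shape", "pixel_size_um", "frame_interval_min", "n_frames",
             "noise_sigma_um", "refractive_increment_um3_per_pg", "seed",
             "velocity", "source", "texture")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown scene key(s): ", paste(unknown, collapse = ", "))
  fix <- function(x) if (is.list(x))
    lapply(x, fix) else x
  syntheticScene(
    shape = unlist(cfg$shape %||% c(120L, 120L)),
    pixelSize = cfg$pixel_size_um %||% 0.25,
    frameInterval = cfg$frame_interval_min %||% 1,
    nFrames = cfg$n_frames %||% 31L,
    velocity = fix(cfg$velocity %||% list(type = "zero")),
    source = fix(cfg$source %||% list(type = "zero")),
    texture = fix(cfg$texture %||% list()),
    noiseSigma = cfg$noise_sigma_um %||% 5e-4,
    refractiveIncrement = cfg$refractive_increment_um3_per_pg %||% 0.18,
    seed = cfg$seed %||% 1L)
}

#' Render a synthetic scene to disk
#'
#' Writes the same artifact layout the pipeline ingests -- a multi-page
#' float OPD TIFF plus metadata sidecar -- together with the ground truth
#' (per-frame density stack and a JSON of total mass and blob centres), so
#' a rendered scene can be fed straight back into [runPipeline()].
#'
#' @param scene a [SyntheticScene-class], or a path to a YAML/JSON scene
#'   configuration
#' @param outDir output directory
#' @return invisibly, list(moviePath, truth)
#' @export
simulateScene <- function(scene, outDir) {
  if (is.character(scene)) {
    cfg <- if (grepl("\\.json$", scene)) jsonlite::read_json(scene)
           else yaml::read_yaml(scene)
    scene <- sceneFromConfig(cfg)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  mv <- renderMovie(scene)
  moviePath <- file.path(outDir, "movie.tif")
  writeFloatTIFF(lapply(mv$frames, opd), moviePath)
  writeLines(canonicalJSON(list(
    pixel_size_um = pixelSize(mv$calibration),
    frame_interval_min = frameInterval(mv$calibration),
    refractive_increment_um3_per_pg = refractiveIncrement(mv$calibration))),
    file.path(outDir, "movie.json"))
  writeFloatTIFF(mv$truth$density, file.path(outDir, "truth_density.tif"))
  writeLines(canonicalJSON(list(
    total_mass_pg = mv$truth$totalMass,
    blob_centers_um = mv$truth$blobCenters,
    velocity = scene@velocity, source = scene@source,
    seed = scene@seed)), file.path(outDir, "truth.json"))
  invisible(list(moviePath = moviePath, truth = mv$truth))
}
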