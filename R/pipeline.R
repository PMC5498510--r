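# End-to-end driver: seed -> track (or read .trk) -> label -> candidate
# image -> vote -> write, with a validated flat config and a JSON
# provenance sidecar so every output is reproducible from its own
# metadata.

#' Build and validate a pipeline configuration
#'
#' A flat list of every pipeline parameter with defaults. Validation
#' enforces \code{wLocal + wNeighbor == 1} and \code{angle} in (0, 90) at
#' construction time, so misconfigured runs fail before any work is done.
#'
#' @param cortexPath path to the cortex parcellation NIfTI.
#' @param wmMaskPath path to the white-matter mask NIfTI.
#' @param tractsPath optional .trk tractogram; when given, tracking is
#'   skipped and these streamlines are used.
#' @param directionsPath,trackingMaskPath principal-direction field and
#'   tracking mask NIfTIs (required when \code{tractsPath} is NULL).
#' @param outPath output parcellation NIfTI path.
#' @param wLocal,wNeighbor voting weights (must sum to 1).
#' @param angle FACT stopping angle in degrees.
#' @param seedsPerVoxel seeds per cortex voxel.
#' @param substep voxelization sub-step in voxels.
#' @param normalizeNeighbors,countTraversals,fillNearestCortex optional
#'   behavior switches (all default \code{FALSE}); \code{fillNearestCortex}
#'   assigns WM voxels left unlabeled by the vote their nearest-cortex
#'   label as a post-pass.
#' @return A validated \code{list} of class \code{"tractparcConfig"}.
#' @export
runConfig <- function(cortexPath = NULL, wmMaskPath = NULL,
                      tractsPath = NULL, directionsPath = NULL,
                      trackingMaskPath = NULL, outPath = NULL,
                      wLocal = 0.5, wNeighbor = 0.5, angle = 35,
                      seedsPerVoxel = 1L, substep = 0.25,
                      normalizeNeighbors = FALSE, countTraversals = FALSE,
                      fillNearestCortex = FALSE) {
  cfg <- list(cortexPath = cortexPath, wmMaskPath = wmMaskPath,
              tractsPath = tractsPath, directionsPath = directionsPath,
              trackingMaskPath = trackingMaskPath, outPath = outPath,
              wLocal = wLocal, wNeighbor = wNeighbor, angle = angle,
              seedsPerVoxel = as.integer(seedsPerVoxel), substep = substep,
              normalizeNeighbors = isTRUE(normalizeNeighbors),
              countTraversals = isTRUE(countTraversals),
              fillNearestCortex = isTRUE(fillNearestCortex))
  if (abs(cfg$wLocal + cfg$wNeighbor - 1) > 1e-12)
    stop("config error: wLocal + wNeighbor must equal 1 (got ",
         cfg$wLocal, " + ", cfg$wNeighbor, ")", call. = FALSE)
  if (cfg$angle <= 0 || cfg$angle >= 90)
    stop("config error: angle must lie in (0, 90) degrees", call. = FALSE)
  if (cfg$substep <= 0 || cfg$substep > 1)
    stop("config error: substep must lie in (0, 1]", call. = FALSE)
  if (cfg$seedsPerVoxel < 1L)
    stop("config error: seedsPerVoxel must be >= 1", call. = FALSE)
  class(cfg) <- "tractparcConfig"
  cfg
}

#' Merge a config file with explicit overrides
#'
#' Reads a YAML (or \code{key: value} per line) config file and merges it
#' with override values, overrides winning; the merged result passes
#' through [runConfig()] validation.
#'
#' @param path config file path.
#' @param overrides named list of values taking precedence.
#' @return A validated config.
#' @export
loadConfig <- function(path, overrides = list()) {
  vals <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE,
                  value = TRUE)
    kv <- strsplit(lines, ":", fixed = TRUE)
    vv <- lapply(kv, function(p) utils::type.convert(trimws(p[2]),
                                                     as.is = TRUE))
    names(vv) <- trimws(vapply(kv, `[`, "", 1))
    vv
  }
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

#' Run the whole parcellation pipeline
#'
#' Loads the inputs named in \code{config}, obtains streamlines (reading
#' the tractogram if given, otherwise tracking out of every cortex
#' region), labels them by cortical origin, populates the candidate
#' image, votes, optionally fills unlabeled WM voxels from the
#' nearest-cortex baseline, writes the parcellation and a JSON provenance
#' sidecar (resolved config plus run counters), and returns the paths.
#'
#' @param config a config from [runConfig()] or [loadConfig()].
#' @return Invisibly, a list with \code{outPath}, \code{sidecarPath} and
#'   the counters (streamlines labeled/dropped, unlabeled WM voxels).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "tractparcConfig"))
  for (f in c("cortexPath", "wmMaskPath", "outPath"))
    if (is.null(config[[f]]))
      stop("config error: ", f, " is required", call. = FALSE)
  cortex <- readLabelVolume(config$cortexPath)
  wmMask <- readMaskVolume(config$wmMaskPath)

  tracts <- if (!is.null(config$tractsPath)) {
    readTractogram(config$tractsPath, cortex)
  } else {
    if (is.null(config$directionsPath) || is.null(config$trackingMaskPath))
      stop("config error: need tractsPath, or directionsPath + ",
           "trackingMaskPath", call. = FALSE)
    field <- readDirectionField(config$directionsPath,
                                config$trackingMaskPath)
    trackFromCortex(field, cortex,
                    trackingParams(angleThreshold = config$angle),
                    seedsPerVoxel = config$seedsPerVoxel)
  }

  labeled <- labelStreamlines(tracts, cortex)
  cortexLabels <- setdiff(sort(unique(as.vector(volumeData(cortex)))), 0L)
  cand <- populateCandidates(labeled, wmMask, labelList = cortexLabels,
                             substep = config$substep,
                             countTraversals = config$countTraversals)
  params <- votingParams(config$wLocal, config$wNeighbor,
                         normalizeNeighbors = config$normalizeNeighbors)
  parc <- assignLabels(cand, wmMask, params)

  if (config$fillNearestCortex) {
    near <- nearestCortexParcellation(cortex, wmMask)
    hole <- volumeData(parc) == 0L & volumeData(wmMask) == 1L
    d <- volumeData(parc); d[hole] <- volumeData(near)[hole]
    parc <- labelVolume(d, volumeAffine(parc), labelTable(cortex))
  }

  unlabeledWM <- sum(volumeData(parc) == 0L & volumeData(wmMask) == 1L)
  writeLabelVolume(parc, config$outPath)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", config$outPath),
                    "_provenance.json")
  counters <- list(nStreamlines = length(streamlines(tracts)),
                   nLabeled = length(streamlines(labeled)),
                   nDropped = nDropped(labeled),
                   unlabeledWMVoxels = unlabeledWM)
  jsonlite::write_json(
    list(tool = "tractparc",
         version = as.character(utils::packageVersion("tractparc")),
         config = unclass(config), counters = counters),
    sidecar, auto_unbox = TRUE, null = "null", pretty = TRUE)
  message(sprintf(
    "parcellation written: %d/%d streamlines labeled (%d dropped), %d WM voxel(s) left unlabeled",
    counters$nLabeled, counters$nStreamlines, counters$nDropped,
    unlabeledWM))
  invisible(c(list(outPath = config$outPath, sidecarPath = sidecar),
              counters))
}

#' Write a phantom scene to disk
#'
#' Materializes [makePhantom()] outputs as standard files consumable by
#' the command-line tools: \code{cortex.nii.gz}, \code{wm_mask.nii.gz},
#' \code{directions.nii.gz} + \code{tracking_mask.nii.gz},
#' \code{truth.nii.gz}, \code{crossing_mask.nii.gz}.
#'
#' @param spec a [PhantomSpec-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named list of file paths.
#' @export
writePhantom <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- makePhantom(spec)
  paths <- list(
    cortex = file.path(dir, "cortex.nii.gz"),
    wmMask = file.path(dir, "wm_mask.nii.gz"),
    directions = file.path(dir, "directions.nii.gz"),
    trackingMask = file.path(dir, "tracking_mask.nii.gz"),
    truth = file.path(dir, "truth.nii.gz"),
    crossingMask = file.path(dir, "crossing_mask.nii.gz"))
  writeLabelVolume(ph$cortex, paths$cortex)
  writeMaskVolume(ph$wmMask, paths$wmMask)
  writeDirectionField(ph$directions, paths$directions, paths$trackingMask)
  writeLabelVolume(ph$truth, paths$truth)
  writeMaskVolume(ph$crossingMask, paths$crossingMask)
  invisible(paths)
}
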