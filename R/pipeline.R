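#' Run the full delineation-to-map pipeline
#'
#' End-to-end driver: calibrate scale, segment the orthoimage, label crown
#' regions, forecast per-tree yield from crown area, and write the thematic
#' map. `config` is a named list or the path of a JSON/YAML file with
#' elements:
#' \describe{
#'   \item{input}{path of an orthoimage (PNG/TIFF), or a named list of
#'     [orchardSpec()] arguments under `simulate` to generate one.}
#'   \item{pixelSize / scaleReference}{exactly one scale source: the ground
#'     sample distance in m/pixel, or `list(px = , m = )` for
#'     [calibrateScale()]. Not needed when simulating or when the image has
#'     a sidecar.}
#'   \item{segmentation}{arguments for [segmentationParams()]; omit
#'     thresholds to use [suggestThresholds()].}
#'   \item{regime}{forecast regime (default `"general"`).}
#'   \item{classes}{yield class count (default 5).}
#'   \item{outDir}{output directory (created).}
#'   \item{seed}{RNG seed; identical config + seed gives identical outputs.}
#'   \item{verbose}{print stage messages (default TRUE).}
#' }
#' Outputs written to `outDir`: `regions.csv`, `regions.geojson`,
#' `yield_map.geojson`, `yield_map.csv`, `yield_map.png`, `run_log.json`
#' (full parameter echo), and for simulated inputs `orthoimage.png` (+
#' sidecar) and `ground_truth.csv`. Any stage failure aborts with a
#' stage-named classed error before partial map outputs are written.
#'
#' @param config named list or config file path.
#' @return invisibly, a list with the region set, the yield map and the
#'   output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!is.list(config)) validationError("config must be a list or a file path")
  verbose <- !identical(config$verbose, FALSE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                          class = c(class(e)[1], "pipelineError", "error")))
    })
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  outDir <- config$outDir
  if (is.null(outDir)) validationError("config needs an outDir")

  trees <- NULL
  img <- stage("input", {
    if (!is.null(config$simulate)) {
      spec <- do.call(orchardSpec, config$simulate)
      say("simulate: generating %s %s orchard", spec@regime, spec@category)
      trees <- generateOrchard(spec)
      attr(trees, "spec") <- spec
      renderOrthoimage(trees, spec)
    } else if (!is.null(config$input)) {
      if (!file.exists(config$input)) ioError("input not found: %s", config$input)
      ps <- config$pixelSize
      if (!is.null(config$scaleReference)) {
        if (!is.null(ps))
          validationError("give exactly one scale source (pixelSize or scaleReference)")
        ps <- calibrateScale(config$scaleReference$px, config$scaleReference$m)
      }
      readOrthoimage(config$input, pixelSize = ps)
    } else validationError("config needs either input or simulate")
  })
  say("input: %d x %d px at %.4g m/px", dim(img)[1], dim(img)[2], pixelSize(img))

  params <- stage("segment", {
    sg <- if (is.null(config$segmentation)) list() else config$segmentation
    channel <- if (is.null(sg$channel)) "green" else sg$channel
    if (is.null(sg$groundThreshold) || is.null(sg$shadowThreshold)) {
      thr <- suggestThresholds(extractChannel(img, channel))
      say("segment: auto thresholds ground=%g shadow=%g", thr$ground, thr$shadow)
      sg$groundThreshold <- thr$ground
      sg$shadowThreshold <- thr$shadow
    }
    sg$channel <- channel
    do.call(segmentationParams, sg)
  })
  mask <- stage("segment", segmentCanopy(img, params))

  regions <- stage("label", labelRegions(mask, pixelSize(img),
                                         connectivity = params$connectivity,
                                         minArea = params$minArea,
                                         maxArea = params$maxArea,
                                         origin = imageOrigin(img)))
  say("label: %d crown region(s)", length(regions))
  if (length(regions) == 0L) validationError("[label] no crown regions found")

  regime <- if (is.null(config$regime)) "general" else config$regime
  map <- stage("forecast", {
    classes <- if (is.null(config$classes)) 5L else as.integer(config$classes)
    buildYieldMap(regions, regime = regime, classCount = classes,
                  edges = config$classEdges)
  })
  say("forecast: OAY estimate %.0f kg/ha over %.2f ha", map@totalOAY,
      map@footprintHa)

  paths <- stage("write", {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- list(regionsCsv = file.path(outDir, "regions.csv"),
              regionsGeojson = file.path(outDir, "regions.geojson"),
              mapGeojson = file.path(outDir, "yield_map.geojson"),
              mapCsv = file.path(outDir, "yield_map.csv"),
              mapPng = file.path(outDir, "yield_map.png"),
              runLog = file.path(outDir, "run_log.json"))
    writeRegionsCSV(regions, p$regionsCsv)
    writeRegionsGeoJSON(regions, p$regionsGeojson)
    exportYieldMap(map, p$mapGeojson, "geojson")
    exportYieldMap(map, p$mapCsv, "csv")
    exportYieldMap(map, p$mapPng, "png")
    if (!is.null(trees)) {
      p$groundTruth <- file.path(outDir, "ground_truth.csv")
      writeGroundTruth(trees, p$groundTruth)
      p$orthoimage <- file.path(outDir, "orthoimage.png")
      writeOrthoimage(img, p$orthoimage,
                      extra = list(seed = config$seed))
    }
    jsonlite::write_json(list(
      config = config[setdiff(names(config), "verbose")],
      seed = config$seed,
      segmentation = params[c("groundThreshold", "shadowThreshold", "channel",
                              "minArea", "connectivity")],
      regime = regime, n_regions = length(regions),
      oay_kg_ha = map@totalOAY), p$runLog, auto_unbox = TRUE, digits = NA,
      null = "null", force = TRUE)
    p
  })
  say("write: outputs in %s", outDir)
  invisible(list(regions = regions, map = map, trees = trees, paths = paths))
}

#' @rdname runPipeline
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) config file.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) ioError("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      ioError("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else ioError("unsupported config format: .%s", ext)
}
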