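# Readers/writers for images, layouts and call tables, plus the end-to-end
# pipeline orchestrator with provenance logging.

#' Read a TIFF or PNG intensity image
#'
#' Reads 8- or 16-bit single-page or multi-page images into numeric arrays
#' in original intensity units (0..2^bits - 1).  Multi-page TIFFs come back
#' as a rows x cols x pages array.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return list with \code{data} (matrix or 3D array), \code{bits} and
#'   \code{pages}.
#' @export
readImage <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("cannot read TIFF file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    if (!length(pages))
      stop("cannot read TIFF file '", path, "': no pages", call. = FALSE)
    if (length(dim(pages[[1]])) == 3L)
      stop("multi-channel TIFF pages are not supported: ", path,
           call. = FALSE)
    bits <- if (max(vapply(pages, max, numeric(1))) > 255) 16L else 8L
    data <- if (length(pages) == 1L) pages[[1]]
      else array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    return(list(data = data, bits = bits, pages = length(pages)))
  }
  if (ext == "png") {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e)
                      stop("cannot read PNG file '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    if (length(dim(img)) == 3L)
      stop("multi-channel PNG images are not supported: ", path,
           call. = FALSE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    return(list(data = img * (2^bits - 1), bits = bits, pages = 1L))
  }
  stop("unsupported image format '", ext, "' for file: ", path,
       call. = FALSE)
}

#' Write a 16-bit (multi-page) TIFF image
#'
#' @param path output path.
#' @param image numeric matrix, 3D array (rows x cols x pages) or list of
#'   matrices, in intensity counts.
#' @param bits bit depth (8 or 16).
#' @return invisibly, the path.
#' @export
writeImageStack <- function(path, image, bits = 16) {
  scale <- 2^bits - 1
  toPage <- function(m) pmin(pmax(m / scale, 0), 1)
  pages <- if (is.list(image)) lapply(image, toPage)
    else if (is.matrix(image)) list(toPage(image))
    else lapply(seq_len(dim(image)[3]), function(k) toPage(image[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Write / read a chamber layout (CSV plus sidecar JSON)
#'
#' The CSV holds one column per row with header \code{cx_um,cy_um,r_um};
#' chamber dimensions go to a sidecar JSON
#' (\code{width_um,height_um,depth_um}) next to the CSV.
#'
#' @param layout a [ChamberLayout-class].
#' @param csvPath output CSV path; the sidecar is \code{<csvPath>.json}.
#' @return invisibly, the CSV path.
#' @export
writeLayout <- function(layout, csvPath) {
  stopifnot(is(layout, "ChamberLayout"))
  cols <- layoutColumns(layout)
  utils::write.csv(data.frame(cx_um = cols$cx, cy_um = cols$cy,
                              r_um = cols$r),
                   csvPath, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(width_um = layout@width,
                            height_um = layout@height,
                            depth_um = layout@depth),
                       paste0(csvPath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(csvPath)
}

#' @rdname writeLayout
#' @param csvPath layout CSV path; dimensions are read from
#'   \code{<csvPath>.json}.
#' @export
readLayout <- function(csvPath) {
  tab <- utils::read.csv(csvPath)
  if (!all(c("cx_um", "cy_um", "r_um") %in% names(tab)))
    stop("layout CSV must have header cx_um,cy_um,r_um", call. = FALSE)
  side <- paste0(csvPath, ".json")
  if (!file.exists(side))
    stop("missing layout sidecar JSON: ", side, call. = FALSE)
  dims <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("ChamberLayout", width = as.numeric(dims$width_um),
      height = as.numeric(dims$height_um),
      depth = as.numeric(dims$depth_um),
      columns = data.frame(cx = tab$cx_um, cy = tab$cy_um, r = tab$r_um))
}

#' Export a layout as an SVG drawing
#'
#' Minimal scalable drawing of the chamber outline and columns for visual
#' inspection (1 SVG unit = 1 um).
#'
#' @param layout a [ChamberLayout-class].
#' @param path output .svg path.
#' @return invisibly, the path.
#' @export
layoutToSvg <- function(layout, path) {
  stopifnot(is(layout, "ChamberLayout"))
  cols <- layoutColumns(layout)
  circ <- sprintf(
    '  <circle cx="%.2f" cy="%.2f" r="%.2f" fill="#888" stroke="none"/>',
    cols$cx, cols$cy, cols$r)
  svg <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'viewBox="0 0 %.0f %.0f">'),
                   layout@width, layout@height),
           sprintf(paste0('  <rect x="0" y="0" width="%.0f" height="%.0f" ',
                          'fill="white" stroke="black"/>'),
                   layout@width, layout@height),
           circ, "</svg>")
  writeLines(svg, path)
  invisible(path)
}

#' Write / read a per-region call table
#'
#' CSV with columns \code{region_id,flow,wt_call,mut_call,mean_gfp,
#' mean_mcherry,area_um2}.
#'
#' @param calls calls data.frame (see [analyzeChamberImages()]).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeRegionCalls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRegionCalls
#' @export
readRegionCalls <- function(path) {
  calls <- utils::read.csv(path)
  calls$wt_call <- as.logical(calls$wt_call)
  calls$mut_call <- as.logical(calls$mut_call)
  calls
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the region pipeline so that a serialized config
#' plus seed fully determines a run.
#'
#' @param seed integer seed for any stochastic step.
#' @param umPerPx physical pixel size (um).
#' @param occupancyMethod \code{"otsu"} or \code{"k_sigma"}.
#' @param kSigma multiplier for the k-sigma occupancy rule.
#' @param minCoverage streak coverage threshold for an open flow call.
#' @param channelMap named character vector mapping strains to image
#'   channels, e.g. \code{c(wt = "gfp", mutant = "mcherry")}.
#' @param rRangeUm expected column radius range (um) for detection.
#' @return a validated config list.
#' @export
runConfig <- function(seed = 1, umPerPx = 2, occupancyMethod = "k_sigma",
                      kSigma = 5, minCoverage = 0.001,
                      channelMap = c(wt = "gfp", mutant = "mcherry"),
                      rRangeUm = c(40, 240)) {
  occupancyMethod <- match.arg(occupancyMethod, c("otsu", "k_sigma"))
  if (!setequal(names(channelMap), c("wt", "mutant")) ||
      !setequal(unname(channelMap), c("gfp", "mcherry")))
    stop("'channelMap' must map wt and mutant onto gfp and mcherry",
         call. = FALSE)
  assertScalarNum(umPerPx, "umPerPx", lower = 0, strictLower = TRUE)
  assertScalarNum(minCoverage, "minCoverage", lower = 0)
  list(seed = as.integer(seed), umPerPx = umPerPx,
       occupancyMethod = occupancyMethod, kSigma = kSigma,
       minCoverage = minCoverage, channelMap = channelMap,
       rRangeUm = rRangeUm)
}

#' Run the full region/co-occurrence pipeline on one chamber replicate
#'
#' Orchestrates column detection (or layout registration), tessellation,
#' per-region mean intensities, occupancy calls for both strains, bead
#' frame integration, flow scoring and area-normalized occurrence
#' summaries.  When \code{outDir} is given, writes \code{calls.csv},
#' \code{occurrence.csv}, \code{tessellation.json}, \code{config.json} and
#' a \code{provenance.json} (config MD5, seed, package and R versions), so
#' a run is fully reproducible and auditable.
#'
#' @param gfp,mcherry image channels: numeric matrices or file paths.
#' @param beads bead-streak stack: 3D array, list of matrices, or file
#'   path of a multi-page TIFF.
#' @param layout optional [ChamberLayout-class] or layout CSV path; when
#'   NULL, columns are detected from the images.
#' @param config a [runConfig()] list.
#' @param outDir optional output directory.
#' @return list with \code{tessellation}, \code{calls}, \code{occurrence},
#'   \code{provenance}.
#' @export
runPipeline <- function(gfp, mcherry, beads, layout = NULL,
                        config = runConfig(), outDir = NULL) {
  loadChannel <- function(x) if (is.character(x)) readImage(x)$data else x
  images <- list(gfp = loadChannel(gfp), mcherry = loadChannel(mcherry))
  beads <- loadChannel(beads)
  if (is.character(layout)) layout <- readLayout(layout)
  columns <- if (!is.null(layout))
    columnsFromLayout(layout, config$umPerPx) else NULL
  cm <- config$channelMap
  res <- tryCatch(
    analyzeChamberImages(images[[cm[["wt"]]]], images[[cm[["mutant"]]]],
                         beads, columns = columns,
                         umPerPx = config$umPerPx,
                         rRangePx = config$rRangeUm / config$umPerPx,
                         occupancyMethod = config$occupancyMethod,
                         minCoverage = config$minCoverage),
    error = function(e) stop("region-analysis stage failed: ",
                             conditionMessage(e), call. = FALSE))
  calls <- res$calls
  # report intensities under their physical channel names regardless of the
  # strain-to-channel mapping
  if (cm[["wt"]] != "gfp") {
    tmp <- calls$mean_gfp
    calls$mean_gfp <- calls$mean_mcherry
    calls$mean_mcherry <- tmp
  }
  occurrence <- occurrenceByFlowClass(calls)
  provenance <- list(package = "soilchip",
                     version = as.character(utils::packageVersion("soilchip")),
                     r_version = R.version.string,
                     seed = config$seed,
                     config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgPath <- file.path(outDir, "config.json")
    jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA)
    provenance$config_md5 <- unname(tools::md5sum(cfgPath))
    writeRegionCalls(calls, file.path(outDir, "calls.csv"))
    utils::write.csv(occurrence, file.path(outDir, "occurrence.csv"),
                     row.names = FALSE, quote = FALSE)
    tess <- res$tessellation
    jsonlite::write_json(
      list(nodes = unname(apply(tess@nodes, 1, c, simplify = FALSE)),
           radii_px = tess@radii,
           triangles = unname(apply(tess@triangles, 1, c,
                                    simplify = FALSE)),
           effective_area_um2 = effectiveArea(tess, "um2")),
      file.path(outDir, "tessellation.json"), digits = NA)
    jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tessellation = res$tessellation, calls = calls,
       occurrence = occurrence, provenance = provenance)
}
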