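# Tessellation-based region analysis: column detection, Delaunay sampling
# regions with column area removed, per-region intensity, occupancy and flow
# calls.

# Rasterize column disks into a logical mask.  Pixel (i, j) has center
# (j - 0.5, i - 0.5) in continuous pixel coordinates.
rasterizeColumns <- function(columns, imageDim) {
  mask <- matrix(FALSE, imageDim[1], imageDim[2])
  if (!nrow(columns)) return(mask)
  for (k in seq_len(nrow(columns))) {
    cx <- columns$cx[k]; cy <- columns$cy[k]; r <- columns$r[k]
    rows <- max(1L, floor(cy - r)):min(imageDim[1], ceiling(cy + r + 1))
    cols <- max(1L, floor(cx - r)):min(imageDim[2], ceiling(cx + r + 1))
    dx2 <- (cols - 0.5 - cx)^2
    dy2 <- (rows - 0.5 - cy)^2
    mask[rows, cols] <- mask[rows, cols] | outer(dy2, dx2, "+") <= r^2
  }
  mask
}

#' Convert a physical layout to pixel-space columns
#'
#' @param layout a [ChamberLayout-class].
#' @param umPerPx physical pixel size in micrometers.
#' @return data.frame \code{cx}, \code{cy}, \code{r} in continuous pixel
#'   coordinates, with attribute \code{source = "layout_file"}.
#' @export
columnsFromLayout <- function(layout, umPerPx) {
  stopifnot(is(layout, "ChamberLayout"))
  assertScalarNum(umPerPx, "umPerPx", lower = 0, strictLower = TRUE)
  cols <- layoutColumns(layout)
  out <- data.frame(cx = cols$cx / umPerPx, cy = cols$cy / umPerPx,
                    r = cols$r / umPerPx)
  attr(out, "source") <- "layout_file"
  out
}

#' Detect obstacle columns in a fluorescence image
#'
#' Columns appear as near-zero-intensity disks against the fluorescent
#' background.  Pixels darker than \code{darkFrac} times the image median are
#' segmented, connected components are labelled, and each component is
#' summarized by its centroid and area-equivalent radius
#' r = sqrt(area / pi).  Components touching the image border or with radii
#' outside \code{rRangePx} are discarded.
#'
#' @param image numeric matrix, a single fluorescence channel.
#' @param rRangePx length-2 numeric, admissible column radius range in
#'   pixels.
#' @param darkFrac dark threshold as a fraction of the median intensity.
#' @return data.frame \code{cx}, \code{cy}, \code{r} (pixels) with attribute
#'   \code{source = "detected"}, ordered by (cy, cx).
#' @export
detectColumns <- function(image, rRangePx, darkFrac = 0.5) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix", call. = FALSE)
  if (length(rRangePx) != 2L || rRangePx[1] <= 0 || diff(rRangePx) < 0)
    stop("'rRangePx' must be an increasing positive range", call. = FALSE)
  thr <- darkFrac * stats::median(image)
  mask <- image < thr
  if (!any(mask))
    stop(paste("no columns detected; supply a layout file via",
               "columnsFromLayout()"), call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  ij <- arrayInd(idx, dim(lab))
  lb <- lab[idx]
  area <- tabulate(lb)
  cy <- tapply(ij[, 1] - 0.5, lb, mean)
  cx <- tapply(ij[, 2] - 0.5, lb, mean)
  r <- sqrt(area / pi)
  # reject partial disks at the border and out-of-range components
  rmin <- tapply(ij[, 1], lb, min); rmax <- tapply(ij[, 1], lb, max)
  cmin <- tapply(ij[, 2], lb, min); cmax <- tapply(ij[, 2], lb, max)
  keep <- r >= rRangePx[1] & r <= rRangePx[2] &
    rmin > 1 & cmin > 1 & rmax < nrow(image) & cmax < ncol(image)
  if (!any(keep))
    stop(paste("no columns detected within the expected radius range;",
               "supply a layout file via columnsFromLayout()"),
         call. = FALSE)
  out <- data.frame(cx = as.numeric(cx[keep]), cy = as.numeric(cy[keep]),
                    r = r[keep])
  out <- out[order(out$cy, out$cx), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- "detected"
  out
}

#' Tessellate a chamber image into triangular sampling regions
#'
#' Realizes the network-structure quantification scheme: column centers are
#' nodes, straight lines between centers are edges, and the Delaunay
#' triangulation of the nodes partitions the imaged chamber into triangular
#' sampling regions.  Each triangle is rasterized at image resolution (a
#' pixel belongs to the triangle containing its center; boundary pixels go
#' to the lowest-id triangle) and the pixels covered by columns are removed
#' from its effective mask.  Regions outside the node convex hull are not
#' analyzed.
#'
#' @param columns data.frame \code{cx}, \code{cy}, \code{r} in pixels, from
#'   [detectColumns()] or [columnsFromLayout()].
#' @param imageDim integer length-2, image dimensions (rows, cols).
#' @param umPerPx physical pixel size in micrometers.
#' @return a [Tessellation-class].
#' @export
tessellate <- function(columns, imageDim, umPerPx = 1) {
  if (!is.data.frame(columns) || !all(c("cx", "cy", "r") %in% names(columns)))
    stop("'columns' must be a data.frame with cx, cy, r", call. = FALSE)
  if (nrow(columns) < 3L)
    stop("degenerate geometry: need at least 3 columns", call. = FALSE)
  # canonical node order so that layout-registered and detected columns
  # yield identical region ids
  columns <- columns[order(columns$cy, columns$cx), , drop = FALSE]
  x <- columns$cx; y <- columns$cy
  # collinearity check via the largest triangle area among extreme points
  M <- cbind(x - mean(x), y - mean(y))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: column centers are collinear", call. = FALSE)
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (!length(tl))
    stop("degenerate geometry: triangulation is empty", call. = FALSE)
  tri <- t(vapply(tl, function(d) sort(d$ptNum), integer(3)))
  # deterministic region ids: lexicographic by sorted node indices
  ord <- order(tri[, 1], tri[, 2], tri[, 3])
  tri <- tri[ord, , drop = FALSE]
  imageDim <- as.integer(imageDim)
  map <- matrix(0L, imageDim[1], imageDim[2])
  for (t_ in seq_len(nrow(tri))) {
    xa <- x[tri[t_, ]]; ya <- y[tri[t_, ]]
    rows <- max(1L, floor(min(ya))):min(imageDim[1], ceiling(max(ya)) + 1L)
    cols <- max(1L, floor(min(xa))):min(imageDim[2], ceiling(max(xa)) + 1L)
    if (!length(rows) || !length(cols)) next
    px <- rep(cols - 0.5, each = length(rows))
    py <- rep(rows - 0.5, times = length(cols))
    # barycentric containment with boundary tolerance
    d <- (ya[2] - ya[3]) * (xa[1] - xa[3]) + (xa[3] - xa[2]) * (ya[1] - ya[3])
    l1 <- ((ya[2] - ya[3]) * (px - xa[3]) + (xa[3] - xa[2]) * (py - ya[3])) / d
    l2 <- ((ya[3] - ya[1]) * (px - xa[3]) + (xa[1] - xa[3]) * (py - ya[3])) / d
    l3 <- 1 - l1 - l2
    tol <- 1e-9
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    sub <- map[rows, cols]
    sel <- inside & sub == 0L
    sub[sel] <- t_
    map[rows, cols] <- sub
  }
  colMask <- rasterizeColumns(columns, imageDim)
  m <- nrow(tri)
  inReg <- map > 0L
  effPx <- tabulate(map[inReg & !colMask], nbins = m)
  colPx <- tabulate(map[inReg & colMask], nbins = m)
  new("Tessellation", nodes = cbind(x, y), radii = columns$r,
      triangles = tri, regionMap = map, columnMask = colMask,
      effectiveAreaPx = as.numeric(effPx), columnAreaPx = as.numeric(colPx),
      umPerPx = umPerPx)
}

#' Mean fluorescence intensity per sampling region
#'
#' Averages pixel intensities over each region's effective mask (column
#' pixels excluded).  Regions with no effective pixels get NA.
#'
#' @param image numeric matrix matching the tessellation raster.
#' @param tess a [Tessellation-class].
#' @return numeric vector of per-region means.
#' @export
regionMeanIntensity <- function(image, tess) {
  stopifnot(is(tess, "Tessellation"))
  if (!is.matrix(image) || !identical(dim(image), dim(tess@regionMap)))
    stop("image dimensions do not match the tessellation raster",
         call. = FALSE)
  m <- nRegions(tess)
  eff <- tess@regionMap > 0L & !tess@columnMask
  g <- tess@regionMap[eff]
  rs <- rowsum(image[eff], g)
  sums <- as.numeric(rs)
  ids <- as.integer(rownames(rs))
  out <- rep(NA_real_, m)
  out[ids] <- sums / tess@effectiveAreaPx[ids]
  out
}

#' Otsu threshold of a numeric sample
#'
#' Exhaustive sweep over midpoints between consecutive sorted unique values,
#' maximizing the between-class variance.  Used on per-region mean
#' intensities rather than pixel histograms, so no binning is involved.
#'
#' @param x numeric values.
#' @return the threshold; values strictly above it fall in the upper class.
#' @export
otsuThreshold <- function(x) {
  u <- sort(unique(x[is.finite(x)]))
  if (length(u) < 2L) return(Inf)
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; thr <- Inf
  xs <- sort(x[is.finite(x)])
  n <- length(xs)
  csum <- cumsum(xs)
  for (cc in cand) {
    k <- findInterval(cc, xs)       # size of lower class
    if (k == 0L || k == n) next
    m0 <- csum[k] / k
    m1 <- (csum[n] - csum[k]) / (n - k)
    bc <- k * (n - k) * (m0 - m1)^2
    if (bc > best) { best <- bc; thr <- cc }
  }
  thr
}

#' Call per-region biofilm occupancy from mean intensities
#'
#' Thresholds region mean intensities to decide whether biofilm accumulated
#' in each region.  \code{"otsu"} maximizes between-class variance across
#' regions; \code{"k_sigma"} first isolates the background class with an
#' Otsu split, then thresholds at background median + k * MAD of the
#' background class.  Because biofilm cluster sizes vary widely, occupied
#' regions form a long-tailed rather than compact intensity class, which
#' makes the background-anchored \code{"k_sigma"} rule the more sensitive
#' default inside the pipeline.  Ties at the threshold are called negative.
#' \code{minSeparation} is a floor on the margin above the background
#' median required for a positive call, guarding against purely
#' noise-driven splits (0 disables it; pipelines set it from the image
#' noise level).
#'
#' @param means numeric per-region mean intensities (NA regions are called
#'   negative).
#' @param method \code{"otsu"} or \code{"k_sigma"}.
#' @param k MAD multiplier for the \code{"k_sigma"} rule.
#' @param minSeparation minimum intensity margin above the background
#'   median required for a positive call.
#' @param background known background intensity level (e.g. the median of
#'   the column-free image pixels).  When NULL, the \code{"k_sigma"} rule
#'   estimates the background class with an Otsu split of the means, which
#'   is reliable only while unoccupied regions are common.
#' @return logical vector of occupancy calls.
#' @export
callOccupancy <- function(means, method = c("otsu", "k_sigma"), k = 5,
                          minSeparation = 0, background = NULL) {
  method <- match.arg(method)
  ok <- is.finite(means)
  if (sum(ok) < 4L)
    stop("need at least 4 regions with defined means", call. = FALSE)
  vals <- means[ok]
  if (length(unique(vals)) == 1L) {
    warning("all region means identical; calling every region negative")
    return(rep(FALSE, length(means)))
  }
  thr <- if (method == "otsu") {
    split <- otsuThreshold(vals)
    max(split, stats::median(vals[vals <= split]) + minSeparation)
  } else {
    split <- otsuThreshold(vals)
    bgMed <- stats::median(vals[vals <= split])
    # an externally supplied background (e.g. the image pixel median) can
    # only lower the estimate: the Otsu class median is biased upward when
    # occupied regions dominate, the pixel median when blobs are bright
    if (!is.null(background)) bgMed <- min(bgMed, background)
    # scale of the mean noise, from the (reflected) sub-background means
    lo <- vals[vals <= bgMed]
    noiseEst <- if (length(lo) >= 2L)
      robustSd(c(lo, 2 * bgMed - lo)) else 0
    if (!is.finite(noiseEst)) noiseEst <- 0
    bgMed + max(k * noiseEst, minSeparation)
  }
  out <- !is.na(means) & means > thr
  out[!ok] <- FALSE
  out
}

#' Integrate a bead-streak frame stack
#'
#' Pixelwise maximum projection across frames, so that the integrated image
#' covers the union of flow corridors sampled by beads in any frame.
#'
#' @param stack a 3D numeric array (rows x cols x frames) or a list of
#'   matrices.
#' @return numeric matrix, the integrated image.
#' @export
integrateBeadFrames <- function(stack) {
  if (is.list(stack)) {
    if (!length(stack)) stop("empty bead stack", call. = FALSE)
    out <- stack[[1]]
    for (f in stack[-1]) out <- pmax(out, f)
    return(out)
  }
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("'stack' must be a matrix, 3D array or list of matrices",
         call. = FALSE)
  apply(stack, c(1, 2), max)
}

#' Score per-region flow presence from an integrated bead image
#'
#' Streak pixels are segmented at background median + 5 * MAD; a region is
#' called \code{open} when the streak-pixel fraction of its effective mask
#' is at least \code{minCoverage} (the boundary case counts as open),
#' otherwise \code{blocked}.
#'
#' @param integrated numeric matrix from [integrateBeadFrames()].
#' @param tess a [Tessellation-class].
#' @param minCoverage minimum streak coverage fraction for an open call.
#' @return factor with levels \code{open}, \code{blocked}, one per region.
#' @export
scoreFlow <- function(integrated, tess, minCoverage = 0.001) {
  stopifnot(is(tess, "Tessellation"))
  if (!identical(dim(integrated), dim(tess@regionMap)))
    stop("image dimensions do not match the tessellation raster",
         call. = FALSE)
  thr <- stats::median(integrated) + 5 * robustSd(as.numeric(integrated))
  streak <- integrated > thr
  if (!any(streak)) {
    warning("no streak pixels found; scoring every region as blocked")
    return(factor(rep("blocked", nRegions(tess)),
                  levels = c("open", "blocked")))
  }
  eff <- tess@regionMap > 0L & !tess@columnMask
  g <- tess@regionMap[eff]
  hits <- tabulate(g[streak[eff]], nbins = nRegions(tess))
  cov <- ifelse(tess@effectiveAreaPx > 0,
                hits / tess@effectiveAreaPx, 0)
  factor(ifelse(cov >= minCoverage, "open", "blocked"),
         levels = c("open", "blocked"))
}

#' Analyze one chamber replicate end-to-end
#'
#' Runs the full region pipeline on a two-channel scene plus bead stack:
#' column detection (or layout registration), tessellation, per-region
#' means, occupancy calls for both channels, bead-frame integration and flow
#' scoring.  The occupancy guard margin is estimated from the image noise
#' (5 x pixel MAD / sqrt(median effective region area)).
#'
#' @param gfp,mcherry numeric matrices, the two fluorescence channels.
#' @param beads 3D array or list of bead-streak frames.
#' @param columns optional pixel-space column table; when NULL, columns are
#'   detected from the \code{gfp} channel.
#' @param umPerPx physical pixel size (um).
#' @param rRangePx expected column radius range in pixels for detection.
#' @param occupancyMethod threshold rule passed to [callOccupancy()].
#' @param minCoverage flow threshold passed to [scoreFlow()].
#' @return list with the \code{tessellation} and a \code{calls} data.frame
#'   (\code{region_id}, \code{flow}, \code{wt_call}, \code{mut_call},
#'   \code{mean_gfp}, \code{mean_mcherry}, \code{area_um2}).
#' @export
analyzeChamberImages <- function(gfp, mcherry, beads, columns = NULL,
                                 umPerPx = 2,
                                 rRangePx = c(40, 240) / umPerPx,
                                 occupancyMethod = "k_sigma",
                                 minCoverage = 0.001) {
  if (is.null(columns)) columns <- detectColumns(gfp, rRangePx)
  tess <- tessellate(columns, dim(gfp), umPerPx)
  mg <- regionMeanIntensity(gfp, tess)
  mr <- regionMeanIntensity(mcherry, tess)
  effA <- tess@effectiveAreaPx
  effPx <- tess@regionMap > 0L & !tess@columnMask
  callChannel <- function(img, means) {
    bg <- stats::median(img[effPx])
    guard <- 4 * robustSd(img[effPx]) /
      sqrt(max(1, stats::median(effA[effA > 0])))
    callOccupancy(means, occupancyMethod, minSeparation = guard,
                  background = if (occupancyMethod == "k_sigma") bg)
  }
  wt <- callChannel(gfp, mg)
  mut <- callChannel(mcherry, mr)
  flow <- scoreFlow(integrateBeadFrames(beads), tess, minCoverage)
  calls <- data.frame(region_id = seq_len(nRegions(tess)),
                      flow = as.character(flow), wt_call = wt,
                      mut_call = mut, mean_gfp = mg, mean_mcherry = mr,
                      area_um2 = effectiveArea(tess, "um2"))
  list(tessellation = tess, calls = calls)
}
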