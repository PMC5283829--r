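#' @import methods
NULL

#' Close-packed sphere bed
#'
#' A bed of spheres on a face-centered cubic (FCC) lattice used as the
#' three-dimensional model of a granular (soil-like) medium.  Coordinates are
#' in arbitrary units in which the unperturbed sphere radius is 1 and
#' touching neighbors are 2 units apart.
#'
#' @slot centers numeric matrix (n x 3) of sphere centers.
#' @slot radii numeric vector of sphere radii.
#' @slot arrangement character, lattice arrangement (currently \code{"fcc"}).
#'
#' @seealso [packSpheres()], [perturbRadii()], [crossSection()]
#' @export
setClass("PackedBed",
  representation(centers = "matrix", radii = "numeric",
                 arrangement = "character"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@centers) != 3L)
      msg <- c(msg, "'centers' must have 3 columns")
    if (length(object@radii) != nrow(object@centers))
      msg <- c(msg, "'radii' length must match number of centers")
    if (any(!is.finite(object@radii)) || any(object@radii <= 0))
      msg <- c(msg, "all radii must be finite and positive")
    if (!identical(object@arrangement, "fcc"))
      msg <- c(msg, "'arrangement' must be \"fcc\"")
    if (is.null(msg)) TRUE else msg
  })

#' Microfluidic chamber layout
#'
#' The physical arena: a rectangular chamber (micrometers) containing
#' non-overlapping circular columns (PDMS pillars) that obstruct flow.
#'
#' @slot width,height,depth chamber dimensions in micrometers; flow runs
#'   along \code{width} (x), from the inlet at x = 0 to the outlet.
#' @slot columns data.frame with columns \code{cx}, \code{cy}, \code{r}
#'   (micrometers), one circular column per row.
#'
#' @seealso [makeSoilLayout()], [scaleToPhysical()], [writeLayout()]
#' @export
setClass("ChamberLayout",
  representation(width = "numeric", height = "numeric", depth = "numeric",
                 columns = "data.frame"),
  validity = function(object) {
    msg <- NULL
    for (s in c("width", "height", "depth"))
      if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
          slot(object, s) <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    cols <- object@columns
    if (!all(c("cx", "cy", "r") %in% names(cols)))
      msg <- c(msg, "'columns' must have columns cx, cy, r")
    else if (nrow(cols)) {
      if (any(cols$r <= 0)) msg <- c(msg, "column radii must be positive")
      inside <- cols$cx - cols$r >= 0 & cols$cx + cols$r <= object@width &
                cols$cy - cols$r >= 0 & cols$cy + cols$r <= object@height
      if (!all(inside))
        msg <- c(msg, "every column disk must lie fully inside the chamber")
      if (nrow(cols) > 1L) {
        d <- as.matrix(stats::dist(cols[, c("cx", "cy")]))
        rs <- outer(cols$r, cols$r, "+")
        diag(d) <- Inf
        # small tolerance for scaled/rounded coordinates
        if (any(d < rs - 1e-6))
          msg <- c(msg, "columns must be pairwise non-overlapping")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Triangular sampling tessellation of a chamber image
#'
#' Delaunay triangulation of column centers, rasterized at image resolution.
#' Each triangle is a sampling region; pixels covered by columns are removed
#' from its effective mask.  \code{regionMap} holds, per pixel, the id of the
#' triangle whose interior contains the pixel center (0 outside the node
#' convex hull); \code{columnMask} marks column-covered pixels.
#'
#' @slot nodes numeric matrix (n x 2) of column centers, continuous pixel
#'   coordinates (x = column direction, y = row direction).
#' @slot radii numeric vector of column radii in pixels.
#' @slot triangles integer matrix (m x 3) of node indices per triangle.
#' @slot regionMap integer matrix (image rows x cols) of triangle ids.
#' @slot columnMask logical matrix, TRUE where a column covers the pixel.
#' @slot effectiveAreaPx numeric, per-region effective (column-free) pixel
#'   count.
#' @slot columnAreaPx numeric, per-region column-covered pixel count.
#' @slot umPerPx numeric scalar, physical pixel size.
#'
#' @seealso [tessellate()], [regionMeanIntensity()], [scoreFlow()]
#' @export
setClass("Tessellation",
  representation(nodes = "matrix", radii = "numeric", triangles = "matrix",
                 regionMap = "matrix", columnMask = "matrix",
                 effectiveAreaPx = "numeric", columnAreaPx = "numeric",
                 umPerPx = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@nodes) != 2L) msg <- c(msg, "'nodes' must be n x 2")
    if (ncol(object@triangles) != 3L)
      msg <- c(msg, "'triangles' must be m x 3")
    m <- nrow(object@triangles)
    if (length(object@effectiveAreaPx) != m ||
        length(object@columnAreaPx) != m)
      msg <- c(msg, "per-region area vectors must have one entry per triangle")
    if (any(object@effectiveAreaPx < 0))
      msg <- c(msg, "effective areas must be non-negative")
    if (!identical(dim(object@regionMap), dim(object@columnMask)))
      msg <- c(msg, "'regionMap' and 'columnMask' dimensions must agree")
    if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
      msg <- c(msg, "'umPerPx' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Fitted frequency-dependent selection function
#'
#' Result of [fitSelectionFunction()]: a least-squares fit of the frequency
#' change df = f72 - f0 on the basis \{f0(1-f0), f0^2(1-f0)\} (which forces
#' df to vanish at fixation), the classified selection regime, and the
#' estimated critical frequency with a percentile bootstrap confidence
#' interval.
#'
#' @slot regime character: \code{"uniform_positive"},
#'   \code{"uniform_negative"}, \code{"negative_freq_dependent"} or
#'   \code{"none"}.
#' @slot fcHat numeric, estimated critical frequency (NA when the fitted
#'   curve has no interior positive-to-negative zero crossing).
#' @slot coefficients numeric length-2, basis coefficients.
#' @slot ci numeric length-2, bootstrap percentile CI for fcHat (NA when
#'   unavailable).
#' @slot boot numeric, bootstrap replicate estimates of the crossing.
#' @slot records data.frame, the records used for the fit.
#'
#' @export
setClass("SelectionFit",
  representation(regime = "character", fcHat = "numeric",
                 coefficients = "numeric", ci = "numeric", boot = "numeric",
                 records = "data.frame"),
  validity = function(object) {
    ok <- object@regime %in% c("uniform_positive", "uniform_negative",
                               "negative_freq_dependent", "none")
    if (!ok) return("unknown regime")
    if (length(object@coefficients) != 2L)
      return("'coefficients' must have length 2")
    TRUE
  })

# show methods --------------------------------------------------------------

setMethod("show", "PackedBed", function(object) {
  cat(sprintf("PackedBed: %d spheres (%s), radii [%.3g, %.3g]\n",
              nrow(object@centers), object@arrangement,
              min(object@radii), max(object@radii)))
})

setMethod("show", "ChamberLayout", function(object) {
  cat(sprintf(
    "ChamberLayout: %.0f x %.0f x %.0f um, %d columns (r %.1f-%.1f um)\n",
    object@width, object@height, object@depth, nrow(object@columns),
    if (nrow(object@columns)) min(object@columns$r) else NA,
    if (nrow(object@columns)) max(object@columns$r) else NA))
})

setMethod("show", "Tessellation", function(object) {
  cat(sprintf(
    "Tessellation: %d nodes, %d regions on a %d x %d raster (%.3g um/px)\n",
    nrow(object@nodes), nrow(object@triangles), nrow(object@regionMap),
    ncol(object@regionMap), object@umPerPx))
})

setMethod("show", "SelectionFit", function(object) {
  cat(sprintf("SelectionFit: regime = %s\n", object@regime))
  if (is.finite(object@fcHat))
    cat(sprintf("  critical frequency f_c = %.3f (95%% CI %.3f-%.3f)\n",
                object@fcHat, object@ci[1], object@ci[2]))
  cat(sprintf("  coefficients: b1 = %.4g, b2 = %.4g; n = %d records\n",
              object@coefficients[1], object@coefficients[2],
              nrow(object@records)))
})

# accessors -----------------------------------------------------------------

#' @describeIn PackedBed sphere centers (n x 3 matrix).
#' @param object a \code{PackedBed}.
#' @export
setGeneric("sphereCenters", function(object) standardGeneric("sphereCenters"))
#' @export
setMethod("sphereCenters", "PackedBed", function(object) object@centers)

#' @describeIn PackedBed sphere radii.
#' @export
setGeneric("sphereRadii", function(object) standardGeneric("sphereRadii"))
#' @export
setMethod("sphereRadii", "PackedBed", function(object) object@radii)

#' @describeIn ChamberLayout column table (cx, cy, r in micrometers).
#' @param object a \code{ChamberLayout}.
#' @export
setGeneric("layoutColumns", function(object) standardGeneric("layoutColumns"))
#' @export
setMethod("layoutColumns", "ChamberLayout", function(object) object@columns)

#' @describeIn ChamberLayout chamber dimensions, named vector (um).
#' @export
setGeneric("chamberDims", function(object) standardGeneric("chamberDims"))
#' @export
setMethod("chamberDims", "ChamberLayout", function(object)
  c(width = object@width, height = object@height, depth = object@depth))

#' @describeIn Tessellation number of triangular sampling regions.
#' @param object a \code{Tessellation}.
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))
#' @export
setMethod("nRegions", "Tessellation", function(object)
  nrow(object@triangles))

#' Per-region effective (column-free) area
#'
#' @param object a [Tessellation-class].
#' @param units \code{"px"} for pixel counts or \code{"um2"} for square
#'   micrometers.
#' @return numeric vector, one entry per region.
#' @export
setGeneric("effectiveArea",
           function(object, units = c("px", "um2"))
             standardGeneric("effectiveArea"))
#' @rdname effectiveArea
#' @export
setMethod("effectiveArea", "Tessellation", function(object,
                                                    units = c("px", "um2")) {
  units <- match.arg(units)
  a <- object@effectiveAreaPx
  if (units == "um2") a <- a * object@umPerPx^2
  a
})

#' Region centroids in pixel coordinates
#'
#' Centroids of the triangle vertices (not of the effective masks), used for
#' routing bead paths and orienting the chamber.
#'
#' @param object a [Tessellation-class].
#' @return numeric matrix (regions x 2), columns \code{x}, \code{y}.
#' @export
setGeneric("regionCentroids",
           function(object) standardGeneric("regionCentroids"))
#' @rdname regionCentroids
#' @export
setMethod("regionCentroids", "Tessellation", function(object) {
  tri <- object@triangles
  cbind(x = rowMeans(matrix(object@nodes[tri, 1], nrow(tri), 3)),
        y = rowMeans(matrix(object@nodes[tri, 2], nrow(tri), 3)))
})

#' Region adjacency (shared triangulation edge)
#'
#' @param object a [Tessellation-class].
#' @return logical matrix (regions x regions), TRUE where two triangles share
#'   an edge.
#' @export
setGeneric("regionAdjacency",
           function(object) standardGeneric("regionAdjacency"))
#' @rdname regionAdjacency
#' @export
setMethod("regionAdjacency", "Tessellation", function(object) {
  adjL <- adjacencyList(object)
  m <- length(adjL)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) adj[i, adjL[[i]]] <- TRUE
  adj
})

# Neighbor index list per region (shared triangulation edge), the fast
# representation used by connectivity computations.
adjacencyList <- function(tess) {
  tri <- tess@triangles
  m <- nrow(tri)
  edges <- rbind(cbind(tri[, 1], tri[, 2], seq_len(m)),
                 cbind(tri[, 2], tri[, 3], seq_len(m)),
                 cbind(tri[, 1], tri[, 3], seq_len(m)))
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  sp <- split(edges[, 3], ek)
  out <- vector("list", m)
  for (ids in sp) if (length(ids) == 2L) {
    out[[ids[1]]] <- c(out[[ids[1]]], ids[2])
    out[[ids[2]]] <- c(out[[ids[2]]], ids[1])
  }
  lapply(out, function(v) if (is.null(v)) integer(0) else sort(v))
}
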