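# Soil-mimicking chamber geometry: packed-sphere bed, oblique cross-section,
# physical scaling, and wall shear stress for rectangular channels.

#' Generate a close-packed (FCC) bed of unit spheres
#'
#' Builds the three-dimensional granular model from which soil-mimicking
#' column layouts are cut.  Spheres of radius 1 (arbitrary units) sit on a
#' face-centered cubic lattice, the canonical close packing: sites are all
#' integer triples (i, j, k) with even coordinate sum, scaled by sqrt(2) so
#' that nearest neighbors touch (center distance 2).
#'
#' @param nPerAxis number of conventional cubic cells per axis (>= 2); the
#'   lattice spans i, j, k in 0..2*nPerAxis inclusive.
#' @param seed unused (the lattice is deterministic); accepted for interface
#'   symmetry with the other generators.
#' @return a [PackedBed-class] with all radii equal to 1.
#' @examples
#' bed <- packSpheres(2)
#' range(sphereRadii(bed))
#' @export
packSpheres <- function(nPerAxis, seed = NULL) {
  if (!is.numeric(nPerAxis) || length(nPerAxis) != 1L ||
      nPerAxis != round(nPerAxis) || nPerAxis < 2)
    stop("'nPerAxis' must be an integer >= 2", call. = FALSE)
  m <- 2L * as.integer(nPerAxis)
  g <- expand.grid(i = 0:m, j = 0:m, k = 0:m)
  g <- g[(g$i + g$j + g$k) %% 2L == 0L, , drop = FALSE]
  centers <- sqrt(2) * as.matrix(g)
  dimnames(centers) <- NULL
  new("PackedBed", centers = centers, radii = rep(1, nrow(centers)),
      arrangement = "fcc")
}

#' Perturb sphere radii to emulate grain-size heterogeneity
#'
#' Each sphere radius is redrawn i.i.d. uniform on \[rMin, rMax\] (defaults
#' 0.4 to 1.0 in units of the unperturbed radius), leaving centers unchanged.
#' Since radii never exceed 1 and touching centers are 2 apart, perturbed
#' spheres remain pairwise disjoint.
#'
#' @param bed a [PackedBed-class].
#' @param rMin,rMax bounds of the uniform radius distribution,
#'   0 < rMin <= rMax <= 1.
#' @param seed integer seed for reproducible draws (NULL: use current RNG
#'   state).
#' @return a [PackedBed-class] with perturbed radii.
#' @export
perturbRadii <- function(bed, rMin = 0.4, rMax = 1.0, seed = NULL) {
  stopifnot(is(bed, "PackedBed"))
  assertScalarNum(rMin, "rMin", lower = 0, strictLower = TRUE)
  assertScalarNum(rMax, "rMax", upper = 1)
  if (rMin > rMax) stop("'rMin' must be <= 'rMax'", call. = FALSE)
  n <- nrow(bed@centers)
  radii <- withSeed(seed, stats::runif(n, rMin, rMax))
  new("PackedBed", centers = bed@centers, radii = radii,
      arrangement = bed@arrangement)
}

# Unit normals of the FCC symmetry-plane families {100}, {110}, {111}.
latticeSymmetryNormals <- function() {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  v / sqrt(rowSums(v^2))
}

#' Cut an oblique planar cross-section through a sphere bed
#'
#' Intersects the bed with the plane \{x : n.x = offset\}.  A sphere whose
#' center lies at distance d < r from the plane contributes a circle of
#' radius sqrt(r^2 - d^2) at its projected center, reported in an in-plane
#' orthonormal coordinate frame.  Planes parallel (within \code{minAngleDeg})
#' to a lattice symmetry plane are rejected: an oblique cut is required to
#' obtain an irregular, soil-like pattern rather than a crystalline one.
#'
#' @param bed a [PackedBed-class].
#' @param planeNormal length-3 nonzero normal vector; the default
#'   (1, 0.37, 0.22) is comfortably oblique to all symmetry families.
#' @param planeOffset signed plane offset along the unit normal; default cuts
#'   through the middle of the bed's bounding box.
#' @param minAngleDeg minimum angle (degrees) required between the plane and
#'   every \{100\}/\{110\}/\{111\} symmetry plane.
#' @return data.frame with columns \code{cx}, \code{cy}, \code{r}
#'   (arbitrary units, in-plane coordinates).
#' @export
crossSection <- function(bed, planeNormal = c(1, 0.37, 0.22),
                         planeOffset = NULL, minAngleDeg = 5) {
  stopifnot(is(bed, "PackedBed"))
  if (length(planeNormal) != 3L || !all(is.finite(planeNormal)))
    stop("'planeNormal' must be a finite length-3 vector", call. = FALSE)
  nn <- sqrt(sum(planeNormal^2))
  if (nn == 0) stop("'planeNormal' must be nonzero", call. = FALSE)
  n <- planeNormal / nn
  # parallel plane <=> normal parallel to a symmetry-family normal
  sym <- latticeSymmetryNormals()
  cosang <- abs(drop(sym %*% n))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  if (any(ang < minAngleDeg))
    stop(sprintf(paste0("plane is within %g deg of a lattice symmetry ",
                        "plane; choose an oblique normal"), minAngleDeg),
         call. = FALSE)
  ctr <- bed@centers
  if (is.null(planeOffset))
    planeOffset <- sum(n * colMeans(apply(ctr, 2, range)))
  # in-plane orthonormal basis (deterministic)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  d <- drop(ctr %*% n) - planeOffset
  hit <- abs(d) < bed@radii
  if (!any(hit))
    return(data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0)))
  proj <- ctr[hit, , drop = FALSE] - outer(d[hit], n)
  data.frame(cx = drop(proj %*% e1), cy = drop(proj %*% e2),
             r = sqrt(bed@radii[hit]^2 - d[hit]^2))
}

#' Scale a cross-section to physical column sizes
#'
#' Applies one linear scale factor so that the largest circle maps to
#' \code{rPhysMax} (default 200 um), recenters the pattern on the chamber,
#' then discards columns smaller than \code{rPhysMin} (default 80 um, the
#' fine-sand limit) and columns not fully inside the chamber.  Any residual
#' overlapping pair (possible only for user-supplied circles; sections of a
#' disjoint sphere bed are always disjoint) is resolved by shrinking the
#' smaller member until the pair is tangent minus a \code{gapUm} clearance.
#'
#' @param circles data.frame with \code{cx}, \code{cy}, \code{r}
#'   (arbitrary units), e.g. from [crossSection()].
#' @param rPhysMin,rPhysMax retained physical radius range in micrometers.
#' @param chamberWidth,chamberHeight,chamberDepth chamber dimensions (um).
#' @param gapUm minimum clearance imposed between column rims (um).
#' @param wallUm minimum clearance between columns and the chamber walls
#'   (um).
#' @return a [ChamberLayout-class].
#' @export
scaleToPhysical <- function(circles, rPhysMin = 80, rPhysMax = 200,
                            chamberWidth = 4500, chamberHeight = 3000,
                            chamberDepth = 75, gapUm = 5, wallUm = 10) {
  if (!is.data.frame(circles) || !all(c("cx", "cy", "r") %in% names(circles)))
    stop("'circles' must be a data.frame with cx, cy, r", call. = FALSE)
  if (nrow(circles) < 3L)
    stop("need at least 3 circles to form a layout", call. = FALSE)
  assertScalarNum(rPhysMin, "rPhysMin", lower = 0, strictLower = TRUE)
  assertScalarNum(rPhysMax, "rPhysMax", lower = rPhysMin)
  s <- rPhysMax / max(circles$r)
  cx <- circles$cx * s
  cy <- circles$cy * s
  r <- circles$r * s
  # recenter pattern on the chamber
  cx <- cx - mean(range(cx)) + chamberWidth / 2
  cy <- cy - mean(range(cy)) + chamberHeight / 2
  keep <- r >= rPhysMin &
    cx - r >= wallUm & cx + r <= chamberWidth - wallUm &
    cy - r >= wallUm & cy + r <= chamberHeight - wallUm
  cx <- cx[keep]; cy <- cy[keep]; r <- r[keep]
  if (length(r) >= 2L) {
    # resolve overlaps: shrink the smaller member of each offending pair
    repeat {
      d <- as.matrix(stats::dist(cbind(cx, cy)))
      diag(d) <- Inf
      need <- outer(r, r, "+") + gapUm
      bad <- which(d < need, arr.ind = TRUE)
      bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
      if (!nrow(bad)) break
      for (k in seq_len(nrow(bad))) {
        i <- bad[k, 1]; j <- bad[k, 2]
        small <- if (r[i] <= r[j]) i else j
        other <- if (small == i) j else i
        r[small] <- max(d[i, j] - r[other] - gapUm, 0)
      }
      drop_ <- r < rPhysMin
      if (any(drop_)) {
        cx <- cx[!drop_]; cy <- cy[!drop_]; r <- r[!drop_]
      }
      if (length(r) < 2L) break
    }
  }
  if (length(r) < 3L)
    stop("degenerate layout: fewer than 3 columns survive scaling/filtering",
         call. = FALSE)
  new("ChamberLayout", width = chamberWidth, height = chamberHeight,
      depth = chamberDepth,
      columns = data.frame(cx = cx, cy = cy, r = r))
}

#' Generate a soil-mimicking column layout in one call
#'
#' Convenience pipeline: FCC sphere bed, uniform radius perturbation
#' (0.4-1.0), oblique cross-section, and scaling to an 80-200 um physical
#' column range.
#'
#' @param nPerAxis FCC cells per axis passed to [packSpheres()].
#' @param seed integer seed governing the whole generation.
#' @param rMin,rMax perturbation bounds (arbitrary units).
#' @param rPhysMin,rPhysMax physical radius range (um).
#' @param chamberWidth,chamberHeight,chamberDepth chamber dimensions (um).
#' @param planeNormal oblique section plane normal.
#' @param planeOffset plane offset; default mid-box.
#' @return a [ChamberLayout-class].
#' @examples
#' layout <- makeSoilLayout(seed = 13)
#' layout
#' @export
makeSoilLayout <- function(nPerAxis = 10, seed = NULL, rMin = 0.4, rMax = 1.0,
                           rPhysMin = 80, rPhysMax = 200,
                           chamberWidth = 4500, chamberHeight = 3000,
                           chamberDepth = 75,
                           planeNormal = c(1, 0.37, 0.22),
                           planeOffset = NULL) {
  bed <- packSpheres(nPerAxis)
  bed <- perturbRadii(bed, rMin, rMax, seed = seed)
  circ <- crossSection(bed, planeNormal, planeOffset)
  scaleToPhysical(circ, rPhysMin, rPhysMax, chamberWidth, chamberHeight,
                  chamberDepth)
}

#' Pressure gradient for laminar flow in a rectangular duct
#'
#' Exact series solution for fully developed laminar flow in a rectangular
#' channel of height H and width W: the mean velocity satisfies
#' U = (G H^2 / 12 alpha) * (1 - sum_{n odd} 192 H / (n^5 pi^5 W)
#' tanh(n pi W / 2H)), solved here for the gradient G = dp/L.  In the wide
#' channel limit (W >> H) this reduces to the plane-Poiseuille result
#' G = 12 alpha U / H^2.
#'
#' @param meanSpeed mean flow speed U in um/s.
#' @param viscosity dynamic viscosity alpha in Pa s (default water, 1e-3).
#' @param height channel height H in um.
#' @param width channel width W in um.
#' @param nTerms number of (odd) series terms.
#' @return pressure gradient dp/L in Pa/m.
#' @export
ductPressureGradient <- function(meanSpeed, viscosity = 1e-3, height,
                                 width, nTerms = 20) {
  assertScalarNum(meanSpeed, "meanSpeed", lower = 0)
  assertScalarNum(viscosity, "viscosity", lower = 0, strictLower = TRUE)
  assertScalarNum(height, "height", lower = 0, strictLower = TRUE)
  assertScalarNum(width, "width", lower = 0, strictLower = TRUE)
  H <- height * 1e-6
  W <- width * 1e-6
  U <- meanSpeed * 1e-6
  nodd <- seq(1, by = 2, length.out = nTerms)
  series <- sum(192 * H / (nodd^5 * pi^5 * W) * tanh(nodd * pi * W / (2 * H)))
  12 * viscosity * U / (H^2 * (1 - series))
}

#' Wall shear stress in a rectangular flow channel
#'
#' Shear stress at the channel floor, tau = alpha du/dy evaluated at y = 0,
#' expressed through the pressure drop as tau = (dp/L)(H/2).  The default
#' \code{"plate"} mode uses the plane-Poiseuille (parallel-plate)
#' approximation, for which tau = 6 alpha U / H; \code{"duct"} obtains dp/L
#' from the exact rectangular-duct series ([ductPressureGradient()]), which
#' matters for aspect ratios W/H below a few tens.
#'
#' @param meanSpeed mean flow speed U in um/s (typical experiments run at
#'   150-200 um/s).
#' @param viscosity dynamic viscosity alpha in Pa s.
#' @param height channel height H in um.
#' @param width channel width W in um (required for \code{method = "duct"}).
#' @param method \code{"plate"} or \code{"duct"}.
#' @param nTerms series terms for the duct mode.
#' @return wall shear stress tau in Pa.
#' @examples
#' wallShearStress(175, height = 75)  # ~0.014 Pa
#' @export
wallShearStress <- function(meanSpeed, viscosity = 1e-3, height,
                            width = NULL, method = c("plate", "duct"),
                            nTerms = 20) {
  method <- match.arg(method)
  assertScalarNum(meanSpeed, "meanSpeed", lower = 0)
  assertScalarNum(viscosity, "viscosity", lower = 0, strictLower = TRUE)
  assertScalarNum(height, "height", lower = 0, strictLower = TRUE)
  if (method == "plate")
    return(6 * viscosity * (meanSpeed * 1e-6) / (height * 1e-6))
  if (is.null(width))
    stop("'width' is required for the duct pressure-drop mode",
         call. = FALSE)
  G <- ductPressureGradient(meanSpeed, viscosity, height, width, nTerms)
  G * (height * 1e-6) / 2
}
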