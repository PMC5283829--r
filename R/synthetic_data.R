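# Synthetic-data generators with region-level ground truth: clogging truth,
# two-channel chamber scenes, bead-streak stacks, competition tables, and
# logistic growth curves.

# Open-region connectivity: which open regions belong to a component that
# touches both the inlet (left) and outlet (right) side of the chamber.
# Membership in a side is decided by triangle centroid x within 15% of the
# centroid x-range of the respective extreme.
flowConnectedOpen <- function(tess, open, adjL = NULL, cen = NULL) {
  m <- nRegions(tess)
  if (is.null(adjL)) adjL <- adjacencyList(tess)
  if (is.null(cen)) cen <- regionCentroids(tess)
  xr <- range(cen[, "x"])
  band <- 0.2 * max(diff(xr), 1e-9)
  inlet <- open & cen[, "x"] <= xr[1] + band
  outlet <- open & cen[, "x"] >= xr[2] - band
  comp <- rep(0L, m)
  cid <- 0L
  stack <- integer(m)
  for (s in which(open)) {
    if (comp[s]) next
    cid <- cid + 1L
    top <- 1L
    stack[1L] <- s
    comp[s] <- cid
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      for (w in adjL[[v]]) {
        if (open[w] && comp[w] == 0L) {
          comp[w] <- cid
          top <- top + 1L
          stack[top] <- w
        }
      }
    }
  }
  good <- intersect(unique(comp[inlet]), unique(comp[outlet]))
  good <- good[good > 0L]
  open & comp %in% good
}

#' Sample a region-level ground truth for a tessellated chamber
#'
#' Emulates the end state of a clogging competition experiment.  A blocked
#' set is grown by breadth-first search over region adjacency from a random
#' clog site until a target fraction of regions is blocked (clogs propagate
#' contiguously).  Open regions that are not connected, through open
#' neighbors, to both the inlet and outlet sides are relabelled blocked,
#' since no flow path can reach them.  Strain occupancy is then drawn per
#' region: the matrix-producing wild type occupies regions independently of
#' flow, while the matrix-deficient mutant is shear-sensitive and occupies
#' blocked regions with much higher probability (default 0.75 vs 0.15, a
#' 5:1 ratio).
#'
#' @param tess a [Tessellation-class].
#' @param blockedFraction target fraction of regions blocked by clogging.
#' @param pWt wild-type occupancy probability (both flow classes).
#' @param pMutBlocked,pMutOpen mutant occupancy probability in blocked and
#'   open regions.
#' @param seed integer seed.
#' @return data.frame with \code{region_id}, \code{flow} (open/blocked),
#'   \code{wt}, \code{mut} (logical occupancy).
#' @export
makeGroundTruth <- function(tess, blockedFraction = 0.4, pWt = 0.5,
                            pMutBlocked = 0.75, pMutOpen = 0.15,
                            seed = NULL) {
  stopifnot(is(tess, "Tessellation"))
  assertScalarNum(blockedFraction, "blockedFraction", lower = 0, upper = 1)
  for (p in c(pWt, pMutBlocked, pMutOpen))
    assertScalarNum(p, "occupancy probability", lower = 0, upper = 1)
  m <- nRegions(tess)
  withSeed(seed, {
    blocked <- rep(FALSE, m)
    target <- round(blockedFraction * m)
    if (target > 0 && target < m) {
      adjL <- adjacencyList(tess)
      cen <- regionCentroids(tess)
      # a candidate may join the clog only while every remaining open
      # region stays connected to both inlet and outlet: clogs grow where
      # flow still delivers cells, and stagnant pockets are blocked by
      # definition, so the open set never contains unreachable regions
      admissible <- function(cand) {
        openSet <- !blocked
        openSet[cand] <- FALSE
        if (!any(openSet)) return(FALSE)
        identical(flowConnectedOpen(tess, openSet, adjL, cen), openSet)
      }
      starts <- sample.int(m)
      for (s in starts) if (admissible(s)) {
        blocked[s] <- TRUE
        break
      }
      clogSeed <- which(blocked)
      while (length(clogSeed) && sum(blocked) < target) {
        nb <- setdiff(unique(unlist(adjL[blocked])), which(blocked))
        if (!length(nb)) break
        d <- sqrt((cen[nb, "x"] - cen[clogSeed, "x"])^2 +
                    (cen[nb, "y"] - cen[clogSeed, "y"])^2)
        added <- FALSE
        for (cand in nb[order(d)]) {
          if (admissible(cand)) {
            blocked[cand] <- TRUE
            added <- TRUE
            break
          }
        }
        if (!added) break
      }
    }
    mut <- ifelse(blocked,
                  stats::runif(m) < pMutBlocked,
                  stats::runif(m) < pMutOpen)
    wt <- stats::runif(m) < pWt
    data.frame(region_id = seq_len(m),
               flow = factor(ifelse(blocked, "blocked", "open"),
                             levels = c("open", "blocked")),
               wt = wt, mut = mut)
  })
}

# Per-pixel clearance of region effective px to the triangle's edge lines,
# in pixels.  Blobs truncated within this margin cannot reach a neighboring
# region; overlap with the vertex columns is harmless because column pixels
# are excluded from every region mean.
regionMargins <- function(tess, region) {
  idx <- which(tess@regionMap == region & !tess@columnMask)
  if (!length(idx)) return(list(idx = integer(0)))
  ij <- arrayInd(idx, dim(tess@regionMap))
  px <- ij[, 2] - 0.5
  py <- ij[, 1] - 0.5
  v <- tess@triangles[region, ]
  xs <- tess@nodes[v, 1]; ys <- tess@nodes[v, 2]
  marg <- rep(Inf, length(idx))
  for (e in 1:3) {
    a <- e; b <- if (e == 3) 1 else e + 1
    dx <- xs[b] - xs[a]; dy <- ys[b] - ys[a]
    len <- sqrt(dx^2 + dy^2)
    dist <- abs(dx * (py - ys[a]) - dy * (px - xs[a])) / len
    marg <- pmin(marg, dist)
  }
  list(idx = idx, px = px, py = py, margin = marg)
}

# Add a truncated Gaussian blob to `img` (modified in place via return).
addBlob <- function(img, bx, by, sigma, cutoff, amplitude) {
  rows <- max(1L, floor(by - cutoff)):min(nrow(img), ceiling(by + cutoff + 1))
  cols <- max(1L, floor(bx - cutoff)):min(ncol(img), ceiling(bx + cutoff + 1))
  d2 <- outer((rows - 0.5 - by)^2, (cols - 0.5 - bx)^2, "+")
  contrib <- amplitude * exp(-d2 / (2 * sigma^2))
  contrib[d2 > cutoff^2] <- 0
  img[rows, cols] <- img[rows, cols] + contrib
  img
}

#' Render a two-channel fluorescence scene from a ground truth
#'
#' Draws an epifluorescence-like chamber image pair (GFP = wild type,
#' mCherry = mutant): uniform fluorescent background, near-zero-intensity
#' column disks, and 1-4 Gaussian biofilm blobs per occupied region.  Blob
#' peak amplitude is \code{snr} times the background noise scale
#' sqrt(background + readNoiseSd^2).  Blobs are truncated at three standard
#' deviations and placed only where they fit entirely inside the region's
#' effective mask, so an occupied region never elevates its neighbors.
#' Poisson photon noise plus Gaussian read noise is added unless
#' \code{noise = FALSE}.
#'
#' @param tess a [Tessellation-class].
#' @param truth ground-truth data.frame from [makeGroundTruth()].
#' @param background mean background intensity (counts).
#' @param columnLevel intensity of column pixels (counts).
#' @param snr peak blob signal-to-noise ratio (>= 5 recommended).
#' @param readNoiseSd Gaussian read noise standard deviation (counts).
#' @param blobSigmaUm blob standard deviation in micrometers.
#' @param maxBlobs maximum number of blobs per occupied region.
#' @param noise logical; FALSE renders the noise-free expectation.
#' @param seed integer seed.
#' @return list with numeric matrices \code{gfp} and \code{mcherry}.
#' @export
renderChamberScene <- function(tess, truth, background = 100,
                               columnLevel = 2, snr = 6, readNoiseSd = 3,
                               blobSigmaUm = 25, maxBlobs = 4,
                               noise = TRUE, seed = NULL) {
  stopifnot(is(tess, "Tessellation"))
  if (nRegions(tess) < 1L || nrow(tess@nodes) < 3L)
    stop("tessellation must contain at least 3 columns", call. = FALSE)
  if (!all(c("region_id", "wt", "mut") %in% names(truth)))
    stop("'truth' must come from makeGroundTruth()", call. = FALSE)
  if (nrow(truth) != nRegions(tess))
    stop("'truth' does not match the tessellation", call. = FALSE)
  amp <- snr * sqrt(background + readNoiseSd^2)
  sigmaPx <- blobSigmaUm / tess@umPerPx
  base <- matrix(background, nrow(tess@regionMap), ncol(tess@regionMap))
  base[tess@columnMask] <- columnLevel
  withSeed(seed, {
    channels <- list(gfp = base, mcherry = base)
    occupancy <- list(gfp = truth$wt, mcherry = truth$mut)
    for (ch in names(channels)) {
      img <- channels[[ch]]
      for (region in which(occupancy[[ch]])) {
        rm_ <- regionMargins(tess, region)
        if (!length(rm_$idx)) next
        # largest blob scale that fits this region with 3 sigma clearance
        sig <- max(1, min(sigmaPx, max(rm_$margin) / 3))
        # cap the total blob footprint at ~40% of the region so background
        # pixels always dominate the scene
        maxNb <- max(1, floor(0.4 * length(rm_$idx) / (pi * (3 * sig)^2)))
        nb <- min(sample.int(maxBlobs, 1), maxNb)
        for (b in seq_len(nb)) {
          eligible <- which(rm_$margin >= 3 * sig)
          pick <- if (length(eligible))
            eligible[sample.int(length(eligible), 1)]
          else which.max(rm_$margin)
          cut <- min(3 * sig, max(rm_$margin[pick], 1))
          img <- addBlob(img, rm_$px[pick], rm_$py[pick], sig, cut, amp)
        }
      }
      channels[[ch]] <- img
    }
    if (noise) {
      for (ch in names(channels)) {
        v <- channels[[ch]]
        v[] <- stats::rpois(length(v), pmax(v, 0)) +
          stats::rnorm(length(v), 0, readNoiseSd)
        channels[[ch]] <- pmax(v, 0)
      }
    }
    channels
  })
}

# Depth-first walk over an undirected adjacency restricted to `nodes`,
# emitting the node sequence including backtracking steps (consecutive
# entries are always adjacent).
dfsWalk <- function(adj, start) {
  visited <- rep(FALSE, nrow(adj))
  visited[start] <- TRUE
  walk <- integer(0)
  recurse <- function(v) {
    walk <<- c(walk, v)
    for (w in which(adj[v, ])) {
      if (!visited[w]) {
        visited[w] <<- TRUE
        recurse(w)
        walk <<- c(walk, v)
      }
    }
  }
  recurse(start)
  walk
}

# Splat an anti-aliased 1 px segment into `img` with bilinear weights,
# keeping the running maximum per pixel.
drawSegment <- function(img, x0, y0, x1, y1, value) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len * 2))
  t_ <- seq(0, 1, length.out = n)
  xs <- x0 + t_ * (x1 - x0)
  ys <- y0 + t_ * (y1 - y0)
  j0 <- floor(xs - 0.5); i0 <- floor(ys - 0.5)
  fx <- xs - 0.5 - j0; fy <- ys - 0.5 - i0
  for (k in 1:4) {
    di <- c(0L, 0L, 1L, 1L)[k]; dj <- c(0L, 1L, 0L, 1L)[k]
    w <- (if (di == 0) 1 - fy else fy) * (if (dj == 0) 1 - fx else fx)
    ii <- i0 + di + 1L; jj <- j0 + dj + 1L
    ok <- ii >= 1L & ii <= nrow(img) & jj >= 1L & jj <= ncol(img)
    idx <- cbind(ii[ok], jj[ok])
    img[idx] <- pmax(img[idx], value * w[ok])
  }
  img
}

#' Render a bead-streak image stack consistent with a ground truth
#'
#' Long-exposure tracer-bead images: bright streaks run along open flow
#' corridors only.  Paths are depth-first walks over the adjacency graph of
#' open regions (restricted to regions connected to both inlet and outlet),
#' split into sub-walks spanning several regions; each sub-walk is drawn as
#' a polyline through region centroids and shared-edge midpoints in one or
#' more randomly chosen frames.  Streak pixels falling in a blocked region's
#' effective mask or on a column are cleared, so the stack never contradicts
#' the truth.
#'
#' @param tess a [Tessellation-class].
#' @param truth ground-truth data.frame from [makeGroundTruth()].
#' @param nFrames number of exposures (typical experiments integrate
#'   10 to 15; default 12).
#' @param background mean background intensity (counts).
#' @param streakAmp streak peak intensity above background (counts).
#' @param readNoiseSd Gaussian read noise sd (counts).
#' @param walkSpan number of regions per drawn sub-walk.
#' @param noise logical; FALSE renders the noise-free expectation.
#' @param seed integer seed.
#' @return 3D numeric array (rows x cols x nFrames).
#' @export
renderBeadStack <- function(tess, truth, nFrames = 12, background = 5,
                            streakAmp = 80, readNoiseSd = 2, walkSpan = 4,
                            noise = TRUE, seed = NULL) {
  stopifnot(is(tess, "Tessellation"))
  if (nrow(truth) != nRegions(tess))
    stop("'truth' does not match the tessellation", call. = FALSE)
  if (nFrames < 1L) stop("'nFrames' must be >= 1", call. = FALSE)
  dims <- dim(tess@regionMap)
  open <- truth$flow == "open"
  drawable <- flowConnectedOpen(tess, open)
  frames <- array(0, c(dims, nFrames))
  withSeed(seed, {
    if (!any(drawable)) {
      warning("no open path from inlet to outlet; returning zero streaks")
    } else {
      adj <- regionAdjacency(tess)
      cen <- regionCentroids(tess)
      tri <- tess@triangles
      nodes <- tess@nodes
      edgeMid <- function(a, b) {
        shared <- intersect(tri[a, ], tri[b, ])
        colMeans(nodes[shared, , drop = FALSE])
      }
      # route streaks through the deepest point of each pore (the vertex
      # centroid of a sliver triangle can fall inside a column disk)
      anchor <- cen
      for (s in which(drawable)) {
        rm_ <- regionMargins(tess, s)
        if (length(rm_$idx)) {
          pick <- which.max(rm_$margin)
          anchor[s, ] <- c(rm_$px[pick], rm_$py[pick])
        }
      }
      done <- rep(FALSE, nRegions(tess))
      walks <- list()
      for (s in which(drawable)) {
        if (done[s]) next
        w <- dfsWalk(adj & outer(drawable, drawable, "&"), s)
        done[w] <- TRUE
        if (length(w) == 1L) {
          walks <- c(walks, list(w))
        } else {
          starts <- seq(1L, max(length(w) - 1L, 1L), by = walkSpan - 1L)
          for (st in starts)
            walks <- c(walks, list(w[st:min(st + walkSpan - 1L, length(w))]))
        }
      }
      # blocked-region clearance mask (effective pixels of blocked regions
      # plus columns); streaks must never appear there
      blockedIds <- which(truth$flow == "blocked")
      inBlocked <- matrix(tess@regionMap %in% blockedIds,
                          dims[1], dims[2])
      clear <- tess@columnMask | (inBlocked & !tess@columnMask)
      for (w in walks) {
        f <- sample.int(nFrames, 1)
        img <- frames[, , f]
        if (length(w) == 1L) {
          rm_ <- regionMargins(tess, w)
          if (length(rm_$idx)) {
            pick <- which.max(rm_$margin)
            half <- max(2, min(rm_$margin[pick], 10))
            img <- drawSegment(img, rm_$px[pick] - half, rm_$py[pick],
                               rm_$px[pick] + half, rm_$py[pick], streakAmp)
          }
        } else {
          pts <- anchor[w[1], , drop = FALSE]
          for (k in seq_len(length(w) - 1L)) {
            mid <- edgeMid(w[k], w[k + 1L])
            pts <- rbind(pts, mid, anchor[w[k + 1L], ])
          }
          for (k in seq_len(nrow(pts) - 1L))
            img <- drawSegment(img, pts[k, 1], pts[k, 2],
                               pts[k + 1L, 1], pts[k + 1L, 2], streakAmp)
        }
        img[clear] <- 0
        frames[, , f] <- img
      }
    }
    frames <- frames + background
    if (noise) {
      frames[] <- stats::rpois(length(frames), pmax(frames, 0)) +
        stats::rnorm(length(frames), 0, readNoiseSd)
      frames <- pmax(frames, 0)
    }
    frames
  })
}

#' Simulate a complete chamber experiment
#'
#' Generates a soil-mimicking layout, tessellates it at the requested pixel
#' size, samples a clogging/occupancy ground truth, and renders the
#' two-channel scene plus bead-streak stack.
#'
#' @param seed integer seed governing every step.
#' @param umPerPx physical pixel size (um).
#' @param layout optional [ChamberLayout-class]; default generated with
#'   [makeSoilLayout()] from the same seed.
#' @param nPerAxis passed to [makeSoilLayout()].
#' @param blockedFraction,pWt,pMutBlocked,pMutOpen passed to
#'   [makeGroundTruth()].
#' @param noise logical; FALSE gives noise-free images.
#' @param nFrames bead exposures.
#' @param ... further arguments to [renderChamberScene()].
#' @return list with \code{layout}, \code{tessellation}, \code{truth},
#'   \code{gfp}, \code{mcherry}, \code{beads}.
#' @export
simulateChamberExperiment <- function(seed = 1, umPerPx = 2, layout = NULL,
                                      nPerAxis = 10, blockedFraction = 0.4,
                                      pWt = 0.5, pMutBlocked = 0.75,
                                      pMutOpen = 0.15, noise = TRUE,
                                      nFrames = 12, ...) {
  if (is.null(layout)) layout <- makeSoilLayout(nPerAxis, seed = seed)
  dims <- c(round(layout@height / umPerPx), round(layout@width / umPerPx))
  cols <- columnsFromLayout(layout, umPerPx)
  tess <- tessellate(cols, dims, umPerPx)
  truth <- makeGroundTruth(tess, blockedFraction, pWt, pMutBlocked,
                           pMutOpen, seed = seed + 1L)
  scene <- renderChamberScene(tess, truth, noise = noise,
                              seed = seed + 2L, ...)
  beads <- renderBeadStack(tess, truth, nFrames = nFrames, noise = noise,
                           seed = seed + 3L)
  list(layout = layout, tessellation = tess, truth = truth,
       gfp = scene$gfp, mcherry = scene$mcherry, beads = beads)
}

#' Sample competition outcomes from a selection model
#'
#' Generates (initial, final) wild-type frequency pairs over a fixed
#' competition window.  Under \code{"uniform_positive"} selection the
#' frequency change is df = a f0 (1 - f0); under
#' \code{"negative_freq_dependent"} selection df =
#' a f0 (1 - f0) (fc - f0), which favors the wild type below the critical
#' frequency fc and the mutant above it.  Gaussian noise of sd
#' \code{noiseSd} is added to df and the final frequency is clipped to
#' \[0, 1\], so df never exceeds 1 - f0.
#'
#' @param f0 numeric vector of initial wild-type frequencies in (0, 1).
#' @param regime selection regime.
#' @param a selection strength (> 0).
#' @param fc critical frequency in (0, 1); used only for
#'   \code{"negative_freq_dependent"}.
#' @param noiseSd replicate noise sd on df (>= 0).
#' @param condition label stored with the records.
#' @param seed integer seed.
#' @return data.frame \code{condition}, \code{f0}, \code{f72}.
#' @export
sampleCompetition <- function(f0,
                              regime = c("negative_freq_dependent",
                                         "uniform_positive"),
                              a = 1, fc = 0.6, noiseSd = 0,
                              condition = "columns", seed = NULL) {
  regime <- match.arg(regime)
  if (!length(f0) || any(f0 <= 0 | f0 >= 1))
    stop("all initial frequencies must lie strictly in (0, 1)",
         call. = FALSE)
  assertScalarNum(a, "a", lower = 0, strictLower = TRUE)
  assertScalarNum(noiseSd, "noiseSd", lower = 0)
  if (regime == "negative_freq_dependent")
    assertScalarNum(fc, "fc", lower = 0, upper = 1, strictLower = TRUE)
  df <- switch(regime,
    uniform_positive = a * f0 * (1 - f0),
    negative_freq_dependent = a * f0 * (1 - f0) * (fc - f0))
  withSeed(seed, {
    f72 <- f0 + df + stats::rnorm(length(f0), 0, noiseSd)
    f72 <- pmin(pmax(f72, 0), 1)
    data.frame(condition = condition, f0 = f0, f72 = f72)
  })
}

#' Sample a logistic OD600 growth curve
#'
#' OD(t) = K od0 exp(r t) / (K + od0 (exp(r t) - 1)) with i.i.d. Gaussian
#' measurement noise, sampled on a regular grid (default every 30 minutes,
#' matching plate-reader protocols; a 10-minute preset is just
#' \code{dtMin = 10}).
#'
#' @param r per-hour growth rate (> 0).
#' @param K carrying capacity (OD units).
#' @param od0 initial OD (> 0).
#' @param dtMin sampling interval in minutes.
#' @param tEndHr last sampled time in hours.
#' @param noiseSd measurement noise sd (OD units, >= 0).
#' @param seed integer seed.
#' @return data.frame \code{t_hr}, \code{od600}.
#' @export
sampleGrowthCurve <- function(r = 0.25, K = 1.0, od0 = 0.01, dtMin = 30,
                              tEndHr = 48, noiseSd = 0, seed = NULL) {
  assertScalarNum(r, "r", lower = 0, strictLower = TRUE)
  assertScalarNum(K, "K", lower = 0, strictLower = TRUE)
  assertScalarNum(od0, "od0", lower = 0, strictLower = TRUE)
  assertScalarNum(dtMin, "dtMin", lower = 0, strictLower = TRUE)
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || is.na(noiseSd) ||
      noiseSd < 0)
    stop("'noiseSd' must be a single non-negative number", call. = FALSE)
  t_ <- seq(0, tEndHr, by = dtMin / 60)
  od <- K * od0 * exp(r * t_) / (K + od0 * (exp(r * t_) - 1))
  withSeed(seed, {
    data.frame(t_hr = t_, od600 = od + stats::rnorm(length(od), 0, noiseSd))
  })
}

#' Simulate replicate co-occurrence experiments at the region level
#'
#' Fast generator for statistical calibration: for each replicate, a fresh
#' ground truth is drawn on a fixed tessellation and summarized into
#' area-normalized occurrence frequencies per strain and flow class (no
#' image rendering).  With \code{pMutBlocked == pMutOpen} this is a null
#' generator in which mutant occupancy is independent of flow.
#'
#' @param tess a [Tessellation-class].
#' @param nReplicates replicate chambers per experiment.
#' @param blockedFraction,pWt,pMutBlocked,pMutOpen truth parameters, see
#'   [makeGroundTruth()].
#' @param seed integer seed.
#' @return data.frame of per-replicate occurrence summaries, see
#'   [occurrenceByFlowClass()], with a \code{replicate} column.
#' @export
simulateOccurrenceExperiment <- function(tess, nReplicates = 3,
                                         blockedFraction = 0.4, pWt = 0.5,
                                         pMutBlocked = 0.75,
                                         pMutOpen = 0.15, seed = NULL) {
  stopifnot(is(tess, "Tessellation"))
  areas <- effectiveArea(tess, "um2")
  withSeed(seed, {
    out <- lapply(seq_len(nReplicates), function(rep_) {
      truth <- makeGroundTruth(tess, blockedFraction, pWt, pMutBlocked,
                               pMutOpen, seed = NULL)
      calls <- data.frame(region_id = truth$region_id,
                          flow = as.character(truth$flow),
                          wt_call = truth$wt, mut_call = truth$mut,
                          area_um2 = areas)
      s <- occurrenceByFlowClass(calls)
      s$replicate <- rep_
      s
    })
    do.call(rbind, out)
  })
}
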