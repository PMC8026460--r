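## Seeded level-tracing segmentation, slice by axial slice.
##
## Starting from a seed pixel, the traced region is the 4-connected set of
## pixels whose intensity lies within a symmetric tolerance window of the
## seed intensity; its outer boundary is followed along pixel cracks so
## that a closed simple contour results (the tolerance-0 limit reproduces
## the literal "same grey level as the seed" rule).

## 4-connected flood fill of {p : |I(p) - I(seed)| <= tol}, vectorized BFS.
floodMask <- function(img, seed, tol) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- abs(img - img[seed[1], seed[2]]) <= tol
  filled <- matrix(FALSE, nr, nc)
  frontier <- (seed[2] - 1L) * nr + seed[1]
  filled[frontier] <- TRUE
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    cand <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier[frontier > nr] - nr,
              frontier[frontier <= nr * (nc - 1L)] + nr)
    cand <- unique(cand[ok[cand] & !filled[cand]])
    filled[cand] <- TRUE
    frontier <- cand
  }
  filled
}

## Outer crack boundary of a 4-connected region, counter-clockwise in the
## (row, col) screen convention, region kept to the left of travel. Corner
## (r, c) of the integer corner lattice maps to coordinates (r+0.5, c+0.5)
## so pixel (i, j) has corners (i - 0.5 .. i + 0.5, j - 0.5 .. j + 0.5).
traceBoundary <- function(filled) {
  nr <- nrow(filled); nc <- ncol(filled)
  at <- function(i, j) i >= 1L & i <= nr & j >= 1L & j <= nc &
    filled[cbind(pmax(pmin(i, nr), 1L), pmax(pmin(j, nc), 1L))]
  idx <- which(filled, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  edges <- rbind(
    ## top side, travelled -col: (i-1, j) -> (i-1, j-1)
    cbind(i - 1L, j, i - 1L, j - 1L)[!at(i - 1L, j), , drop = FALSE],
    ## bottom side, +col: (i, j-1) -> (i, j)
    cbind(i, j - 1L, i, j)[!at(i + 1L, j), , drop = FALSE],
    ## left side, +row: (i-1, j-1) -> (i, j-1)
    cbind(i - 1L, j - 1L, i, j - 1L)[!at(i, j - 1L), , drop = FALSE],
    ## right side, -row: (i, j) -> (i-1, j)
    cbind(i, j, i - 1L, j)[!at(i, j + 1L), , drop = FALSE])
  key <- function(r, c) r * (nc + 1L) + c + 1L
  from <- key(edges[, 1], edges[, 2])
  ## start at the top edge of the topmost-leftmost region pixel
  p0 <- idx[order(idx[, 1], idx[, 2])[1L], ]
  start <- c(p0[1] - 1L, p0[2])
  cur <- start; dir <- c(0L, -1L)
  path <- matrix(0L, nrow(edges) + 1L, 2L)
  path[1L, ] <- cur
  np <- 1L
  repeat {
    cand <- which(from == key(cur[1], cur[2]))
    if (length(cand) > 1L) {
      ## pinch corner: sharpest left turn keeps 4-connectivity semantics
      turns <- vapply(cand, function(e) {
        d <- c(edges[e, 3] - edges[e, 1], edges[e, 4] - edges[e, 2])
        left <- c(-dir[2], dir[1])
        if (all(d == left)) 0L else if (all(d == dir)) 1L else 2L
      }, integer(1))
      cand <- cand[which.min(turns)]
    }
    if (!length(cand)) stop("boundary tracing failed (internal error)")
    dir <- c(edges[cand, 3] - edges[cand, 1], edges[cand, 4] - edges[cand, 2])
    cur <- edges[cand, 3:4]
    from[cand] <- -1L                 # consume
    np <- np + 1L
    path[np, ] <- cur
    if (all(cur == start)) break
  }
  path <- path[seq_len(np), , drop = FALSE]
  path + 0.5
}

#' Level-trace a region from a seed pixel
#'
#' @param slice 2D numeric matrix (an axial slice; rows/cols are pixel
#'   indices, 1-based).
#' @param seed integer length-2 (row, col) inside the grid.
#' @param tolerance intensity half-width (>= 0); a pixel belongs to the
#'   region when its intensity differs from the seed intensity by at most
#'   this amount and it is 4-connected to the seed through such pixels.
#'   `tolerance = 0` selects exactly the seed grey level.
#' @return a [TracedRegion-class]: filled mask, closed outer crack
#'   boundary (counter-clockwise, region on the left; regions touching the
#'   image border are closed along it) and the tolerance used.
#' @examples
#' img <- matrix(0, 5, 5); img[2:4, 3] <- 1000; img[3, 2:4] <- 1000
#' levelTrace(img, c(3, 3), 0)
#' @export
levelTrace <- function(slice, seed, tolerance = 0) {
  stopifnot(is.matrix(slice))
  seed <- as.integer(seed)
  if (length(seed) != 2L || any(seed < 1L) || seed[1] > nrow(slice) ||
      seed[2] > ncol(slice))
    stop("seed outside the grid")
  if (!is.numeric(tolerance) || tolerance < 0)
    stop("tolerance must be >= 0")
  filled <- floodMask(slice, seed, tolerance)
  new("TracedRegion", slice = NA_integer_, seed = seed,
      boundary = traceBoundary(filled), filled = filled,
      tolerance = as.numeric(tolerance))
}

#' Suggest a level-tracing tolerance for a slice
#'
#' Half the distance between the two Otsu intensity-class means of the
#' slice: on a bimodal bone/background slice this reproduces midpoint
#' thresholding when seeding inside bone.
#'
#' @param slice 2D numeric matrix.
#' @return non-negative tolerance (intensity units).
#' @export
suggestTolerance <- function(slice) {
  rng <- range(slice)
  if (diff(rng) == 0) return(0)
  u <- (slice - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(u), range = c(0, 1))
  (mean(u[u > thr]) - mean(u[u <= thr])) * diff(rng) / 2
}

#' Segment a volume by per-slice level tracing
#'
#' Applies [levelTrace()] on each seeded axial slice and unions the filled
#' regions into a binary mask congruent with the volume. Slices without a
#' seed stay empty. If a traced region covers more than half its slice, a
#' warning is recorded in the provenance (the seed likely fell on
#' background when bone is expected compact).
#'
#' @param volume a [VoxelVolume-class].
#' @param seeds data.frame/matrix with columns `slice`, `row`, `col`
#'   (1-based; axial slice = third volume index); at least one seed.
#' @param tolerance intensity half-width shared by all seeds.
#' @return a [BinaryMask-class]; `provenance(mask)` records seeds,
#'   tolerance and warnings.
#' @export
segmentVolume <- function(volume, seeds, tolerance) {
  stopifnot(is(volume, "VoxelVolume"))
  seeds <- as.data.frame(seeds)
  if (!all(c("slice", "row", "col") %in% names(seeds)))
    stop("'seeds' needs columns slice, row, col")
  if (nrow(seeds) == 0L) stop("at least one seed is required")
  vox <- volume@intensities
  d <- dim(vox)
  if (any(seeds$slice < 1L | seeds$slice > d[3]))
    stop("seed slice index out of range")
  if (any(seeds$row < 1L | seeds$row > d[1] | seeds$col < 1L | seeds$col > d[2]))
    stop("seed pixel outside the grid")
  if (!is.numeric(tolerance) || tolerance < 0) stop("tolerance must be >= 0")
  mask <- array(FALSE, d)
  warnings <- character()
  for (k in sort(unique(seeds$slice))) {
    sl <- vox[, , k]
    acc <- matrix(FALSE, d[1], d[2])
    sk <- seeds[seeds$slice == k, , drop = FALSE]
    for (q in seq_len(nrow(sk))) {
      f <- floodMask(sl, c(sk$row[q], sk$col[q]), tolerance)
      if (mean(f) > 0.5)
        warnings <- c(warnings, sprintf(
          "slice %d seed (%d,%d): traced region covers %.0f%% of the slice",
          k, sk$row[q], sk$col[q], 100 * mean(f)))
      acc <- acc | f
    }
    mask[, , k] <- acc
  }
  new("BinaryMask", mask = mask, spacing = volume@spacing,
      origin = volume@origin,
      provenance = list(seeds = seeds, tolerance = tolerance,
                        warnings = warnings))
}

#' Suggest one seed per bone component per slice
#'
#' For every axial slice containing supra-threshold pixels, returns one
#' seed per 4-connected supra-threshold component: the intensity-weighted
#' centroid of the component snapped to the nearest in-component pixel.
#'
#' @param volume a [VoxelVolume-class].
#' @param bone_threshold intensity threshold; voxels with intensity at or
#'   above it are considered bone. A threshold above the global maximum
#'   yields no seeds; one at or below the global minimum yields one seed
#'   per slice.
#' @return data.frame with columns `slice`, `row`, `col` (possibly 0 rows).
#' @export
suggestBoneSeeds <- function(volume, bone_threshold) {
  stopifnot(is(volume, "VoxelVolume"))
  vox <- volume@intensities
  d <- dim(vox)
  out <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    sl <- vox[, , k]
    bw <- sl >= bone_threshold
    if (!any(bw)) next
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    lab <- matrix(as.integer(EBImage::imageData(lab)), d[1], d[2])
    rows <- integer(0); cols <- integer(0)
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      wts <- sl[px]
      if (!all(is.finite(wts)) || sum(wts) <= 0) wts <- rep(1, length(wts))
      ctr <- colSums(px * wts) / sum(wts)
      nearest <- which.min((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
      rows <- c(rows, px[nearest, 1]); cols <- c(cols, px[nearest, 2])
    }
    out[[k]] <- data.frame(slice = k, row = rows, col = cols)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(slice = integer(0), row = integer(0),
                                      col = integer(0))
  res
}
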