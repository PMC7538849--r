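# Internal raster geometry helpers. All coordinates are 0-based pixel
# centers, x = column - 1, y = row - 1; distances are Euclidean in pixel
# units (callers scale by spacing).

# boundary pixels of a region: active with at least one inactive 4-neighbor
# (image edge counts as inactive)
.boundaryMask <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up    <- rbind(FALSE, m[-nr, , drop = FALSE])
  down  <- rbind(m[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, m[, -nc, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}

.coords <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

.boundaryCoords <- function(m) .coords(.boundaryMask(m))

# max pairwise distance between points (max Feret diameter over pixel centers)
.maxFeret <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  if (nrow(pts) > 3L) {
    hull <- grDevices::chull(pts)
    if (length(hull) >= 2L) pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts))
}

# directed boundary distance: max over rows of `from` of the min distance to
# rows of `to` (one-sided Hausdorff on vertex sets)
.directedMaxMin <- function(from, to) {
  if (nrow(from) == 0L || nrow(to) == 0L) return(0)
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  sqrt(max(apply(d2, 1L, min)))
}

# largest pairwise distance between the two vertex sets
.maxPairDist <- function(from, to) {
  if (nrow(from) == 0L || nrow(to) == 0L) return(0)
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  sqrt(max(d2))
}

# label the holes of A (background regions enclosed by the filled mask B),
# 4-connected; returns an integer matrix, 0 = not a hole
.labelHoles <- function(A, B = fillMask(A)) {
  holes <- B & !A
  if (!any(holes)) return(matrix(0L, nrow(A), ncol(A)))
  lab <- EBImage::bwlabel(holes)
  matrix(as.integer(lab), nrow(A), ncol(A))
}
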