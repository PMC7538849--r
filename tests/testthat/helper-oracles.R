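# Independent brute-force oracles, deliberately naive: loop/queue
# implementations that share no code with the package internals.

# flood fill background from the border (4-connected); anything not
# reached and not active is an interior hole
fillOracle <- function(A) {
  A <- A != 0
  nr <- nrow(A); nc <- ncol(A)
  reached <- matrix(FALSE, nr, nc)
  queue <- list()
  for (r in seq_len(nr)) for (cc in c(1L, nc))
    if (!A[r, cc]) queue[[length(queue) + 1L]] <- c(r, cc)
  for (cc in seq_len(nc)) for (r in c(1L, nr))
    if (!A[r, cc]) queue[[length(queue) + 1L]] <- c(r, cc)
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    r <- p[1]; cc <- p[2]
    if (reached[r, cc] || A[r, cc]) next
    reached[r, cc] <- TRUE
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
          !A[rr, c2] && !reached[rr, c2])
        queue[[length(queue) + 1L]] <- c(rr, c2)
    }
  }
  A | (!A & !reached)
}

# 4-connected labeling by repeated flood fill
labelOracle <- function(m) {
  m <- m != 0
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  for (i in which(m & lab == 0L)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[j] != 0L) next
      lab[j] <- nxt
      r <- (j - 1L) %% nrow(m) + 1L; cc <- (j - 1L) %/% nrow(m) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= nrow(m) && c2 >= 1 && c2 <= ncol(m) &&
            m[rr, c2] && lab[rr, c2] == 0L)
          stack <- c(stack, (c2 - 1L) * nrow(m) + rr)
      }
    }
  }
  lab
}

# boundary pixels: active with an inactive 4-neighbor or on the image edge
boundaryOracle <- function(m) {
  m <- m != 0
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
    if (!m[r, cc]) next
    edge <- r == 1 || r == nrow(m) || cc == 1 || cc == ncol(m)
    if (edge || !m[r - 1, cc] || !m[r + 1, cc] ||
        !m[r, cc - 1] || !m[r, cc + 1])
      out[r, cc] <- TRUE
  }
  out
}

coordsOracle <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# max Feret diameter by looping over all boundary pixel pairs
spanOracle <- function(B) {
  pts <- coordsOracle(boundaryOracle(B))
  if (nrow(pts) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts))
    best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  best
}

# directed boundary distance of the largest hole to the outer wall, by
# exhaustive pair loops
losaOracle <- function(A) {
  B <- fillOracle(A)
  holes <- B & !(A != 0)
  if (!any(holes)) return(0)
  lab <- labelOracle(holes)
  areas <- tabulate(lab[lab > 0])
  outer <- coordsOracle(boundaryOracle(B))
  best <- 0
  for (h in which(areas == max(areas))) {   # every largest-area region
    inner <- coordsOracle(boundaryOracle(lab == h))
    for (i in seq_len(nrow(inner))) {
      mn <- Inf
      for (j in seq_len(nrow(outer)))
        mn <- min(mn, sqrt(sum((inner[i, ] - outer[j, ])^2)))
      best <- max(best, mn)
    }
  }
  best
}

# AUC by counting concordant pairs (ties = 1/2)
aucOracle <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random blobby mask with optional carved holes, <= side x side
randomMask <- function(side = 32, holes = TRUE) {
  repeat {
    m <- matrix(FALSE, side, side)
    nblob <- sample(1:3, 1)
    for (b in seq_len(nblob)) {
      cx <- runif(1, side * 0.3, side * 0.7)
      cy <- runif(1, side * 0.3, side * 0.7)
      a <- runif(1, 2, max(3.5, side * 0.3))
      bb <- runif(1, 2, max(3.5, side * 0.3))
      th <- runif(1, 0, pi)
      xs <- matrix(rep(seq_len(side), each = side), side)
      ys <- matrix(rep(seq_len(side), times = side), side)
      xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      m <- m | ((xr / a)^2 + (yr / bb)^2 <= 1)
    }
    if (holes && runif(1) < 0.8) {
      interior <- m & !boundaryOracle(m)
      cand <- which(interior)
      if (length(cand) > 4) {
        k <- sample(seq_len(max(1, floor(length(cand) / 3))), 1)
        m[sample(cand, k)] <- FALSE
      }
    }
    if (sum(m) >= 4) return(m)
  }
}
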