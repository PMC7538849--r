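block <- function(n, hole = NULL) {
  A <- matrix(1, n, n)
  if (!is.null(hole)) A[hole, hole] <- 0
  A
}

test_that("hole filling recovers enclosed cavities and nothing else", {
  expect_equal(sum(fillMask(block(3))), 9)
  expect_equal(sum(fillMask(block(3, hole = 2))), 9)
  expect_equal(sum(fillMask(block(7, hole = 3:5))), 49)
  # a notch open to the border is not a hole
  A <- block(5); A[1:3, 3] <- 0
  expect_equal(fillMask(A), A == 1)
  expect_error(fillMask(matrix(numeric(0), 0, 0)), "empty")
})

test_that("hole filling matches the border flood-fill oracle on random masks", {
  set.seed(11)
  for (i in 1:25) {
    m <- randomMask(sample(8:24, 1))
    expect_identical(fillMask(m), fillOracle(m))
  }
})

test_that("pixel counts are exact and PBiA equals PA", {
  v <- TumorVolume(list(block(3, hole = 2)))
  expect_equal(pixelCounts(v), c(PA = 8, PB = 9, PBiA = 8))
  expect_equal(pixelCounts(TumorVolume(list(block(3)))),
               c(PA = 9, PB = 9, PBiA = 9))
  expect_equal(unname(pixelCounts(TumorVolume(list(block(7, 3:5))))[1:2]),
               c(40, 49))
})

test_that("composition scores follow the per-slice means", {
  v <- TumorVolume(list(block(3, hole = 2)))
  expect_equal(rdc(v), 8 / 9)
  expect_equal(rlc(v), 1 / 9)
  expect_equal(atRatio(v), 1 / 8)
  solid <- TumorVolume(list(block(5), block(5)))
  expect_equal(rdc(solid), 1)
  expect_equal(rlc(solid), 0)
  expect_equal(atRatio(solid), 0)
  # two slices with solid fractions 1 and 1/2 average to 3/4
  half <- matrix(0, 4, 4); half[1:2, ] <- 1
  full <- matrix(1, 4, 4)
  v2 <- TumorVolume(list(full, half))
  expect_equal(rdc(v2), mean(c(1, 1)))  # no holes: half-block has no hole
  # build a genuine 50% lucent slice instead
  A <- matrix(1, 6, 6); A[2:5, 2:5] <- 0; A[1, ] <- 1  # 16-px hole? open?
  A <- matrix(1, 8, 8); A[3:6, 3:6] <- 0               # 16/64 = 25% lucent
  v3 <- TumorVolume(list(matrix(1, 8, 8), A))
  expect_equal(rdc(v3), mean(c(1, 48 / 64)))
})

test_that("difference of composition is the absolute difference", {
  expect_equal(doc(0.8, 0.2), 0.6)
  expect_equal(doc(0.5, 0.5), 0)
  expect_equal(doc(8 / 9, 1 / 9), 7 / 9)
})

test_that("span is the max Feret diameter of the mask boundary", {
  v <- TumorVolume(list(block(7)))
  expect_equal(spanDiameter(v), 6 * sqrt(2))
  row <- matrix(1, 1, 5)
  expect_equal(spanDiameter(TumorVolume(list(row))), 4)
  single <- matrix(0, 3, 3); single[2, 2] <- 1
  expect_equal(spanDiameter(TumorVolume(list(single))), 0)
})

test_that("wall thickness (losa) follows the directed boundary distance", {
  expect_equal(losa(TumorVolume(list(block(7, hole = 4)))), 3)
  expect_equal(losa(TumorVolume(list(block(7, hole = 3:5)))), 2)
  expect_equal(losa(TumorVolume(list(block(5)))), 0)
  # ratio to span
  v <- TumorVolume(list(block(7, hole = 4)))
  expect_equal(losaRatio(v), 3 / (6 * sqrt(2)))
  expect_equal(losaRatio(TumorVolume(list(block(7)))), 0)
})

test_that("span and losa match exhaustive pair-loop oracles on random masks", {
  set.seed(23)
  for (i in 1:20) {
    m <- randomMask(sample(10:32, 1))
    v <- TumorVolume(list(m))
    expect_equal(spanDiameter(v), spanOracle(maskSlices(v)[[1]]))
    expect_equal(losa(v), losaOracle(m))
  }
})

test_that("cavity diameters use the area-equivalent circle", {
  v1 <- TumorVolume(list(block(5, hole = 3)))
  expect_equal(innerDiameter(v1), 2 * sqrt(1 / pi))
  v9 <- TumorVolume(list(block(7, hole = 3:5)))
  expect_equal(innerDiameter(v9), 2 * sqrt(9 / pi))
  # two holes of areas 1 and 9 average their equivalent diameters
  A <- matrix(1, 9, 13); A[3:5, 3:5] <- 0; A[5, 10] <- 0
  expect_equal(innerDiameter(TumorVolume(list(A))),
               mean(2 * sqrt(c(9, 1) / pi)))
  expect_error(innerDiameter(TumorVolume(list(block(3)))), "no lucent")
})

test_that("loca averages over lucency-bearing slices only", {
  expect_equal(loca(TumorVolume(list(block(5)))), 0)
  v <- TumorVolume(list(block(7, hole = 3:5), block(7)))
  expect_equal(loca(v), 2 * sqrt(9 / pi))   # hole-free slice skipped
  s1 <- block(7); s1[4, 4] <- 0            # single-pixel hole, same dims
  v2 <- TumorVolume(list(s1, block(7, hole = 3:5)))
  expect_equal(loca(v2), mean(2 * sqrt(c(1, 9) / pi)))
  expect_equal(locaRatio(v), 2 * sqrt(9 / pi) / (6 * sqrt(2)))
})

test_that("solidity is the bounding-box fill fraction of the solid image", {
  expect_equal(solidity(TumorVolume(list(block(3)))), 1)
  expect_equal(solidity(TumorVolume(list(block(3, hole = 2)))), 8 / 9)
  L <- matrix(0, 4, 4); L[2, 2] <- 1; L[3, 2] <- 1; L[3, 3] <- 1
  expect_equal(solidity(TumorVolume(list(L))), 3 / 4)
})

test_that("computeIBM assembles consistent scores and spacing scales lengths", {
  v <- TumorVolume(list(block(7, hole = 4)))
  ib <- computeIBM(v)
  expect_equal(unname(ib["rdc"]), 48 / 49)
  expect_equal(unname(ib["at_r"]), 1 / 48)
  expect_equal(unname(ib["losa"]), 3)
  expect_equal(unname(ib["rdc"] + ib["rlc"]), 1, tolerance = 1e-12)
  solid <- computeIBM(TumorVolume(list(block(5))))
  expect_equal(unname(solid[c("rlc", "at_r", "losa", "losa_r", "loca",
                              "loca_r")]), rep(0, 6))
  expect_equal(unname(solid[c("rdc", "doc", "solidity")]), rep(1, 3))
  # mm spacing scales lengths, leaves ratios unchanged
  vmm <- TumorVolume(list(block(7, hole = 4)), spacing = 0.7)
  ibmm <- computeIBM(vmm)
  expect_equal(unname(ibmm["losa"]), 3 * 0.7)
  expect_equal(unname(ibmm["losa_r"]), unname(ib["losa_r"]))
  expect_equal(unname(ibmm["rdc"]), unname(ib["rdc"]))
})

test_that("algebraic identities hold on random volumes", {
  set.seed(31)
  for (i in 1:20) {
    nsl <- sample(1:4, 1)
    side <- sample(10:24, 1)
    v <- TumorVolume(lapply(seq_len(nsl), function(s) randomMask(side)))
    ib <- computeIBM(v)
    expect_equal(unname(ib["rdc"] + ib["rlc"]), 1, tolerance = 1e-12)
    expect_equal(unname(ib["doc"]), unname(abs(2 * ib["rdc"] - 1)),
                 tolerance = 1e-12)
    expect_gte(ib["losa_r"], 0); expect_lte(ib["losa_r"], 1)
    if (nsl == 1)
      expect_equal(unname(ib["at_r"]), unname(ib["rlc"] / ib["rdc"]),
                   tolerance = 1e-12)
  }
})

test_that("rotating a slice by 90 degrees leaves every score unchanged", {
  set.seed(41)
  for (i in 1:5) {
    m <- randomMask(20)
    rot <- t(m)[ncol(m):1, , drop = FALSE]
    expect_equal(computeIBM(TumorVolume(list(m))),
                 computeIBM(TumorVolume(list(rot))))
  }
})

test_that("enlarging a hole never increases rdc nor decreases rlc and at_r", {
  set.seed(53)
  for (i in 1:10) {
    side <- sample(14:24, 1)
    m <- randomMask(side, holes = FALSE)
    interior <- m & !boundaryOracle(m)
    cand <- which(interior)
    if (length(cand) < 6) next
    k1 <- sample(2:(length(cand) %/% 2), 1)
    hole1 <- sample(cand, k1)
    hole2 <- c(hole1, sample(setdiff(cand, hole1),
                             min(3, length(cand) - k1)))
    a1 <- m; a1[hole1] <- FALSE
    a2 <- m; a2[hole2] <- FALSE
    v1 <- TumorVolume(list(a1)); v2 <- TumorVolume(list(a2))
    expect_lte(rdc(v2), rdc(v1))
    expect_gte(rlc(v2), rlc(v1))
    expect_gte(atRatio(v2), atRatio(v1))
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(TumorVolume(list(matrix(0, 4, 4))), "no tumor pixels")
  single <- matrix(0, 3, 3); single[2, 2] <- 1
  expect_error(losaRatio(TumorVolume(list(single))), "degenerate")
  allLucent <- matrix(1, 5, 5); allLucent[2:4, 2:4] <- 0
  # center 3x3 carved from 5x5: PA>0 still; construct an impossible case via
  # a slice that is pure hole is unreachable by construction, so check the
  # atRatio guard directly on a crafted volume
  v <- TumorVolume(list(matrix(1, 3, 3)))
  v@solid[[1]][] <- FALSE
  expect_error(atRatio(v), "no solid tissue")
})

test_that("CT binarization thresholds inside the ROI", {
  ct <- matrix(c(-900, -600, -100, 40), 2, 2)
  expect_equal(sum(binarizeCT(ct)), 2)
  roi <- matrix(c(1, 1, 0, 1), 2, 2)
  expect_equal(sum(binarizeCT(ct, roi)), 1)
  expect_equal(sum(binarizeCT(ct, huThreshold = -1000)), 4)
})
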