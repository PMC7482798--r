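point_volume <- function(pos, side = 16L, value = 10) {
  a <- array(0, rep(side, 3))
  a[pos[1], pos[2], pos[3]] <- value
  vol <- PETVolume(a, spacing = 2, units = "SUV")
  mask <- new("SegmentationMask", data = a > 0, spacing = rep(2, 3))
  list(vol = vol, mask = mask)
}

test_that("cube is centered on the mask centroid", {
  pv <- point_volume(c(8, 8, 8))
  cube <- extractCube(pv$vol, pv$mask, side_mm = 16) # 8 voxels at 2 mm
  d <- petData(cube)
  ctr <- which(d == max(d), arr.ind = TRUE)
  expect_true(all(abs(ctr - 4.5) <= 1))
  expect_equal(sum(d > 0), 1)
})

test_that("regions outside the volume are zero-padded", {
  pv <- point_volume(c(2, 2, 2))
  cube <- extractCube(pv$vol, pv$mask, side_mm = 16, normMode = "none")
  d <- petData(cube)
  # lesion sits at the corner: over half the cube lies outside the volume
  expect_equal(sum(d == 10), 1)
  expect_gt(sum(d == 0), length(d) / 2)
})

test_that("cube content matches the crop-and-pad index oracle", {
  vol <- make_blob_volume(41, side = 16L)
  mask <- segmentTumor(vol, thresholdParams(c(3, 14, 3, 14, 3, 14)))
  cube <- extractCube(vol, mask, side_mm = 24, normMode = "none") # 12 voxels
  idx <- which(petData(mask), arr.ind = TRUE)
  start <- round(colMeans(idx) - (12 - 1) / 2)
  oracle <- array(0, c(12, 12, 12))
  vd <- petData(vol)
  for (k in 1:12) for (j in 1:12) for (i in 1:12) {
    s <- start + c(i, j, k) - 1
    if (all(s >= 1) && all(s <= 16)) oracle[i, j, k] <- vd[s[1], s[2], s[3]]
  }
  expect_equal(petData(cube), oracle)
})

test_that("max normalization and the lesion-exceeds-cube guard work", {
  vol <- make_blob_volume(43, side = 16L)
  mask <- segmentTumor(vol, thresholdParams(c(3, 14, 3, 14, 3, 14)))
  cube <- extractCube(vol, mask, side_mm = 24, normMode = "max")
  expect_equal(max(petData(cube)), 1)
  expect_error(extractCube(vol, mask, side_mm = 2), "exceeds cube")
  expect_error(extractCube(vol, new("SegmentationMask",
                                    data = array(FALSE, c(16, 16, 16)),
                                    spacing = rep(2, 3)), 24), "empty mask")
})

test_that("whole-voxel lesion shifts do not change the cube content", {
  set.seed(47)
  lesion <- array(runif(125, 1, 5), c(5, 5, 5))
  a1 <- array(0, c(16, 16, 16))
  a1[6:10, 6:10, 6:10] <- lesion
  a2 <- array(0, c(16, 16, 16))
  a2[8:12, 4:8, 7:11] <- lesion # shifted by (+2, -2, +1) voxels
  msk <- function(a) new("SegmentationMask", data = a > 0, spacing = rep(2, 3))
  c1 <- extractCube(PETVolume(a1, spacing = 2), msk(a1), side_mm = 20,
                    normMode = "none")
  c2 <- extractCube(PETVolume(a2, spacing = 2), msk(a2), side_mm = 20,
                    normMode = "none")
  expect_equal(petData(c1), petData(c2))
})

test_that("zero-angle rotation is the identity", {
  set.seed(51)
  cube <- new("TumorCube", data = array(runif(8^3), c(8, 8, 8)),
              normMode = "none", spacing = 2)
  expect_identical(petData(rotateCube(cube, c(0, 0, 0))), petData(cube))
})

test_that("right-angle rotations permute the voxel multiset exactly", {
  set.seed(53)
  cube <- new("TumorCube", data = array(runif(8^3), c(8, 8, 8)),
              normMode = "none", spacing = 2)
  for (ang in list(c(90, 0, 0), c(0, 90, 0), c(0, 0, 90), c(90, 90, 0))) {
    r <- rotateCube(cube, ang)
    expect_equal(sort(as.numeric(petData(r))),
                 sort(as.numeric(petData(cube))))
  }
})

test_that("a fixed seed reproduces the augmentation batch bit-for-bit", {
  set.seed(55)
  cube <- new("TumorCube", data = array(runif(8^3), c(8, 8, 8)),
              normMode = "none", spacing = 2)
  pol <- augmentationPolicy(nCopies = 15, seed = 7)
  b1 <- randomRotations(cube, pol)
  b2 <- randomRotations(cube, pol)
  expect_length(b1, 15)
  for (k in 1:15) expect_identical(petData(b1[[k]]), petData(b2[[k]]))
  ang <- attr(b1, "angles")
  expect_true(all(ang >= 0 & ang <= 90))
  expect_gt(nrow(unique(ang)), 1)
})

test_that("rotation approximately preserves total uptake of a centered blob", {
  x <- seq_len(16) - 8.5
  g <- exp(-outer(outer(x^2, x^2, "+"), x^2, "+") / (2 * 9))
  cube <- new("TumorCube", data = array(g, c(16, 16, 16)),
              normMode = "none", spacing = 2)
  for (s in 1:5) {
    r <- randomRotations(cube, augmentationPolicy(nCopies = 1,
                                                  seed = 60 + s))[[1]]
    expect_lt(abs(sum(petData(r)) - sum(petData(cube))) / sum(petData(cube)),
              0.05)
  }
})
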