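# Viable-tumor quantification against explicit voxel-loop oracles and
# analytic phantom truth.

randomVolume <- function(dim, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  ScalarVolume3D(array(rnorm(prod(dim), 100, 30), dim = dim),
                 spacing = spacing)
}

test_that("background subtraction matches voxel-by-voxel loop and edge cases", {
  v <- randomVolume(c(6, 5, 4), seed = 1)
  expect_equal(volumeData(subtractBackground(v, v)),
               array(0, dim = c(6, 5, 4)))
  shifted <- ScalarVolume3D(volumeData(v) + 50, spacing = voxelSpacing(v))
  expect_equal(volumeData(subtractBackground(shifted, v)),
               array(50, dim = c(6, 5, 4)))
  w <- randomVolume(c(6, 5, 4), seed = 2)
  got <- volumeData(subtractBackground(v, w))
  want <- array(0, dim = c(6, 5, 4))
  for (i in 1:6) for (j in 1:5) for (k in 1:4)
    want[i, j, k] <- volumeData(v)[i, j, k] - volumeData(w)[i, j, k]
  expect_identical(got, want)
  bad <- randomVolume(c(6, 5, 3), seed = 3)
  expect_error(subtractBackground(v, bad), "dimension")
})

test_that("parenchymal threshold averages reference neighborhoods", {
  m <- array(0, dim = c(8, 8, 8))
  m[2, 2, 2] <- 10; m[5, 5, 5] <- 20; m[7, 7, 7] <- 30
  vol <- ScalarVolume3D(m)
  refs0 <- ReferencePointSet(rbind(c(2, 2, 2), c(5, 5, 5), c(7, 7, 7)),
                             neighborhoodRadius = 0L)
  expect_equal(parenchymaThreshold(vol, refs0), 20)

  cvol <- ScalarVolume3D(array(7.5, dim = c(8, 8, 8)))
  refs1 <- ReferencePointSet(rbind(c(2, 2, 2), c(4, 4, 4), c(6, 6, 6)))
  expect_equal(parenchymaThreshold(cvol, refs1), 7.5)

  # radius-1 neighborhoods on a random map: explicit 27-voxel averaging
  rv <- randomVolume(c(8, 8, 8), seed = 4)
  pts <- rbind(c(2, 3, 4), c(5, 5, 5), c(7, 2, 6))
  oracle <- mean(apply(pts, 1, function(p) {
    acc <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
      acc <- c(acc, volumeData(rv)[p[1] + di, p[2] + dj, p[3] + dk])
    mean(acc)
  }))
  expect_equal(parenchymaThreshold(rv, ReferencePointSet(pts)), oracle)

  expect_error(ReferencePointSet(rbind(c(1, 1, 1), c(2, 2, 2))), "3")
  refsOut <- ReferencePointSet(rbind(c(1, 1, 1), c(2, 2, 2), c(9, 1, 1)))
  expect_error(parenchymaThreshold(rv, refsOut), "bounds")
})

test_that("viable segmentation is strict and matches the loop oracle", {
  rv <- randomVolume(c(7, 6, 5), seed = 5)
  set.seed(6)
  seg1 <- BinaryMask3D(array(rbinom(7 * 6 * 5, 1, 0.5), dim = c(7, 6, 5)))
  thr <- 100
  got <- volumeData(segmentViable(rv, seg1, thr))
  want <- array(0, dim = c(7, 6, 5))
  for (i in 1:7) for (j in 1:6) for (k in 1:5)
    want[i, j, k] <- as.numeric(volumeData(seg1)[i, j, k] == 1 &&
                                volumeData(rv)[i, j, k] > thr)
  expect_identical(got, want)

  const <- ScalarVolume3D(array(thr, dim = c(7, 6, 5)))
  expect_equal(sum(volumeData(segmentViable(const, seg1, thr))), 0)
  expect_identical(volumeData(segmentViable(rv, seg1, -Inf)),
                   volumeData(seg1))
})

test_that("mask volume follows voxel count x voxel volume", {
  m <- array(0, dim = c(20, 10, 10)); m[1:10, 1:10, 1:10] <- 1
  expect_equal(maskVolume(BinaryMask3D(m)), 1)
  expect_equal(maskVolume(BinaryMask3D(array(0, dim = c(4, 4, 4)))), 0)
  # anisotropic spacing
  expect_equal(maskVolume(BinaryMask3D(m, spacing = c(0.5, 1, 2))), 1)

  # digitized ellipsoid vs analytic volume
  a <- 20; b <- 15; cc <- 10
  d <- c(45, 35, 25)
  ctr <- (d - 1) / 2
  g <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  inside <- ((g$i - ctr[1]) / a)^2 + ((g$j - ctr[2]) / b)^2 +
            ((g$k - ctr[3]) / cc)^2 <= 1
  vol <- maskVolume(BinaryMask3D(array(as.numeric(inside), dim = d)))
  expect_lt(abs(vol - 4 / 3 * pi * a * b * cc / 1000) /
            (4 / 3 * pi * a * b * cc / 1000), 0.02)
})

test_that("quantification recovers phantom truth and respects invariants", {
  ph <- generatePhantom(phantomSpec(seed = 1L))
  res <- quantifyViableTumor(ph$enhanced, ph$unenhanced, ph$seg1,
                             ph$refPoints)
  expect_lt(abs(vtv(res) - ph$trueVtvCm3) / ph$trueVtvCm3, 0.02)
  # Seg2 subset of Seg1, VTV bounded by whole-tumor volume
  expect_true(all(volumeData(seg2(res)) <= volumeData(ph$seg1)))
  expect_lte(vtv(res), maskVolume(ph$seg1))

  # fully necrotic tumor: no viable voxels
  nec <- generatePhantom(phantomSpec(viableFraction = 0, seed = 2L))
  resNec <- quantifyViableTumor(nec$enhanced, nec$unenhanced, nec$seg1,
                                nec$refPoints)
  expect_equal(vtv(resNec), 0)
})

test_that("threshold monotonicity and joint translation invariance hold", {
  ph <- generatePhantom(phantomSpec(dim = c(24, 24, 24),
                                    semiAxes = c(8, 7, 6), noiseSd = 5,
                                    seed = 3L))
  enhMap <- subtractBackground(ph$enhanced, ph$unenhanced)
  thr <- parenchymaThreshold(enhMap, ph$refPoints)
  vols <- sapply(thr + c(-20, -10, 0, 10, 20), function(t)
    maskVolume(segmentViable(enhMap, ph$seg1, t)))
  expect_true(all(diff(vols) <= 0))

  res <- quantifyViableTumor(ph$enhanced, ph$unenhanced, ph$seg1,
                             ph$refPoints)
  shiftE <- ScalarVolume3D(volumeData(ph$enhanced) + 137)
  shiftU <- ScalarVolume3D(volumeData(ph$unenhanced) + 137)
  res2 <- quantifyViableTumor(shiftE, shiftU, ph$seg1, ph$refPoints)
  expect_equal(vtv(res2), vtv(res))
  expect_equal(enhancementThreshold(res2), enhancementThreshold(res))
})

test_that("NIfTI and reference-point round trips preserve the inputs", {
  ph <- generatePhantom(phantomSpec(dim = c(16, 16, 16),
                                    semiAxes = c(5, 4, 4),
                                    spacing = c(0.8, 0.8, 2.5), seed = 4L))
  tmp <- withr::local_tempdir()
  pv <- file.path(tmp, "enh.nii.gz")
  writeVolume(ph$enhanced, pv)
  back <- readVolume(pv)
  expect_equal(volumeData(back), volumeData(ph$enhanced), tolerance = 1e-6)
  expect_equal(voxelSpacing(back), voxelSpacing(ph$enhanced),
               tolerance = 1e-6)
  pm <- file.path(tmp, "seg1.nii.gz")
  writeMask(ph$seg1, pm)
  expect_equal(volumeData(readMask(pm)), volumeData(ph$seg1))

  pr <- file.path(tmp, "refs.csv")
  write.csv(data.frame(x = c(1, 2, 3), y = c(4, 5, 6), z = c(7, 8, 9)),
            pr, row.names = FALSE)
  refs <- readReferencePoints(pr)
  expect_equal(unname(refs@points[, 1]), c(2, 3, 4))  # 0-based -> 1-based
})
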