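test_that("ROI extraction reproduces single-voxel traces and constant regions", {
  # two regions of one voxel each: the mean is the voxel trace itself
  img <- array(0, c(5, 2, 1, 1))
  img[, 1, 1, 1] <- 1:5
  img[, 2, 1, 1] <- 11:15
  atl <- array(c(1L, 2L), c(2, 1, 1))
  ts <- extractRoiTimeseries(img, atl, dropLeading = 0)
  expect_equal(unname(seriesValues(ts)), cbind(1:5, 11:15) * 1.0)

  # a 3-voxel region holding 5 everywhere averages to a constant 5
  img2 <- array(5, c(4, 3, 1, 1))
  img2[, 1, 1, 1] <- c(7, 7, 7, 7)  # second region
  atl2 <- array(c(2L, 1L, 1L), c(3, 1, 1))
  # make region 1 have 3 voxels of value 5: add one plane
  img3 <- array(5, c(4, 2, 2, 1))
  atl3 <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  ts3 <- extractRoiTimeseries(img3, atl3, dropLeading = 0)
  expect_equal(unname(seriesValues(ts3)[, 1]), rep(5, 4))
})

test_that("ROI extraction with leading-frame drop matches a brute-force voxel loop", {
  set.seed(7)
  img <- array(rnorm(4 * 3 * 2 * 2), c(4, 3, 2, 2))
  atl <- array(sample(c(0L, 1L, 2L), 12, replace = TRUE,
                      prob = c(0.2, 0.4, 0.4)), c(3, 2, 2))
  atl[1, 1, 1] <- 1L; atl[2, 1, 1] <- 2L  # both regions populated
  ts <- extractRoiTimeseries(img, atl, dropLeading = 1)
  expect_equal(unname(seriesValues(ts)),
               bruteForceRoiMeans(img, atl, dropLeading = 1))
  expect_equal(nrow(seriesValues(ts)), 3)
})

test_that("ROI extraction rejects bad grids, empty regions, and over-dropping", {
  img <- array(0, c(5, 2, 2, 1))
  atlWrong <- array(1L, c(3, 2, 1))
  expect_error(extractRoiTimeseries(img, atlWrong, 0), "dimension error")
  atlGap <- array(c(1L, 1L, 3L, 3L), c(2, 2, 1))  # region 2 empty
  expect_error(extractRoiTimeseries(img, atlGap, 0), "atlas error")
  atl <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  expect_error(extractRoiTimeseries(img, atl, dropLeading = 5), "input error")
})

test_that("Pearson FC reproduces the analytic and oracle-derived examples", {
  perfect <- pearsonFC(roiTimeSeries(cbind(c(1, 2, 3), c(2, 4, 6))))
  expect_equal(fcValues(perfect)[1, 2], 1)
  inverse <- pearsonFC(roiTimeSeries(cbind(c(1, 2, 3), c(3, 2, 1))))
  expect_equal(fcValues(inverse)[1, 2], -1)
  # oracle value: direct evaluation of the correlation formula gives 0.8
  mixed <- pearsonFC(roiTimeSeries(cbind(c(1, 2, 3, 4), c(1, 3, 2, 4))))
  expect_equal(fcValues(mixed)[1, 2], 0.8)
  expect_equal(fcValues(mixed)[1, 2],
               cor(c(1, 2, 3, 4), c(1, 3, 2, 4)))
})

test_that("Pearson FC matches a brute-force implementation on random series", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rnorm(30 * 6), 30, 6)
    got <- fcValues(pearsonFC(roiTimeSeries(x)))
    expect_lt(max(abs(got - bruteForcePearson(x))), 1e-12)
  }
})

test_that("Pearson FC is invariant under positive affine maps and flips under negation", {
  set.seed(12)
  x <- matrix(rnorm(40 * 5), 40, 5)
  base <- fcValues(pearsonFC(roiTimeSeries(x)))
  y <- sweep(sweep(x, 2, c(2, 0.5, 3, 1.5, 10), "*"), 2, rnorm(5), "+")
  expect_equal(fcValues(pearsonFC(roiTimeSeries(y))), base,
               tolerance = 1e-12, ignore_attr = TRUE)
  z <- x
  z[, 2] <- -z[, 2]
  flipped <- fcValues(pearsonFC(roiTimeSeries(z)))
  expected <- base
  expected[2, ] <- -expected[2, ]
  expected[, 2] <- -expected[, 2]
  diag(expected) <- 1
  expect_equal(flipped, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("FC of an image built from known region traces equals FC of the traces", {
  set.seed(13)
  traces <- matrix(rnorm(25 * 3), 25, 3)
  # region r occupies r voxels, all carrying the region trace
  atl <- array(c(1L, 2L, 2L, 3L, 3L, 3L), c(6, 1, 1))
  img <- array(0, c(25, 6, 1, 1))
  for (v in 1:6) img[, v, 1, 1] <- traces[, atl[v, 1, 1]]
  viaImage <- fcValues(pearsonFC(extractRoiTimeseries(img, atl, 0)))
  direct <- fcValues(pearsonFC(roiTimeSeries(traces)))
  expect_equal(viaImage, direct, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-variance regions yield zero correlations with a warning, not NaN", {
  x <- cbind(rnorm(10), rep(3, 10), rnorm(10))
  expect_warning(fc <- pearsonFC(roiTimeSeries(x)), "zero-variance")
  v <- fcValues(fc)
  expect_true(all(is.finite(v)))
  expect_equal(v[2, 1], 0)
  expect_equal(v[3, 2], 0)
  expect_equal(v[2, 2], 1)
  expect_true(validObject(fc))
})

test_that("FC matrices satisfy their invariants on random inputs", {
  set.seed(14)
  for (rep in 1:10) {
    v <- fcValues(randomFC(8))
    expect_equal(v, t(v))
    expect_equal(unname(diag(v)), rep(1, 8))
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("FD exclusion applies the strict over-threshold, over-count rule", {
  # 51 frames above 0.5 out of 140 -> exclude
  res <- fdExclude(c(rep(0.6, 51), rep(0, 89)))
  expect_true(res$exclude)
  expect_equal(res$badFrames, 51L)
  # no motion -> keep with count 0
  res0 <- fdExclude(rep(0, 140))
  expect_false(res0$exclude)
  expect_equal(res0$badFrames, 0L)
  # values exactly at the threshold do not count (strict inequality)
  resB <- fdExclude(rep(0.5, 50))
  expect_false(resB$exclude)
  expect_equal(resB$badFrames, 0L)
  # exactly 50 frames above threshold is still kept (count > 50 excludes)
  res50 <- fdExclude(c(rep(0.51, 50), rep(0.1, 90)))
  expect_false(res50$exclude)
  expect_true(fdExclude(c(rep(0.51, 51), rep(0.1, 89)))$exclude)
  expect_error(fdExclude(numeric(0)), "input error")
  expect_error(fdExclude(c(0.1, -0.2)), "input error")
})

test_that("series and FC round-trip through their TSV dialect", {
  dir <- withr::local_tempdir()
  ts <- roiTimeSeries(matrix(rnorm(30), 10, 3), subjectId = "s1",
                      timepoint = "12m")
  p <- file.path(dir, "series.tsv")
  writeRoiSeries(ts, p)
  back <- readRoiSeries(p, subjectId = "s1", timepoint = "12m")
  expect_equal(seriesValues(back), seriesValues(ts), tolerance = 1e-12,
               ignore_attr = TRUE)
  fc <- pearsonFC(ts)
  pf <- file.path(dir, "fc.tsv")
  writeFCMatrix(fc, pf)
  fcBack <- readFCMatrix(pf)
  expect_equal(fcValues(fcBack), fcValues(fc), tolerance = 1e-12,
               ignore_attr = TRUE)
  fdp <- file.path(dir, "fd.txt")
  writeLines(format(c(0.1, 0.6, 0.2)), fdp)
  expect_equal(readFDTrace(fdp), c(0.1, 0.6, 0.2))
})

test_that("upper-triangle vectorization is row-major and invertible", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 0.1; m[1, 3] <- 0.2; m[2, 3] <- 0.3
  m <- m + t(m); diag(m) <- 1
  expect_equal(upperTriVec(m), c(0.1, 0.2, 0.3))
  expect_equal(vecToSymmetric(c(0.1, 0.2, 0.3)), m)
  set.seed(15)
  v <- runif(45, -1, 1)
  expect_equal(upperTriVec(vecToSymmetric(v)), v)
})

test_that("NIfTI image and atlas files feed extraction like in-memory arrays", {
  dir <- withr::local_tempdir()
  arr <- array(rnorm(2 * 2 * 2 * 6), c(2, 2, 2, 6))  # X, Y, Z, frames
  atl <- array(c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L), c(2, 2, 2))
  imgPath <- file.path(dir, "img.nii.gz")
  atlPath <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), imgPath)
  RNifti::writeNifti(RNifti::asNifti(atl), atlPath)
  fromFile <- extractRoiTimeseries(imgPath, atlPath, dropLeading = 1)
  inMem <- extractRoiTimeseries(aperm(arr, c(4, 1, 2, 3)), atl,
                                dropLeading = 1)
  expect_equal(seriesValues(fromFile), seriesValues(inMem),
               tolerance = 1e-6, ignore_attr = TRUE)
})
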