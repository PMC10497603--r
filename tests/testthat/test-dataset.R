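test_that("ROI extraction crops to the requested size and tracks the centroid", {
  wl <- seq(400, 700, by = 10)
  big <- HyperCube(array(runif(40 * 60 * length(wl)), c(40, 60, length(wl))),
                   wl)
  roi <- extractROI(big, 20L)
  expect_equal(dim(reflectance(roi)), c(20L, 20L, length(wl)))
  # an exactly ROI-sized image is returned unchanged
  exact <- randomCube(20L, 20L, wl, seed = 3L)
  expect_equal(reflectance(extractROI(exact, 20L)), reflectance(exact))
  expect_error(extractROI(randomCube(10L, 10L, wl), 20L), "smaller")
})

test_that("the ROI centers on the valid-pixel disk centroid", {
  wl <- seq(400, 500, by = 10)
  img <- HyperCube(array(0.5, c(60, 60, length(wl))), wl)
  center <- c(38, 22)
  for (i in 1:60) for (j in 1:60)
    img@mask[i, j] <- sum((c(i, j) - center)^2) <= 8^2
  roi <- extractROI(img, 20L)
  idx <- which(img@mask, arr.ind = TRUE)
  expect_equal(dim(validMask(roi)), c(20L, 20L))
  # the crop center must sit within one pixel of the disk centroid
  # (recover the crop offset from the mask pattern)
  expect_true(all(validMask(roi)[10:11, 10:11]))
})

test_that("mean spectra match a scalar double-loop oracle and skip masked pixels", {
  cube <- randomCube(5L, 6L, seq(400, 500, by = 10), seed = 17L)
  cube@mask[2, 3] <- FALSE
  cube@mask[5, 1] <- FALSE
  spec <- toMeanSpectrum(cube)
  expect_length(spec, nBands(cube))
  oracle <- numeric(nBands(cube))
  for (k in seq_len(nBands(cube))) {
    s <- 0; n <- 0
    for (i in 1:5) for (j in 1:6) if (cube@mask[i, j]) {
      s <- s + reflectance(cube)[i, j, k]
      n <- n + 1
    }
    oracle[k] <- s / n
  }
  expect_lt(max(abs(spec - oracle)), 1e-12)
  # constant cube -> constant vector
  expect_equal(toMeanSpectrum(constantCube(0.9)), rep(0.9, 31))
  allBad <- cube
  allBad@mask[] <- FALSE
  expect_error(toMeanSpectrum(allBad), "flagged")
})

test_that("mean spectra are invariant to spatial pixel shuffling", {
  cube <- randomCube(4L, 4L, seq(400, 450, by = 10), seed = 23L)
  set.seed(1)
  perm <- sample(16L)
  shuf <- array(0, dim(reflectance(cube)))
  flat <- matrix(reflectance(cube), 16L)
  shuf <- array(flat[perm, ], dim(reflectance(cube)))
  cubeShuf <- HyperCube(shuf, wavelengths(cube))
  expect_equal(toMeanSpectrum(cubeShuf), toMeanSpectrum(cube),
               tolerance = 1e-12)
})

test_that("Brix groups follow the half-open interval convention", {
  expect_equal(assignBrixGroup(c(8.65, 10.44, 11.48, 12.52, 14.01)), 1:5)
  # boundaries belong to the upper group
  expect_equal(assignBrixGroup(c(10, 11, 12, 13)), 2:5)
  expect_equal(assignBrixGroup(9.999), 1L)
  expect_error(assignBrixGroup(NaN), "finite")
  expect_error(assignBrixGroup(-1), "positive")
})

test_that("stratified splits reproduce the published group counts", {
  s218 <- splitDataset(as.character(1:218), seed = 5L)
  expect_equal(lengths(list(s218@trainIds, s218@validIds, s218@testIds)),
               c(131L, 44L, 43L))
  s162 <- splitDataset(as.character(1:162), seed = 5L)
  expect_equal(lengths(list(s162@trainIds, s162@validIds, s162@testIds)),
               c(97L, 33L, 32L))
  # degenerate ratios: everything in training
  s0 <- splitDataset(as.character(1:10), ratios = c(1, 0, 0))
  expect_equal(length(s0@trainIds), 10L)
  expect_equal(length(s0@testIds), 0L)
})

test_that("splits are disjoint, exhaustive, deterministic, and stratified", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(1:400, 1)
    ids <- paste0("x", seq_len(n))
    groups <- sample(1:5, n, replace = TRUE)
    sp <- splitDataset(ids, groups, seed = rep)
    all_ids <- c(sp@trainIds, sp@validIds, sp@testIds)
    expect_equal(sort(all_ids), sort(ids))
    expect_equal(anyDuplicated(all_ids), 0L)
    sp2 <- splitDataset(ids, groups, seed = rep)
    expect_identical(sp@trainIds, sp2@trainIds)
    # per-group counts follow the floor/ceiling rule
    for (g in unique(groups)) {
      ng <- sum(groups == g)
      gids <- ids[groups == g]
      expect_equal(sum(sp@testIds %in% gids), floor(0.2 * ng))
      expect_equal(sum(sp@validIds %in% gids), ceiling(0.2 * ng))
    }
  }
  expect_warning(splitDataset(character(0), integer(0)), NA)
})

test_that("split JSON round trips", {
  sp <- splitDataset(as.character(1:50), seed = 8L)
  path <- file.path(tempdir(), "split.json")
  writeSplit(sp, path)
  back <- readSplit(path)
  expect_identical(back@trainIds, sp@trainIds)
  expect_identical(back@testIds, sp@testIds)
  expect_equal(back@seed, sp@seed)
})

test_that("sample sets keep spectra consistent with their cubes", {
  wl <- seq(400, 700, by = 10)
  grid <- makeRangeGrid("VIS", 15)
  cubes <- lapply(1:4, function(i)
    resampleToBands(randomCube(6L, 6L, wl, seed = i), grid))
  ss <- makeSampleSet(cubes, brix = c(9, 10.5, 12, 14))
  expect_equal(length(ss), 4L)
  expect_equal(ss@group, c(1L, 2L, 4L, 5L))
  for (i in 1:4)
    expect_lt(max(abs(ss@spectra[i, ] -
                        apply(ss@cubes[, , , i], 3, mean))), 1e-10)
  sub <- subsetSamples(ss, c("s3", "s1"))
  expect_equal(brix(sub), c(12, 9))
  expect_error(subsetSamples(ss, "nope"), "unknown sample ids")
})

test_that("labels CSV derives groups when absent", {
  path <- file.path(tempdir(), "labels.csv")
  write.csv(data.frame(sample_id = c("a", "b"), brix = c(9.5, 13.2)),
            path, row.names = FALSE)
  df <- readLabels(path)
  expect_equal(df$group, c(1L, 5L))
})
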