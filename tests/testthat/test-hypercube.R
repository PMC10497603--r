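test_that("calibration reproduces identity and zero limits", {
  wl <- seq(400, 420, by = 10)
  dark <- array(100, c(2, 2, 3))
  white <- array(1100, c(2, 2, 3))
  cube1 <- calibrateReflectance(RawFrames(white, dark, white, wl))
  expect_equal(reflectance(cube1), array(1, c(2, 2, 3)))
  cube0 <- calibrateReflectance(RawFrames(dark, dark, white, wl))
  expect_equal(reflectance(cube0), array(0, c(2, 2, 3)))
  expect_false(isSmoothed(cube1))
})

test_that("calibration matches the scalar-loop oracle elementwise", {
  raw <- randomRawFrames(2L, 2L, 3L, seed = 42L)
  cube <- calibrateReflectance(raw)
  expect_lt(max(abs(reflectance(cube) - calibrateOracle(raw))), 1e-12)
})

test_that("calibration is scale-invariant in the raw counts", {
  raw <- randomRawFrames(3L, 2L, 4L, seed = 7L)
  for (c in c(0.5, 3, 1000)) {
    scaled <- RawFrames(raw@sample * c, raw@dark * c, raw@white * c,
                        raw@wavelengths)
    expect_lt(max(abs(reflectance(calibrateReflectance(scaled)) -
                        reflectance(calibrateReflectance(raw)))), 1e-12)
  }
})

test_that("degenerate white-dark pixels are masked, not NaN", {
  wl <- seq(400, 410, by = 10)
  dark <- array(100, c(2, 2, 2))
  white <- array(1100, c(2, 2, 2))
  white[1, 1, 1] <- 100        # one band of one pixel degenerates
  cube <- calibrateReflectance(RawFrames(white, dark, white, wl))
  expect_false(validMask(cube)[1, 1])
  expect_true(all(validMask(cube)[-1]))
  expect_true(all(is.finite(reflectance(cube))))
  # fully degenerate cube errors
  expect_error(calibrateReflectance(RawFrames(dark, dark, dark, wl)),
               "every pixel")
})

test_that("frame shape mismatches name the offending axis", {
  wl <- seq(400, 420, by = 10)
  a <- array(1, c(2, 2, 3))
  b <- array(1, c(2, 3, 3))
  expect_error(RawFrames(a, b, a, wl), "axis 2")
  expect_error(RawFrames(a, a, a, c(420, 410, 400)), "strictly increasing")
})

test_that("SG smoothing preserves constants and linear spectra", {
  cube <- constantCube(0.7)
  sm <- smoothSavitzkyGolay(cube, 11L, 2L)
  expect_true(isSmoothed(sm))
  expect_equal(reflectance(sm), reflectance(cube), tolerance = 1e-12)
  # linear in wavelength: interior points reproduced exactly by order >= 1
  wl <- seq(400, 700, by = 10)
  lin <- HyperCube(array(rep(0.001 * wl, each = 4), c(2, 2, length(wl))), wl)
  smLin <- smoothSavitzkyGolay(lin, 5L, 2L)
  interior <- 3:(length(wl) - 2)
  expect_lt(max(abs(reflectance(smLin)[, , interior] -
                      reflectance(lin)[, , interior])), 1e-10)
})

test_that("window-5 order-2 smoothing equals the classic quadratic weights", {
  expect_equal(sgCoefficients(5L, 2L), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  set.seed(3)
  y <- rnorm(10)
  cube <- HyperCube(array(rep(y, each = 1), c(1, 1, 10)),
                    seq(400, 445, by = 5))
  sm <- reflectance(smoothSavitzkyGolay(cube, 5L, 2L))[1, 1, ]
  oracle <- sgOracleCenter(y, 5L, 2L)
  interior <- 3:8
  expect_lt(max(abs(sm[interior] - oracle[interior])), 1e-10)
})

test_that("SG smoothing matches the per-window least-squares oracle", {
  set.seed(11)
  y <- cumsum(rnorm(40, sd = 0.1)) + 0.5
  wl <- seq(400, by = 2, length.out = 40)
  for (cfg in list(c(7L, 2L), c(11L, 3L), c(9L, 0L))) {
    cube <- HyperCube(array(y, c(1, 1, 40)), wl)
    sm <- reflectance(smoothSavitzkyGolay(cube, cfg[1], cfg[2]))[1, 1, ]
    oracle <- sgOracleCenter(y, cfg[1], cfg[2])
    h <- (cfg[1] - 1) %/% 2
    interior <- (h + 1):(40 - h)
    expect_lt(max(abs(sm[interior] - oracle[interior])), 1e-10)
  }
})

test_that("SG coefficients sum to 1 and smoothing is linear", {
  for (w in c(5L, 7L, 11L, 15L)) for (p in 0:3) {
    if (p >= w) next
    expect_equal(sum(sgCoefficients(w, p)), 1, tolerance = 1e-12)
  }
  set.seed(5)
  x <- randomCube(seed = 20L)
  y <- randomCube(seed = 21L)
  a <- 2.5; b <- -1.2
  comb <- HyperCube(a * reflectance(x) + b * reflectance(y), wavelengths(x))
  left <- reflectance(smoothSavitzkyGolay(comb, 7L, 2L))
  right <- a * reflectance(smoothSavitzkyGolay(x, 7L, 2L)) +
    b * reflectance(smoothSavitzkyGolay(y, 7L, 2L))
  expect_lt(max(abs(left - right)), 1e-12)
})

test_that("SG smoothing rejects bad configurations", {
  cube <- constantCube(1, wl = seq(400, 440, by = 10))
  expect_error(smoothSavitzkyGolay(cube, 11L, 2L), "longer than the spectrum")
  expect_error(smoothSavitzkyGolay(cube, 4L, 2L), "odd")
  sm <- smoothSavitzkyGolay(cube, 5L, 2L)
  expect_error(smoothSavitzkyGolay(sm, 5L, 2L), "already smoothed")
})

test_that("ENVI round trip is lossless for both interleaves", {
  cube <- randomCube(3L, 5L, seq(450, 600, by = 15), seed = 9L,
                     smoothed = TRUE)
  cube@mask[2, 3] <- FALSE
  for (il in c("bsq", "bil")) {
    path <- file.path(tempdir(), paste0("cube_", il))
    writeCube(cube, path, "envi", interleave = il)
    back <- readCube(path, "envi")
    expect_equal(reflectance(back), reflectance(cube))
    expect_equal(wavelengths(back), wavelengths(cube))
    expect_equal(validMask(back), validMask(cube))
    expect_true(isSmoothed(back))
  }
  expect_error(readCube(file.path(tempdir(), "cube_bsq"), "zarr"),
               "unknown cube format")
})

test_that("out-of-order ENVI bands are sorted with data permuted to match", {
  cube <- randomCube(2L, 2L, c(400, 410, 420, 430), seed = 4L)
  path <- file.path(tempdir(), "scrambled")
  writeENVI(cube, path)
  # scramble the header wavelengths and the band order consistently
  hdr <- readLines(paste0(path, ".hdr"))
  perm <- c(3L, 1L, 4L, 2L)
  hdr[grepl("^wavelength =", hdr)] <-
    sprintf("wavelength = {%s}", paste(wavelengths(cube)[perm], collapse = ", "))
  writeLines(hdr, paste0(path, ".hdr"))
  scrambled <- reflectance(cube)[, , perm]
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.numeric(aperm(scrambled, c(2, 1, 3))), con, size = 8,
           endian = "little")
  close(con)
  back <- readENVI(path)
  expect_equal(wavelengths(back), wavelengths(cube))
  expect_equal(reflectance(back), reflectance(cube))
})

test_that("an ENVI file without wavelengths is rejected", {
  cube <- randomCube(2L, 2L, c(400, 410, 420), seed = 2L)
  path <- file.path(tempdir(), "nowl")
  writeENVI(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(path, ".hdr"))
  expect_error(readENVI(path), "wavelength")
})
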