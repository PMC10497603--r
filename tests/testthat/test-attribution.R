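# A linear model built from the network primitives: F(r) = a . r + b.
linearModel <- function(a, b = 0) {
  net <- buildNetwork(length(a), list(nnDense(1L)), seed = 1L)
  net$params[[1]]$W <- matrix(a, 1L)
  net$params[[1]]$b <- b
  specband:::newSbModel(net, modelSpec("fnn_multi", fcUnits = 1L),
                        inputKind = "spectrum")
}

# Scalar quadratic F(r) = r^2 with analytic gradient 2r.
quadraticModel <- function() {
  analyticModel(predictFn = function(x) rowSums(x^2),
                gradientFn = function(x) 2 * x)
}

test_that("literal-mode MIG of a linear model is exactly its coefficients", {
  set.seed(21)
  a <- rnorm(12)
  m <- linearModel(a, b = 1.3)
  x <- matrix(rnorm(5 * 12), 5, 12)
  for (M in c(1L, 7L, 50L)) {
    mig <- integratedGradients(m, x, M = M, mode = "literal")
    expect_equal(mig, a, tolerance = 1e-12)
  }
  # arbitrary baseline changes nothing for a constant-gradient model
  mig2 <- integratedGradients(m, x, baseline = rnorm(12), mode = "literal")
  expect_equal(mig2, a, tolerance = 1e-12)
  # constant model: zero gradient everywhere
  mig0 <- integratedGradients(linearModel(rep(0, 12), b = 2), x)
  expect_equal(mig0, rep(0, 12))
})

test_that("full-IG of a linear model recovers a_i * (x_i - baseline_i)", {
  a <- c(2, -1, 0.5)
  m <- linearModel(a)
  x <- matrix(c(1, 2, 3), 1, 3)
  attr <- integratedGradients(m, x, M = 10L, mode = "full_ig")
  expect_equal(attr, a * c(1, 2, 3), tolerance = 1e-12)
  # completeness is exact for linear models: sum = F(x) - F(0)
  expect_equal(sum(attr), sum(a * x), tolerance = 1e-12)
})

test_that("the scalar quadratic reproduces the (M+1)/M closed form", {
  # gradient 2r at right-endpoint path points k/M for input 1, baseline 0:
  # literal MIG = sum(2k/M)/M = (M+1)/M
  m <- quadraticModel()
  x <- matrix(1, 1, 1)
  mig50 <- integratedGradients(m, x, M = 50L, mode = "literal")
  expect_equal(as.numeric(mig50), 51 / 50, tolerance = 1e-12)
  # full-IG converges to completeness: F(1) - F(0) = 1 as M grows
  for (M in c(50L, 200L, 1000L)) {
    attr <- integratedGradients(m, x, M = M, mode = "full_ig")
    expect_equal(as.numeric(attr), (M + 1) / M, tolerance = 1e-12)
  }
  expect_lt(abs(sum(integratedGradients(m, x, M = 200L, mode = "full_ig")) -
                  (predictBrix(m, x) - predictBrix(m, matrix(0, 1, 1)))),
            0.01)
})

test_that("ReLU-gated model exposes the right-endpoint path convention", {
  # F(r) = relu(r - 0.5): gradient 1 where r > 0.5, else 0. Path points
  # k/M for input 1, baseline 0: exactly floor(M/2) of k = 1..M satisfy
  # k/M > 0.5 for even M, so the literal MIG is 0.5 under right-endpoint
  # sampling (and would differ for left-endpoint or trapezoid).
  net <- buildNetwork(1L, list(nnDense(1L), nnReLU()), seed = 1L)
  net$params[[1]]$W <- matrix(1, 1, 1)
  net$params[[1]]$b <- -0.5
  m <- specband:::newSbModel(net, modelSpec("fnn_multi", fcUnits = 1L),
                             inputKind = "spectrum")
  mig <- integratedGradients(m, matrix(1, 1, 1), M = 50L, mode = "literal")
  expect_equal(as.numeric(mig), 0.5)
})

test_that("full-IG approaches completeness on a trained network", {
  grid <- makeRangeGrid("VIS", 15)
  ss <- spectraSampleSet(synthParams(wavelengths = seq(400, 700, by = 5),
                                     groupSizes = c(10L, 8L, 10L, 10L, 10L),
                                     plantedBands = data.frame(center = 550,
                                                               weight = 0.3),
                                     noiseSd = 0.05, seed = 6L), grid)
  split <- splitDataset(ss@sampleId, ss@group, seed = 6L)
  fit <- trainModel(buildFNN(fnnMultiSpec("VIS"), nBands(grid), seed = 6L),
                    ss, split, trainConfig(maxEpochs = 10L, seed = 6L))
  m <- fit$model
  x <- ss@spectra[1:8, , drop = FALSE]
  attr <- integratedGradients(m, x, M = 200L, mode = "full_ig")
  baselinePred <- predictBrix(m, matrix(0, 1, nBands(grid)))
  meanDiff <- mean(predictBrix(m, x)) - baselinePred
  expect_lt(abs(sum(attr) - meanDiff) / abs(meanDiff), 0.01)
})

test_that("band scores take the absolute of the spatial mean", {
  # FNN: score is |mig|
  expect_equal(scoreBands(c(-2, 3, 0)), c(2, 3, 0))
  # CNN: +a on half the pixels, -a on the other half cancels to zero
  mig <- array(0, c(4, 4, 2))
  mig[1:2, , 1] <- 5
  mig[3:4, , 1] <- -5
  mig[, , 2] <- 1
  expect_equal(scoreBands(mig), c(0, 1))
  # published signed attributions sort strictly descending by score
  migs <- c(37.260, 23.970, -23.750, -18.619, 16.998, -16.412)
  expect_true(all(diff(scoreBands(migs)) < 0))
})

test_that("scores are invariant to sample permutation", {
  a <- rnorm(6)
  m <- linearModel(a)
  set.seed(33)
  x <- matrix(rnorm(10 * 6), 10, 6)
  mig1 <- integratedGradients(m, x, mode = "full_ig")
  mig2 <- integratedGradients(m, x[sample(10), ], mode = "full_ig")
  expect_equal(mig1, mig2, tolerance = 1e-12)
})

test_that("greedy selection keeps the top scores subject to the spacing rule", {
  grid <- makeRangeGrid("VIS", 10)     # centers 410, 430, ..., 690
  score <- rep(0.1, 15)
  score[c(1, 4, 7, 10, 13, 15)] <- c(9, 8, 7, 6, 5, 4)
  sig <- selectSignatureBands(score, grid)
  expect_equal(bandCenters(sig),
               bandCenters(grid)[c(1, 4, 7, 10, 13, 15)])
  # adjacent centers exactly 20 nm apart are both admissible
  score2 <- rep(0, 15)
  score2[8:9] <- c(10, 9)              # 550 and 570, spaced exactly 20 nm
  score2[c(1, 3, 5, 12)] <- c(4, 3, 2, 1)
  sig2 <- selectSignatureBands(score2, grid)
  expect_true(all(c(550, 570) %in% bandCenters(sig2)))
  # too few admissible bands errors with the achievable count
  tiny <- makeBandGrid(400, 480, 10)   # 4 centers within 20 nm steps
  expect_error(selectSignatureBands(rep(1, nBands(tiny)), tiny, nBands = 6L),
               "only 4")
})

test_that("greedy selection matches the brute-force oracle on random scores", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    halfBw <- sample(c(5, 7.5, 10, 12.5, 15), 1)
    grid <- makeBandGrid(400, 400 + 2 * halfBw * n, halfBw)
    score <- round(runif(nBands(grid)), 3)   # rounded to force ties
    k <- sample(3:6, 1)
    got <- tryCatch(
      sort(bandCenters(selectSignatureBands(score, grid, nBands = k))),
      error = function(e) NULL)
    want <- greedyOracle(score, bandCenters(grid), k, 20)
    if (length(want) < k) {
      expect_null(got)
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("every signature set respects the exclusion radius", {
  expect_error(new("SignatureSet", centers = c(500, 510), scores = c(1, 1),
                   migs = c(1, 1), family = "fnn_multi", range = "VIS",
                   halfBandwidth = 5, exclusionRadius = 20,
                   igMode = "literal", seed = 1L),
               "exclusion")
})

test_that("signature sets serialize to JSON with provenance", {
  grid <- makeRangeGrid("VIS", 10)
  score <- seq(15, 1)
  sig <- selectSignatureBands(score, grid, family = "fnn_multi",
                              range = "VIS", seed = 4L)
  path <- file.path(tempdir(), "sig.json")
  writeSignatureSet(sig, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$centers_nm, bandCenters(sig))
  expect_equal(back$model_family, "fnn_multi")
  expect_equal(back$exclusion_nm, 20)
})
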