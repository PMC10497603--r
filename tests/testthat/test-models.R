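test_that("FNN architectures follow the published layer widths", {
  m <- buildFNN(fnnMultiSpec("VIS"), inputLength = 261L, seed = 1L)
  widths <- vapply(Filter(function(l) l$type == "dense", m$net$layers),
                   `[[`, 1L, "units")
  expect_equal(widths, c(256L, 128L, 64L, 32L, 1L))
  msig <- buildFNN(fnnSignatureSpec("VIS"), inputLength = 6L, seed = 1L)
  expect_equal(vapply(Filter(function(l) l$type == "dense", msig$net$layers),
                      `[[`, 1L, "units"), c(512L, 256L, 128L, 64L, 1L))
  # the signature FNN has no dropout layers
  expect_false(any(vapply(msig$net$layers, function(l)
    l$type == "dropout", TRUE)))
  expect_true(any(vapply(m$net$layers, function(l)
    l$type == "dropout", TRUE)))
  expect_error(modelSpec("fnn_multi", fcUnits = c(32L, 8L)), "end in 1")
})

test_that("FNN parameter counts match the closed-form oracle", {
  nIn <- 261L
  m <- buildFNN(fnnMultiSpec("VISWIR"), inputLength = nIn, seed = 1L)
  widths <- c(256L, 128L, 64L, 32L, 1L)
  ins <- c(nIn, widths[-5])
  dense <- sum(ins * widths + widths)          # weights + biases
  bn <- 2L * sum(widths[-5])                   # gamma + beta per hidden unit
  expect_equal(nParams(m$net), dense + bn)
})

test_that("forward passes give finite nonnegative outputs of the right shape", {
  m <- buildFNN(fnnMultiSpec("VIS"), inputLength = 30L, seed = 2L)
  p <- predictBrix(m, matrix(0, 5, 30))
  expect_length(p, 5L)
  expect_true(all(is.finite(p) & p >= 0))
  cm <- buildCNN(cnnSignatureSpec("VISWIR"), c(20L, 20L, 6L), seed = 2L)
  pc <- predictBrix(cm, array(0, c(20, 20, 6, 3)))
  expect_length(pc, 3L)
  expect_true(all(is.finite(pc) & pc >= 0))
})

test_that("the multispectral CNN reproduces the published shape arithmetic", {
  m <- buildCNN(cnnMultiSpec("VISWIR"), c(20L, 20L, 261L), seed = 1L)
  fl <- Filter(function(l) l$type == "flatten", m$net$layers)[[1L]]
  expect_equal(fl$outShape, 20L * 5L * 64L)
  dense <- vapply(Filter(function(l) l$type == "dense", m$net$layers),
                  `[[`, 1L, "units")
  expect_equal(dense, c(2048L, 512L, 1L))
  # signature CNN: four conv blocks, one average pool, FC 1024/512/1
  ms <- buildCNN(cnnSignatureSpec("VISWIR"), c(20L, 20L, 6L), seed = 1L)
  expect_equal(sum(vapply(ms$net$layers, function(l) l$type == "conv", TRUE)),
               4L)
  pools <- Filter(function(l) l$type == "pool", ms$net$layers)
  expect_length(pools, 1L)
  expect_equal(pools[[1L]]$kind, "average")
})

test_that("rmsle matches closed forms and hand computation", {
  expect_equal(rmsle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsle(exp(1) - 1, 0), 1, tolerance = 1e-12)
  hand <- sqrt(((log(2) - log(3))^2 + (log(4) - log(3))^2) / 2)
  expect_equal(rmsle(c(1, 3), c(2, 2)), hand, tolerance = 1e-12)
  expect_error(rmsle(-1, 1), "nonnegative")
  expect_error(rmsle(1:3, 1:2), "lengths differ")
})

test_that("the learning-rate schedule decays exponentially per epoch", {
  expect_equal(lrSchedule(0.0006, 1e-6, 0L), 0.0006)
  expect_equal(lrSchedule(0.0006, 1e-6, 1e6), 0.0006 / exp(1),
               tolerance = 1e-12)
  expect_equal(lrSchedule(0.0006, 1e-6, 1e6), 2.2073e-4, tolerance = 1e-4)
  expect_equal(lrSchedule(0.001, 0, 500L), 0.001)
  expect_error(lrSchedule(-1), "nonnegative")
})

test_that("MAE and R-squared match their definitions", {
  expect_equal(maeMetric(c(1, 2), c(2, 4)), 1.5)
  expect_equal(maeMetric(1:5, 1:5), 0)
  expect_equal(rSquared(1:5, 1:5), 1)
  true <- c(2, 4, 6, 9)
  expect_equal(rSquared(rep(mean(true), 4), true), 0)
  # symmetry and translation invariance of MAE
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(maeMetric(a, b), maeMetric(b, a))
  expect_equal(maeMetric(a + 3, b + 3), maeMetric(a, b))
  expect_error(rSquared(c(1, 2), c(3, 3)), "zero variance")
  # literal mode centers on the prediction mean
  expect_equal(rSquared(c(1, 3), c(2, 4), literal = TRUE),
               1 - ((2 - 1)^2 + (4 - 3)^2) / ((2 - 2)^2 + (4 - 2)^2))
})

test_that("zero-epoch training returns the initial weights and empty history", {
  grid <- makeRangeGrid("VIS", 15)
  ss <- spectraSampleSet(synthTinyParams(seed = 2L), grid, sgWindow = 5L)
  split <- splitDataset(ss@sampleId, ratios = c(0.5, 0.25, 0.25), seed = 1L)
  m <- buildFNN(fnnMultiSpec("VIS"), nBands(grid), seed = 9L)
  fit <- trainModel(m, ss, split, trainConfig(maxEpochs = 0L, seed = 1L))
  expect_length(fit$history$train, 0L)
  expect_length(fit$history$valid, 0L)
  # weights untouched (the output bias is initialized to the label mean)
  expect_equal(fit$model$net$params[[1]]$W, m$net$params[[1]]$W)
})

test_that("training is reproducible and checkpoints the best validation epoch", {
  grid <- makeRangeGrid("VIS", 10)
  params <- synthParams(wavelengths = seq(400, 700, by = 5),
                        groupSizes = c(8L, 6L, 8L, 8L, 8L),
                        plantedBands = data.frame(center = 550, weight = 0.3),
                        noiseSd = 0.1, seed = 4L)
  ss <- spectraSampleSet(params, grid)
  split <- splitDataset(ss@sampleId, ss@group, seed = 2L)
  cfg <- trainConfig(maxEpochs = 15L, patience = 15L, seed = 3L)
  fit1 <- trainModel(buildFNN(fnnMultiSpec("VIS"), nBands(grid), seed = 3L),
                     ss, split, cfg)
  fit2 <- trainModel(buildFNN(fnnMultiSpec("VIS"), nBands(grid), seed = 3L),
                     ss, split, cfg)
  expect_identical(fit1$metrics$mae, fit2$metrics$mae)
  expect_identical(fit1$history$valid, fit2$history$valid)
  expect_length(fit1$history$train, 15L)
  # checkpoint contract: returned weights achieve the minimal recorded
  # validation RMSLE
  expect_equal(fit1$bestEpoch, which.min(fit1$history$valid))
  pv <- predictBrix(fit1$model, subsetSamples(ss, split@validIds))
  expect_equal(rmsle(pv, brix(subsetSamples(ss, split@validIds))),
               min(fit1$history$valid), tolerance = 1e-12)
})

test_that("training reaches the noise floor on a linear synthetic task", {
  # mean |N(0, sigma)| = sigma * sqrt(2/pi); the trained model should land
  # within 25% of that floor for most seeds
  sigma <- 0.3
  bound <- 1.25 * sigma * sqrt(2 / pi)
  grid <- makeRangeGrid("VIS", 10)
  ok <- 0L
  for (seed in 1:3) {
    params <- synthParams(wavelengths = seq(400, 700, by = 5),
                          groupSizes = c(60L, 60L, 60L, 60L, 60L),
                          plantedBands = data.frame(center = c(500, 620),
                                                    weight = c(0.3, -0.25)),
                          noiseSd = sigma, seed = seed)
    ss <- spectraSampleSet(params, grid)
    split <- splitDataset(ss@sampleId, ss@group, seed = seed)
    fit <- trainModel(buildFNN(fnnMultiSpec("VIS"), nBands(grid), seed = seed),
                      ss, split,
                      trainConfig(maxEpochs = 300L, patience = 100L,
                                  seed = seed))
    pv <- predictBrix(fit$model, subsetSamples(ss, split@validIds))
    vmae <- maeMetric(pv, brix(subsetSamples(ss, split@validIds)))
    if (vmae <= bound) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})
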