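# Model families:
#   cnn_multi      - two same-padded Conv(64)->ReLU->BN blocks, each followed
#                    by max pooling, then two FC->ReLU->BN->Dropout blocks and
#                    a ReLU-activated scalar head; for multispectral cubes.
#   fnn_multi      - four FC->ReLU->BN->Dropout blocks + ReLU scalar head; for
#                    spatial-mean spectra.
#   cnn_signature  - four Conv(64)->ReLU->BN blocks, one average pool, two
#                    FC->ReLU->BN->Dropout blocks + ReLU scalar head; for
#                    six-band signature cubes.
#   fnn_signature  - four FC->ReLU->BN blocks (no dropout) + ReLU scalar head.
# Conv kernels act on the 20x20 spatial grid with bands as channels.

.cnnMultiTable <- list(
  VISWIR = list(kernel = c(1L, 5L), pools = list(c(1L, 2L), c(1L, 2L)),
                fc = c(2048L, 512L, 1L), batch = 32L, dropout = 0.3,
                lr = 6e-4),
  VISNIR = list(kernel = c(1L, 2L), pools = list(c(1L, 2L), c(2L, 1L)),
                fc = c(1024L, 256L, 1L), batch = 64L, dropout = 0.3,
                lr = 6e-4),
  VIS = list(kernel = c(1L, 2L), pools = list(c(2L, 1L), c(2L, 1L)),
             fc = c(1024L, 512L, 1L), batch = 128L, dropout = 0.2,
             lr = 6e-4),
  SWIR = list(kernel = c(1L, 5L), pools = list(c(2L, 2L), c(2L, 2L)),
              fc = c(1024L, 512L, 1L), batch = 32L, dropout = 0.1,
              lr = 1e-3)
)

.fnnMultiBatch <- c(VISWIR = 32L, VISNIR = 64L, VIS = 128L, SWIR = 64L)

.cnnSignatureTable <- list(
  VISWIR = list(kernel = c(4L, 1L), pool = c(2L, 2L),
                fc = c(1024L, 512L, 1L), batch = 16L, lr = 4e-4),
  VISNIR = list(kernel = c(4L, 1L), pool = c(2L, 2L),
                fc = c(1024L, 512L, 1L), batch = 128L, lr = 8e-4),
  VIS = list(kernel = c(4L, 1L), pool = c(1L, 4L),
             fc = c(1024L, 512L, 1L), batch = 64L, lr = 4e-4)
)

.fnnSignatureBatch <- c(VISWIR = 64L, VISNIR = 128L, VIS = 128L)

#' Architecture specification for a Brix regression model
#'
#' Bundles the published per-range hyperparameters of the four model
#' families. \code{modelSpec} gives full control; the \code{*Spec}
#' convenience constructors look the values up by spectral range.
#'
#' @param family one of \code{"cnn_multi"}, \code{"fnn_multi"},
#'   \code{"cnn_signature"}, \code{"fnn_signature"}.
#' @param convKernel integer length-2 convolution kernel (CNN families).
#' @param poolKind "max" or "average".
#' @param poolSizes list of integer length-2 pool sizes.
#' @param convFilters filters per convolution layer.
#' @param fcUnits fully-connected widths, ending in 1.
#' @param dropoutRate dropout probability in [0, 1).
#' @param l2Lambda L2 penalty on convolution weights.
#' @param batchSize minibatch size.
#' @param lr initial learning rate.
#' @return a list of class \code{ModelSpec}.
#' @export
modelSpec <- function(family, convKernel = NULL, poolKind = "max",
                      poolSizes = list(), convFilters = 64L,
                      fcUnits, dropoutRate = 0, l2Lambda = 1e-10,
                      batchSize = 32L, lr = 1e-3) {
  if (utils::tail(fcUnits, 1L) != 1L)
    stop("fcUnits must end in 1 (scalar Brix output)")
  structure(list(family = family, convKernel = convKernel,
                 poolKind = poolKind, poolSizes = poolSizes,
                 convFilters = as.integer(convFilters),
                 fcUnits = as.integer(fcUnits), dropoutRate = dropoutRate,
                 l2Lambda = l2Lambda, batchSize = as.integer(batchSize),
                 lr = lr),
            class = "ModelSpec")
}

#' @rdname modelSpec
#' @param range spectral-range label (VIS, VISNIR, SWIR, VISWIR).
#' @export
cnnMultiSpec <- function(range = "VISWIR") {
  p <- .cnnMultiTable[[range]]
  if (is.null(p)) stop("no multispectral CNN hyperparameters for ", range)
  modelSpec("cnn_multi", convKernel = p$kernel, poolKind = "max",
            poolSizes = p$pools, fcUnits = p$fc, dropoutRate = p$dropout,
            batchSize = p$batch, lr = p$lr)
}

#' @rdname modelSpec
#' @export
fnnMultiSpec <- function(range = "VISWIR") {
  b <- .fnnMultiBatch[[range]]
  if (is.null(b)) stop("no multispectral FNN hyperparameters for ", range)
  modelSpec("fnn_multi", fcUnits = c(256L, 128L, 64L, 32L, 1L),
            dropoutRate = 0.3, batchSize = b, lr = 1e-3)
}

#' @rdname modelSpec
#' @export
cnnSignatureSpec <- function(range = "VISWIR") {
  p <- .cnnSignatureTable[[range]]
  if (is.null(p)) stop("no signature CNN hyperparameters for ", range)
  modelSpec("cnn_signature", convKernel = p$kernel, poolKind = "average",
            poolSizes = list(p$pool), fcUnits = p$fc, dropoutRate = 0.3,
            batchSize = p$batch, lr = p$lr)
}

#' @rdname modelSpec
#' @export
fnnSignatureSpec <- function(range = "VISWIR") {
  b <- .fnnSignatureBatch[[range]]
  if (is.null(b)) stop("no signature FNN hyperparameters for ", range)
  modelSpec("fnn_signature", fcUnits = c(512L, 256L, 128L, 64L, 1L),
            dropoutRate = 0, batchSize = b, lr = 8e-4)
}

#' Build a feedforward Brix regressor
#'
#' One FC-ReLU-BN(-Dropout) block per hidden width, then a ReLU-activated
#' scalar head. Dropout is present only when the spec's rate is positive
#' (the signature-band FNN family omits it).
#'
#' @param spec a \code{\link{modelSpec}} of an FNN family.
#' @param inputLength number of spectral bands in the input vector.
#' @param seed weight-initialization seed.
#' @return an \code{sbModel}.
#' @export
buildFNN <- function(spec, inputLength, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (!grepl("^fnn", spec$family))
    stop("buildFNN expects an fnn_* spec, got ", spec$family)
  hidden <- spec$fcUnits[-length(spec$fcUnits)]
  layers <- list()
  for (u in hidden) {
    layers <- c(layers, list(nnDense(u), nnReLU(), nnBatchNorm()))
    if (spec$dropoutRate > 0) layers <- c(layers, list(nnDropout(spec$dropoutRate)))
  }
  layers <- c(layers, list(nnDense(1L), nnReLU()))
  net <- buildNetwork(as.integer(inputLength), layers, seed = seed)
  newSbModel(net, spec, inputKind = "spectrum")
}

#' Build a convolutional Brix regressor
#'
#' \code{cnn_multi}: two same-padded Conv-ReLU-BN blocks (64 filters), each
#' followed by a max pool, then flatten and two FC-ReLU-BN-Dropout blocks
#' before the ReLU scalar head. \code{cnn_signature}: four Conv-ReLU-BN
#' blocks, a single average pool, then the same fully-connected tail. The L2
#' penalty of the spec applies to convolution weights during training.
#'
#' @param spec a \code{\link{modelSpec}} of a CNN family.
#' @param inputShape integer (height, width, bands) of one sample cube.
#' @param seed weight-initialization seed.
#' @return an \code{sbModel}.
#' @export
buildCNN <- function(spec, inputShape, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (!grepl("^cnn", spec$family))
    stop("buildCNN expects a cnn_* spec, got ", spec$family)
  layers <- list()
  if (spec$family == "cnn_multi") {
    for (pool in spec$poolSizes) {
      layers <- c(layers, list(
        nnConv2d(spec$convFilters, spec$convKernel), nnReLU(), nnBatchNorm(),
        nnPool("max", pool)))
    }
  } else {
    for (rep in 1:4) {
      layers <- c(layers, list(
        nnConv2d(spec$convFilters, spec$convKernel), nnReLU(), nnBatchNorm()))
    }
    layers <- c(layers, list(nnPool("average", spec$poolSizes[[1L]])))
  }
  layers <- c(layers, list(nnFlatten()))
  hidden <- spec$fcUnits[-length(spec$fcUnits)]
  for (u in hidden) {
    layers <- c(layers, list(nnDense(u), nnReLU(), nnBatchNorm()))
    if (spec$dropoutRate > 0) layers <- c(layers, list(nnDropout(spec$dropoutRate)))
  }
  layers <- c(layers, list(nnDense(1L), nnReLU()))
  net <- buildNetwork(as.integer(inputShape), layers, seed = seed)
  newSbModel(net, spec, inputKind = "cube")
}

newSbModel <- function(net, spec, inputKind) {
  structure(list(net = net, spec = spec, inputKind = inputKind),
            class = "sbModel")
}

#' @export
print.sbModel <- function(x, ...) {
  cat(sprintf("sbModel (%s): input (%s), %d parameters\n", x$spec$family,
              paste(x$net$inputShape, collapse = "x"), nParams(x$net)))
  invisible(x)
}

# Pull the family-appropriate input batch out of a SampleSet (or pass arrays
# through). FNN: (N, bands) matrix. CNN: (H, W, bands, N) array.
modelInput <- function(model, data) {
  if (is(data, "SampleSet")) {
    if (model$inputKind == "spectrum") data@spectra else data@cubes
  } else data
}

#' Root mean squared logarithmic error
#'
#' \code{sqrt(mean((log1p(pred) - log1p(true))^2))}; the training loss.
#'
#' @param pred,true nonnegative numeric vectors of equal length.
#' @return the RMSLE.
#' @export
rmsle <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred and true lengths differ")
  if (any(pred < 0) || any(true < 0)) stop("RMSLE requires nonnegative values")
  sqrt(mean((log1p(pred) - log1p(true))^2))
}

#' Exponentially decayed learning rate
#'
#' \code{lr0 * exp(-k * j)} for epoch index \code{j} (0-based).
#'
#' @param lr0 initial learning rate, positive.
#' @param k decay rate per epoch (default 1e-6).
#' @param j integer epoch index >= 0.
#' @return the learning rate at epoch \code{j}.
#' @export
lrSchedule <- function(lr0, k = 1e-6, j = 0L) {
  if (lr0 < 0) stop("initial learning rate must be nonnegative")
  if (any(j < 0)) stop("epoch index must be nonnegative")
  lr0 * exp(-k * j)
}

#' Mean absolute error
#'
#' @param pred,true numeric vectors of equal, nonzero length.
#' @return MAE in the units of the inputs (degrees Brix here).
#' @export
maeMetric <- function(pred, true) {
  if (length(pred) != length(true) || length(pred) == 0L)
    stop("pred and true must have equal nonzero length")
  mean(abs(pred - true))
}

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot}. By default the total sum of squares is taken
#' about the mean of the reference values (the conventional definition,
#' under which a perfect predictor scores exactly 1);
#' \code{literal = TRUE} centers on the mean of the predictions instead.
#'
#' @param pred,true numeric vectors of equal, nonzero length.
#' @param literal center SS_tot on the prediction mean instead.
#' @return R-squared (at most 1; can be negative for poor fits).
#' @export
rSquared <- function(pred, true, literal = FALSE) {
  if (length(pred) != length(true) || length(pred) == 0L)
    stop("pred and true must have equal nonzero length")
  center <- if (literal) mean(pred) else mean(true)
  ssTot <- sum((true - center)^2)
  if (ssTot == 0) stop("reference values have zero variance; R^2 undefined")
  1 - sum((true - pred)^2) / ssTot
}

#' Training configuration
#'
#' @param lr initial learning rate (defaults to the spec's when used through
#'   \code{\link{trainModel}}).
#' @param k exponential learning-rate decay per epoch.
#' @param batchSize minibatch size.
#' @param maxEpochs maximum training epochs.
#' @param patience early-stop after this many epochs without a validation
#'   improvement.
#' @param seed RNG seed for init, shuffling and dropout.
#' @return a list of class \code{TrainConfig}.
#' @export
trainConfig <- function(lr = NULL, k = 1e-6, batchSize = NULL,
                        maxEpochs = 500L, patience = 100L, seed = 1L) {
  stopifnot(is.null(lr) || lr > 0, k >= 0)
  structure(list(lr = lr, k = k, batchSize = batchSize,
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Train a Brix regressor
#'
#' Adam-optimizes the RMSLE loss over minibatches with the per-epoch
#' exponential learning-rate schedule. After every epoch the validation
#' RMSLE is computed in inference mode and the best-so-far weights are
#' checkpointed; the returned model carries the checkpointed weights. The
#' scalar head's bias is initialized to the training-label mean so the ReLU
#' output unit starts alive and near the data scale.
#'
#' @param model an \code{sbModel} from \code{\link{buildFNN}} or
#'   \code{\link{buildCNN}}.
#' @param data a \linkS4class{SampleSet}.
#' @param split a \linkS4class{DatasetSplit} over \code{data}'s sample ids.
#' @param config a \code{\link{trainConfig}}; \code{lr}/\code{batchSize}
#'   default to the model spec's values.
#' @return a list with elements \code{model} (trained), \code{metrics}
#'   (test \code{mae}, \code{r2} when a test set exists), \code{history}
#'   (per-epoch train loss and validation RMSLE), \code{bestEpoch}.
#' @export
trainModel <- function(model, data, split, config = trainConfig()) {
  stopifnot(inherits(model, "sbModel"), is(data, "SampleSet"),
            is(split, "DatasetSplit"))
  lr0 <- config$lr %||% model$spec$lr
  batch <- config$batchSize %||% model$spec$batchSize
  lambda <- model$spec$l2Lambda
  trainSet <- subsetSamples(data, split@trainIds)
  validSet <- if (length(split@validIds)) subsetSamples(data, split@validIds)
  xTrain <- toInternal(modelInput(model, trainSet))
  yTrain <- trainSet@brix
  xValid <- if (!is.null(validSet)) toInternal(modelInput(model, validSet))
  nTrain <- length(yTrain)
  if (nTrain == 0L) stop("empty training set")

  net <- model$net
  # start the ReLU head alive and near the label scale
  lastDense <- max(which(vapply(net$layers, function(l) l$type == "dense",
                                TRUE)))
  net$params[[lastDense]]$b[] <- mean(yTrain)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  opt <- adamInit(net$params)
  convIdx <- which(vapply(net$layers, function(l) l$type == "conv", TRUE))
  trainHist <- validHist <- numeric(0)
  bestVal <- Inf
  bestNet <- net
  bestEpoch <- 0L
  step <- 0L
  sinceBest <- 0L

  for (epoch in seq_len(config$maxEpochs)) {
    lr <- lrSchedule(lr0, config$k, epoch - 1L)
    ord <- sample.int(nTrain)
    epochLoss <- 0
    nBatches <- 0L
    for (start in seq(1L, nTrain, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, nTrain)]
      xb <- sliceBatch(xTrain, idx)
      yb <- yTrain[idx]
      fw <- netForward(net, xb, train = TRUE)
      net$state <- fw$state
      pred <- as.numeric(fw$out)
      e <- log1p(pred) - log1p(yb)
      loss <- sqrt(mean(e^2))
      if (!is.finite(loss))
        stop("training diverged to a non-finite loss at epoch ", epoch)
      dOut <- if (loss > 0)
        matrix(e / (length(e) * loss * (1 + pred)), 1L) else
        matrix(0, 1L, length(e))
      bw <- netBackward(net, fw$caches, dOut)
      if (lambda > 0) for (ci in convIdx)
        bw$grads[[ci]]$W <- bw$grads[[ci]]$W + 2 * lambda * net$params[[ci]]$W
      step <- step + 1L
      upd <- adamStep(net, bw$grads, opt, lr, step)
      net <- upd$net
      opt <- upd$opt
      epochLoss <- epochLoss + loss
      nBatches <- nBatches + 1L
    }
    trainHist <- c(trainHist, epochLoss / nBatches)
    if (!is.null(validSet)) {
      pv <- as.numeric(netForward(net, xValid, train = FALSE)$out)
      vloss <- rmsle(pv, validSet@brix)
      validHist <- c(validHist, vloss)
      if (vloss < bestVal) {
        bestVal <- vloss
        bestNet <- net
        bestEpoch <- epoch
        sinceBest <- 0L
      } else sinceBest <- sinceBest + 1L
      if (sinceBest >= config$patience) break
    } else {
      bestNet <- net
      bestEpoch <- epoch
    }
  }

  model$net <- bestNet
  metrics <- list(mae = NA_real_, r2 = NA_real_)
  if (length(split@testIds)) {
    testSet <- subsetSamples(data, split@testIds)
    pt <- predictBrix(model, testSet)
    metrics <- list(mae = maeMetric(pt, testSet@brix),
                    r2 = rSquared(pt, testSet@brix))
  }
  list(model = model, metrics = metrics,
       history = list(train = trainHist, valid = validHist),
       bestEpoch = bestEpoch)
}

sliceBatch <- function(x, idx) {
  if (length(dim(x)) == 4L) x[, , , idx, drop = FALSE]
  else x[, idx, drop = FALSE]
}

#' Predict Brix values
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout).
#'
#' @param model a trained \code{sbModel}.
#' @param data a \linkS4class{SampleSet}, an (N, bands) spectrum matrix (FNN)
#'   or an (H, W, bands, N) cube stack (CNN).
#' @return numeric vector of predictions.
#' @export
predictBrix <- function(model, data) {
  if (!is.null(model$predictFn))
    return(model$predictFn(modelInput(model, data)))
  x <- toInternal(modelInput(model, data))
  as.numeric(netForward(model$net, x, train = FALSE)$out)
}

#' Analytic model wrapper for attribution checks
#'
#' Wraps closed-form prediction and gradient functions in the model
#' interface consumed by \code{\link{integratedGradients}}, so attribution
#' arithmetic can be validated against models whose integrated gradients are
#' known exactly.
#'
#' @param predictFn function(x) -> numeric predictions for a batch in user
#'   layout.
#' @param gradientFn function(x) -> gradient array in the same layout as
#'   \code{x}.
#' @param inputKind "spectrum" or "cube".
#' @return an \code{sbModel}-compatible object.
#' @export
analyticModel <- function(predictFn, gradientFn, inputKind = "spectrum") {
  structure(list(predictFn = predictFn, gradientFn = gradientFn,
                 spec = list(family = "analytic"), inputKind = inputKind),
            class = "sbModel")
}

#' Gradient of the model output with respect to its input
#'
#' Inference-mode reverse-mode gradient, the primitive behind integrated
#' gradients.
#'
#' @param model an \code{sbModel}.
#' @param x input batch in user layout ((N, bands) matrix or
#'   (H, W, bands, N) array).
#' @return gradient array in the same user layout as \code{x}.
#' @export
inputGradient <- function(model, x) {
  if (!is.null(model$gradientFn)) return(model$gradientFn(x))
  xi <- toInternal(x)
  n <- if (length(dim(xi)) == 4L) dim(xi)[4L] else ncol(xi)
  fw <- netForward(model$net, xi, train = FALSE)
  bw <- netBackward(model$net, fw$caches, matrix(1, 1L, n))
  g <- bw$dInput
  if (length(dim(g)) == 4L) aperm(g, c(2L, 3L, 1L, 4L)) else t(g)
}
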