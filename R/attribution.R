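#' Mean of integrated gradients over a sample batch
#'
#' Averages the model's input gradient along the straight path from a
#' baseline \eqn{R'} to each input \eqn{R}, evaluated at the right-endpoint
#' path points \eqn{R' + (k/M)(R - R')}, \eqn{k = 1..M}, then averages over
#' samples:
#' \deqn{MIG = \frac{1}{S}\frac{1}{M} \sum_s \sum_{k=1}^{M}
#'       \nabla F\big(R' + \tfrac{k}{M}(R_s - R')\big)}
#' \code{mode = "literal"} returns exactly this path-averaged gradient.
#' \code{mode = "full_ig"} multiplies each sample's path average elementwise
#' by \eqn{(R_s - R')} before the sample average — the standard
#' integrated-gradients attribution, which satisfies completeness
#' (attributions sum to \eqn{F(R) - F(R')}) as \eqn{M} grows.
#'
#' @param model an \code{sbModel} (or any object accepted by
#'   \code{\link{inputGradient}}).
#' @param samples input batch in user layout: an (N, bands) matrix for FNN
#'   models or an (H, W, bands, N) array for CNN models; or a
#'   \linkS4class{SampleSet}.
#' @param baseline baseline input of one sample's shape; default all zeros
#'   (the black reference, the natural zero of reflectance).
#' @param M number of path steps (default 50).
#' @param mode "literal" (as defined above) or "full_ig".
#' @return the MIG array shaped like one input sample: a length-C vector
#'   (FNN) or an (H, W, C) array (CNN).
#' @export
integratedGradients <- function(model, samples, baseline = NULL, M = 50L,
                                mode = c("literal", "full_ig")) {
  mode <- match.arg(mode)
  if (M < 1L) stop("M must be at least 1")
  if (is(samples, "SampleSet")) samples <- modelInput(model, samples)
  isCube <- length(dim(samples)) == 4L
  if (!isCube && is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  d <- dim(samples)
  n <- if (isCube) d[4L] else d[1L]
  oneShape <- if (isCube) d[1:3] else d[2L]
  if (is.null(baseline)) {
    baseline <- if (isCube) array(0, oneShape) else numeric(oneShape)
  }
  bdim <- if (isCube) dim(baseline) else length(baseline)
  if (!isTRUE(all.equal(as.integer(bdim), as.integer(oneShape))))
    stop("baseline shape does not match one input sample")
  # broadcast baseline across the batch
  bFull <- if (isCube) array(baseline, d) else
    matrix(baseline, n, oneShape, byrow = TRUE)
  diffs <- samples - bFull
  acc <- samples * 0
  for (k in seq_len(M)) {
    xk <- bFull + (k / M) * diffs
    acc <- acc + inputGradient(model, xk)
  }
  pathAvg <- acc / M                       # per-sample path-averaged gradient
  if (mode == "full_ig") pathAvg <- pathAvg * diffs
  if (isCube) {
    mig <- apply(pathAvg, 1:3, mean)       # average over samples
  } else {
    mig <- colMeans(pathAvg)
  }
  mig
}

#' Per-band contribution scores from a MIG array
#'
#' CNN (3-D MIG): the score of band \eqn{\lambda_c} is the absolute value of
#' the spatial mean of the MIG over the width and length axes — the absolute
#' of the mean, so spatially cancelling attributions score zero. FNN (1-D
#' MIG): the absolute MIG.
#'
#' @param mig MIG vector (FNN) or (H, W, C) array (CNN) from
#'   \code{\link{integratedGradients}}.
#' @return nonnegative numeric vector, one score per band.
#' @export
scoreBands <- function(mig) {
  if (is.null(dim(mig)) || length(dim(mig)) == 1L) return(abs(as.numeric(mig)))
  if (length(dim(mig)) != 3L)
    stop("mig must be a 1-D vector or a 3-D (H, W, bands) array")
  abs(apply(mig, 3L, mean))
}

#' Greedy signature-band selection under a minimum-spacing rule
#'
#' Repeatedly selects the unselected band with the highest score whose
#' center lies at least \code{exclusionRadius} nm from every
#' already-selected center (spacing of exactly the radius is admissible),
#' until \code{nBands} centers are chosen. Score ties break toward the lower
#' wavelength.
#'
#' @param score nonnegative score per grid center.
#' @param grid the \linkS4class{BandGrid} the scores live on.
#' @param nBands number of signature bands to select (default 6).
#' @param exclusionRadius minimum pairwise spacing in nm (default 20).
#' @param positiveOnly if \code{TRUE}, only bands with positive signed
#'   attribution are admissible (requires \code{migs}).
#' @param migs optional signed per-band attributions recorded on the result.
#' @param family,range,igMode,seed provenance recorded on the result.
#' @return a \linkS4class{SignatureSet}.
#' @export
selectSignatureBands <- function(score, grid, nBands = 6L,
                                 exclusionRadius = 20,
                                 positiveOnly = FALSE, migs = NULL,
                                 family = "unknown", range = "unknown",
                                 igMode = "literal", seed = NA_integer_) {
  centers <- grid@centers
  if (length(score) != length(centers))
    stop("one score per grid center required")
  admissibleBase <- rep(TRUE, length(score))
  if (positiveOnly) {
    if (is.null(migs)) stop("positiveOnly selection needs signed migs")
    admissibleBase <- migs > 0
  }
  # stable order: score descending, wavelength ascending on ties
  ord <- order(-score, centers)
  selected <- integer(0)
  for (i in ord) {
    if (!admissibleBase[i]) next
    if (length(selected) &&
        any(abs(centers[selected] - centers[i]) < exclusionRadius - 1e-9))
      next
    selected <- c(selected, i)
    if (length(selected) == nBands) break
  }
  if (length(selected) < nBands)
    stop(sprintf(
      "only %d admissible bands found under the %g nm exclusion rule (%d requested)",
      length(selected), exclusionRadius, nBands))
  selected <- sort(selected)
  new("SignatureSet", centers = centers[selected],
      scores = score[selected],
      migs = if (is.null(migs)) rep(NA_real_, nBands) else migs[selected],
      family = family, range = range,
      halfBandwidth = grid@halfBandwidth,
      exclusionRadius = exclusionRadius, igMode = igMode,
      seed = as.integer(seed))
}

#' Score the bands of a trained model and select its signature set
#'
#' Convenience wrapper: integrated gradients on the supplied samples,
#' band scores, then greedy selection on the sample set's grid.
#'
#' @param model a trained \code{sbModel}.
#' @param data a \linkS4class{SampleSet} (typically the training samples).
#' @param nBands,exclusionRadius,M,mode,baseline see
#'   \code{\link{selectSignatureBands}} and
#'   \code{\link{integratedGradients}}.
#' @param range,seed provenance recorded on the result.
#' @return a \linkS4class{SignatureSet}.
#' @export
extractSignatureBands <- function(model, data, nBands = 6L,
                                  exclusionRadius = 20, M = 50L,
                                  mode = "literal", baseline = NULL,
                                  range = "unknown", seed = NA_integer_) {
  mig <- integratedGradients(model, data, baseline = baseline, M = M,
                             mode = mode)
  sc <- scoreBands(mig)
  bandMig <- if (is.null(dim(mig))) as.numeric(mig) else apply(mig, 3L, mean)
  selectSignatureBands(sc, data@grid, nBands = nBands,
                       exclusionRadius = exclusionRadius, migs = bandMig,
                       family = model$spec$family, range = range,
                       igMode = mode, seed = seed)
}

#' Serialize a signature set to JSON
#'
#' @param x a \linkS4class{SignatureSet}.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeSignatureSet <- function(x, path) {
  jsonlite::write_json(list(
    centers_nm = x@centers, scores = x@scores, mig = x@migs,
    model_family = x@family, range = x@range,
    half_bandwidth_nm = x@halfBandwidth, exclusion_nm = x@exclusionRadius,
    ig_mode = x@igMode, seed = x@seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-band score table
#'
#' @param grid a \linkS4class{BandGrid}.
#' @param mig signed per-band attribution.
#' @param score nonnegative per-band score.
#' @return data.frame with center_nm, mig, score (for bar-plot style
#'   export).
#' @export
bandScoreTable <- function(grid, mig, score) {
  data.frame(center_nm = grid@centers, mig = mig, score = score)
}

#' Bar plot of per-band attribution scores
#'
#' Positive signed attributions are drawn in blue, negative in red; selected
#' signature bands (if given) are shaded.
#'
#' @param grid a \linkS4class{BandGrid}.
#' @param mig signed per-band attributions.
#' @param signature optional \linkS4class{SignatureSet} to highlight.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @return invisibly, the bar midpoints.
#' @export
plotBandScores <- function(grid, mig, signature = NULL, ...) {
  score <- abs(mig)
  col <- ifelse(mig >= 0, "steelblue", "firebrick")
  dens <- rep(NA_real_, length(score))
  if (!is.null(signature))
    dens[grid@centers %in% signature@centers] <- 20
  mid <- graphics::barplot(score, names.arg = grid@centers, col = col,
                           density = dens, border = col,
                           xlab = "center wavelength (nm)",
                           ylab = "|MIG| score", ...)
  invisible(mid)
}
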