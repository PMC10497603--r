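#' @import methods
NULL

#' Raw instrument frames prior to reflectance calibration
#'
#' Holds one acquisition's sample, dark-current and white-reference frames on
#' a shared spatial/spectral geometry, in raw detector counts. The three
#' arrays must agree in all dimensions and the wavelength axis must be
#' strictly increasing.
#'
#' @slot sample,dark,white numeric arrays of dimension width x length x bands
#'   (detector counts).
#' @slot wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length equal to the third array dimension.
#' @exportClass RawFrames
setClass("RawFrames",
  representation(
    sample = "array",
    dark = "array",
    white = "array",
    wavelengths = "numeric"
  )
)

setValidity("RawFrames", function(object) {
  msgs <- character()
  ds <- dim(object@sample); dd <- dim(object@dark); dw <- dim(object@white)
  if (length(ds) != 3L) msgs <- c(msgs, "sample frame must be a 3-D array")
  if (!identical(ds, dd)) {
    ax <- which(ds != dd)[1L]
    msgs <- c(msgs, sprintf("dark frame disagrees with sample frame on axis %d", ax))
  }
  if (!identical(ds, dw)) {
    ax <- which(ds != dw)[1L]
    msgs <- c(msgs, sprintf("white frame disagrees with sample frame on axis %d", ax))
  }
  if (length(object@wavelengths) != ds[3L])
    msgs <- c(msgs, "wavelength axis length must equal the number of bands")
  if (is.unsorted(object@wavelengths, strictly = TRUE))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Calibrated reflectance hypercube
#'
#' A width x length x bands array of dimensionless reflectance with its
#' wavelength axis. Pixels whose white and dark references coincide (within
#' the calibration tolerance) carry no usable reflectance; they are recorded
#' in a spatial validity mask rather than as NaN, and all downstream spatial
#' statistics ignore them.
#'
#' @slot reflectance numeric array, width x length x bands.
#' @slot wavelengths numeric, band centers in nm, strictly increasing.
#' @slot smoothed logical; \code{TRUE} once Savitzky-Golay denoised.
#' @slot mask logical matrix width x length; \code{TRUE} marks valid pixels.
#' @exportClass HyperCube
setClass("HyperCube",
  representation(
    reflectance = "array",
    wavelengths = "numeric",
    smoothed = "logical",
    mask = "matrix"
  )
)

setValidity("HyperCube", function(object) {
  msgs <- character()
  d <- dim(object@reflectance)
  if (length(d) != 3L) msgs <- c(msgs, "reflectance must be a 3-D array")
  if (length(object@wavelengths) != d[3L])
    msgs <- c(msgs, "wavelength axis length must equal the number of bands")
  if (is.unsorted(object@wavelengths, strictly = TRUE))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (!identical(dim(object@mask), d[1:2]))
    msgs <- c(msgs, "mask must match the spatial dimensions")
  if (any(object@mask) &&
      !all(is.finite(object@reflectance[rep(object@mask, d[3L])])))
    msgs <- c(msgs, "reflectance must be finite on unmasked pixels")
  if (length(msgs)) msgs else TRUE
})

#' Center-wavelength grid for multispectral resampling
#'
#' Centers are laid out from \code{rangeMin + w/2} in steps of the full
#' bandwidth \code{w = 2 * halfBandwidth}, keeping every center that lies
#' within the range ("inset" mode, the default). "edge" mode anchors centers
#' at both range limits with step \code{w} instead.
#'
#' @slot rangeMin,rangeMax numeric, spectral range limits in nm.
#' @slot halfBandwidth numeric, half bandwidth w/2 in nm.
#' @slot centers numeric, ascending center wavelengths in nm.
#' @slot mode character, "inset", "edge" or "custom" (non-uniform centers).
#' @exportClass BandGrid
setClass("BandGrid",
  representation(
    rangeMin = "numeric",
    rangeMax = "numeric",
    halfBandwidth = "numeric",
    centers = "numeric",
    mode = "character"
  )
)

setValidity("BandGrid", function(object) {
  msgs <- character()
  w <- 2 * object@halfBandwidth
  ctr <- object@centers
  if (object@halfBandwidth <= 0) msgs <- c(msgs, "halfBandwidth must be positive")
  if (!object@mode %in% c("inset", "edge", "custom"))
    msgs <- c(msgs, "mode must be 'inset', 'edge' or 'custom'")
  if (length(ctr)) {
    if (is.unsorted(ctr, strictly = TRUE))
      msgs <- c(msgs, "centers must be strictly increasing")
    if (object@mode != "custom" && length(ctr) > 1L &&
        any(abs(diff(ctr) - w) > 1e-9))
      msgs <- c(msgs, "consecutive centers must differ by the full bandwidth")
    if (object@mode == "inset") {
      if (ctr[1L] - w / 2 < object@rangeMin - 1e-9)
        msgs <- c(msgs, "first band window extends below rangeMin")
      if (ctr[length(ctr)] > object@rangeMax + 1e-9)
        msgs <- c(msgs, "last center exceeds rangeMax")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Multispectral cube of boxcar-resampled band values
#'
#' @slot values numeric array, width x length x n-bands.
#' @slot grid the \linkS4class{BandGrid} the cube was resampled onto.
#' @slot mask logical matrix of valid pixels (inherited from the source cube).
#' @slot provenance character id of the source hypercube.
#' @exportClass MultiCube
setClass("MultiCube",
  representation(
    values = "array",
    grid = "BandGrid",
    mask = "matrix",
    provenance = "character"
  )
)

setValidity("MultiCube", function(object) {
  msgs <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msgs <- c(msgs, "values must be a 3-D array")
  if (d[3L] != length(object@grid@centers))
    msgs <- c(msgs, "third dimension must equal the number of grid centers")
  if (!identical(dim(object@mask), d[1:2]))
    msgs <- c(msgs, "mask must match the spatial dimensions")
  if (any(object@mask) &&
      !all(is.finite(object@values[rep(object@mask, max(d[3L], 1L))])))
    msgs <- c(msgs, "band values must be finite on unmasked pixels")
  if (length(msgs)) msgs else TRUE
})

#' Model-ready set of labeled samples
#'
#' Stacks one resampled region-of-interest cube per sample together with its
#' spatial-mean spectrum (the feedforward-network input), the Brix label and
#' the Brix group id.
#'
#' @slot cubes numeric array width x length x bands x samples.
#' @slot spectra numeric matrix samples x bands, the per-band spatial means.
#' @slot brix numeric Brix labels, one per sample.
#' @slot group integer Brix group ids (1-5).
#' @slot sampleId character sample identifiers.
#' @slot grid the \linkS4class{BandGrid} shared by all cubes.
#' @exportClass SampleSet
setClass("SampleSet",
  representation(
    cubes = "array",
    spectra = "matrix",
    brix = "numeric",
    group = "integer",
    sampleId = "character",
    grid = "BandGrid"
  )
)

setValidity("SampleSet", function(object) {
  msgs <- character()
  d <- dim(object@cubes)
  n <- d[4L]
  if (length(d) != 4L) msgs <- c(msgs, "cubes must be a 4-D array")
  if (!identical(dim(object@spectra), c(n, d[3L])))
    msgs <- c(msgs, "spectra must be samples x bands")
  if (length(object@brix) != n || length(object@group) != n ||
      length(object@sampleId) != n)
    msgs <- c(msgs, "label vectors must have one entry per sample")
  if (any(!is.finite(object@brix)) || any(object@brix <= 0))
    msgs <- c(msgs, "brix labels must be finite and positive")
  if (length(msgs)) msgs else TRUE
})

#' Stratified train/validation/test partition
#'
#' @slot trainIds,validIds,testIds character, pairwise-disjoint sample ids.
#' @slot ratios numeric length 3, the requested proportions (sum 1).
#' @slot seed integer seed that produced the shuffle.
#' @exportClass DatasetSplit
setClass("DatasetSplit",
  representation(
    trainIds = "character",
    validIds = "character",
    testIds = "character",
    ratios = "numeric",
    seed = "integer"
  )
)

setValidity("DatasetSplit", function(object) {
  msgs <- character()
  all_ids <- c(object@trainIds, object@validIds, object@testIds)
  if (anyDuplicated(all_ids))
    msgs <- c(msgs, "train/valid/test id sets must be pairwise disjoint")
  if (length(object@ratios) != 3L || abs(sum(object@ratios) - 1) > 1e-9)
    msgs <- c(msgs, "ratios must be three proportions summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' Selected signature bands with provenance
#'
#' The result of greedy score-ranked selection under the minimum-spacing
#' rule: every pair of selected centers differs by at least
#' \code{exclusionRadius} nm (boundary equality allowed).
#'
#' @slot centers numeric, selected center wavelengths in nm.
#' @slot scores numeric, the attribution scores at selection time.
#' @slot migs numeric, the signed band attributions at selection time.
#' @slot family character, model family the scores came from.
#' @slot range character, spectral-range label.
#' @slot halfBandwidth numeric, the grid's half bandwidth in nm.
#' @slot exclusionRadius numeric, minimum pairwise spacing in nm.
#' @slot igMode character, "literal" or "full_ig".
#' @slot seed integer, training seed of the source model.
#' @exportClass SignatureSet
setClass("SignatureSet",
  representation(
    centers = "numeric",
    scores = "numeric",
    migs = "numeric",
    family = "character",
    range = "character",
    halfBandwidth = "numeric",
    exclusionRadius = "numeric",
    igMode = "character",
    seed = "integer"
  )
)

setValidity("SignatureSet", function(object) {
  msgs <- character()
  ctr <- object@centers
  if (length(ctr) != length(object@scores))
    msgs <- c(msgs, "centers and scores must have equal length")
  if (length(ctr) > 1L) {
    gaps <- abs(outer(ctr, ctr, "-"))
    gaps <- gaps[upper.tri(gaps)]
    if (any(gaps < object@exclusionRadius - 1e-9))
      msgs <- c(msgs, sprintf(
        "selected centers closer than the %g nm exclusion radius",
        object@exclusionRadius))
  }
  if (any(object@scores < 0)) msgs <- c(msgs, "scores must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Grid of prediction errors with row and column averages
#'
#' Mirrors the layout of the published results tables: one MAE/R-squared cell
#' per (model family, spectral range, bandwidth), plus the arithmetic mean of
#' the MAE cells in each (family, range) row and each bandwidth column.
#'
#' @slot cells data.frame with columns family, range, halfBandwidth, mae, r2.
#' @slot rowAverages data.frame with columns family, range, mae.
#' @slot colAverages data.frame with columns halfBandwidth, mae.
#' @exportClass MaeTable
setClass("MaeTable",
  representation(
    cells = "data.frame",
    rowAverages = "data.frame",
    colAverages = "data.frame"
  )
)
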