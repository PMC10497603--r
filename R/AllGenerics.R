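#' Wavelength axis of a spectral object
#'
#' @param x a \linkS4class{RawFrames} or \linkS4class{HyperCube}.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Reflectance array of a cube
#'
#' @param x a \linkS4class{HyperCube} or \linkS4class{MultiCube}.
#' @return numeric 3-D array (width x length x bands).
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' Band-center wavelengths of a grid-bearing object
#'
#' @param x a \linkS4class{BandGrid}, \linkS4class{MultiCube},
#'   \linkS4class{SampleSet} or \linkS4class{SignatureSet}.
#' @return numeric vector of center wavelengths in nm.
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' Number of spectral bands
#'
#' @param x a spectral object.
#' @return integer band count.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Valid-pixel mask
#'
#' @param x a \linkS4class{HyperCube} or \linkS4class{MultiCube}.
#' @return logical matrix, \code{TRUE} at valid pixels.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Has the cube been Savitzky-Golay smoothed?
#'
#' @param x a \linkS4class{HyperCube}.
#' @return logical flag.
#' @export
setGeneric("isSmoothed", function(x) standardGeneric("isSmoothed"))

#' Brix labels of a sample set
#'
#' @param x a \linkS4class{SampleSet}.
#' @return numeric vector of Brix values.
#' @export
setGeneric("brix", function(x) standardGeneric("brix"))

#' Restrict an object to a named spectral range
#'
#' @param x a \linkS4class{BandGrid} or \linkS4class{MultiCube}.
#' @param range one of \code{"VIS"} (400-700 nm), \code{"VISNIR"}
#'   (400-1000 nm), \code{"SWIR"} (900-1700 nm), \code{"VISWIR"}
#'   (400-1700 nm).
#' @return an object of the same class on the restricted range.
#' @export
setGeneric("subsetRange", function(x, range) standardGeneric("subsetRange"))

setMethod("wavelengths", "RawFrames", function(x) x@wavelengths)
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

setMethod("reflectance", "HyperCube", function(x) x@reflectance)
setMethod("reflectance", "MultiCube", function(x) x@values)

setMethod("bandCenters", "BandGrid", function(x) x@centers)
setMethod("bandCenters", "MultiCube", function(x) x@grid@centers)
setMethod("bandCenters", "SampleSet", function(x) x@grid@centers)
setMethod("bandCenters", "SignatureSet", function(x) x@centers)

setMethod("nBands", "HyperCube", function(x) length(x@wavelengths))
setMethod("nBands", "BandGrid", function(x) length(x@centers))
setMethod("nBands", "MultiCube", function(x) length(x@grid@centers))
setMethod("nBands", "SampleSet", function(x) length(x@grid@centers))

setMethod("validMask", "HyperCube", function(x) x@mask)
setMethod("validMask", "MultiCube", function(x) x@mask)

setMethod("isSmoothed", "HyperCube", function(x) x@smoothed)

setMethod("brix", "SampleSet", function(x) x@brix)

#' @describeIn SampleSet number of samples
#' @param x a SampleSet
#' @export
setMethod("length", "SampleSet", function(x) dim(x@cubes)[4L])

setMethod("show", "RawFrames", function(object) {
  d <- dim(object@sample)
  cat(sprintf("RawFrames: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@reflectance)
  cat(sprintf(
    "HyperCube: %d x %d pixels, %d bands (%.1f-%.1f nm), %s, %d/%d valid pixels\n",
    d[1], d[2], d[3], min(object@wavelengths), max(object@wavelengths),
    if (object@smoothed) "smoothed" else "unsmoothed",
    sum(object@mask), length(object@mask)))
})

setMethod("show", "BandGrid", function(object) {
  cat(sprintf(
    "BandGrid: %d centers, %.1f-%.1f nm, half-bandwidth +/-%.1f nm (%s mode)\n",
    length(object@centers), object@rangeMin, object@rangeMax,
    object@halfBandwidth, object@mode))
})

setMethod("show", "MultiCube", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "MultiCube: %d x %d pixels, %d bands, +/-%.1f nm, source '%s'\n",
    d[1], d[2], d[3], object@grid@halfBandwidth, object@provenance))
})

setMethod("show", "SampleSet", function(object) {
  d <- dim(object@cubes)
  cat(sprintf(
    "SampleSet: %d samples of %d x %d x %d, Brix %.2f-%.2f, groups %s\n",
    d[4], d[1], d[2], d[3], min(object@brix), max(object@brix),
    paste(sort(unique(object@group)), collapse = ",")))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d valid / %d test (seed %d)\n",
              length(object@trainIds), length(object@validIds),
              length(object@testIds), object@seed))
})

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf(
    "SignatureSet (%s, %s, +/-%.1f nm, %s IG): %s nm\n",
    object@family, object@range, object@halfBandwidth, object@igMode,
    paste(format(object@centers), collapse = ", ")))
})

setMethod("show", "MaeTable", function(object) {
  cat("MaeTable\n")
  cells <- object@cells
  cells$mae <- round(cells$mae, 3)
  cells$r2 <- round(cells$r2, 3)
  print(cells, row.names = FALSE)
  if (nrow(object@rowAverages)) {
    cat("Row MAE averages:\n")
    ra <- object@rowAverages; ra$mae <- round(ra$mae, 3)
    print(ra, row.names = FALSE)
  }
  if (nrow(object@colAverages)) {
    cat("Column MAE averages:\n")
    ca <- object@colAverages; ca$mae <- round(ca$mae, 3)
    print(ca, row.names = FALSE)
  }
})
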