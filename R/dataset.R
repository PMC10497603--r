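#' Extract a square region of interest centered on the valid pixels
#'
#' Crops a \code{roiSize} x \code{roiSize} spatial window centered on the
#' centroid of the valid-pixel mask (clipped so the window stays inside the
#' image). One cropped cube per fruit slice is the unit sample of the whole
#' pipeline.
#'
#' @param cube a \linkS4class{HyperCube} or \linkS4class{MultiCube}.
#' @param roiSize side of the square crop in pixels (default 20).
#' @return an object of the same class, cropped to roiSize x roiSize.
#' @export
extractROI <- function(cube, roiSize = 20L) {
  isMulti <- is(cube, "MultiCube")
  x <- if (isMulti) cube@values else cube@reflectance
  mask <- cube@mask
  d <- dim(x)
  if (d[1L] < roiSize || d[2L] < roiSize)
    stop(sprintf("image %d x %d smaller than the %d-pixel ROI",
                 d[1L], d[2L], roiSize))
  if (!any(mask)) stop("no valid pixels to center the ROI on")
  idx <- which(mask, arr.ind = TRUE)
  ci <- round(mean(idx[, 1L]))
  cj <- round(mean(idx[, 2L]))
  half <- roiSize %/% 2L
  i0 <- min(max(ci - half + 1L, 1L), d[1L] - roiSize + 1L)
  j0 <- min(max(cj - half + 1L, 1L), d[2L] - roiSize + 1L)
  rows <- i0:(i0 + roiSize - 1L)
  cols <- j0:(j0 + roiSize - 1L)
  sub <- x[rows, cols, , drop = FALSE]
  subMask <- mask[rows, cols, drop = FALSE]
  if (isMulti) {
    new("MultiCube", values = sub, grid = cube@grid, mask = subMask,
        provenance = cube@provenance)
  } else {
    HyperCube(sub, cube@wavelengths, smoothed = cube@smoothed, mask = subMask)
  }
}

#' Spatial-mean spectrum of a cube
#'
#' Per-band mean over the valid pixels only; the feedforward-network input.
#'
#' @param cube a \linkS4class{HyperCube} or \linkS4class{MultiCube}.
#' @return numeric vector, one value per band.
#' @export
toMeanSpectrum <- function(cube) {
  x <- if (is(cube, "MultiCube")) cube@values else cube@reflectance
  mask <- cube@mask
  if (!any(mask)) stop("all pixels are flagged invalid; no spectrum to average")
  d <- dim(x)
  m <- matrix(x, nrow = d[1L] * d[2L], ncol = d[3L])
  colMeans(m[as.vector(mask), , drop = FALSE])
}

#' Map a Brix value to its group
#'
#' Five half-open intervals: group 1 below 10, then [10, 11), [11, 12),
#' [12, 13), and group 5 at 13 and above, so every label maps to exactly one
#' group.
#'
#' @param y numeric Brix value(s), finite and positive.
#' @return integer group id(s) in 1..5.
#' @examples
#' assignBrixGroup(c(8.65, 10.44, 10.0, 13))  # 1 2 2 5
#' @export
assignBrixGroup <- function(y) {
  if (any(!is.finite(y))) stop("Brix values must be finite")
  if (any(y <= 0)) stop("Brix values must be positive")
  g <- findInterval(y, c(10, 11, 12, 13)) + 1L
  as.integer(g)
}

#' Stratified train/validation/test split
#'
#' Within each group of size n the test set gets \code{floor(r_test * n)}
#' samples, the validation set \code{ceiling(r_valid * n)}, and the training
#' set the remainder (218 -> 131/44/43 at the default 0.6/0.2/0.2 ratios).
#' Assignment is by a seeded shuffle; group splits are concatenated.
#'
#' @param sampleIds character (or coercible) sample identifiers.
#' @param groups group id per sample; a single-group vector is fine.
#' @param ratios train/valid/test proportions summing to 1.
#' @param seed integer RNG seed for the shuffles.
#' @return a \linkS4class{DatasetSplit}.
#' @export
splitDataset <- function(sampleIds, groups = rep(1L, length(sampleIds)),
                         ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  if (length(groups) != length(sampleIds))
    stop("one group id per sample id required")
  sampleIds <- as.character(sampleIds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tr <- va <- te <- character()
  for (g in sort(unique(groups))) {
    ids <- sampleIds[groups == g]
    n <- length(ids)
    if (n == 0L) {
      warning("group ", g, " is empty; skipped")
      next
    }
    nTest <- floor(ratios[3L] * n)
    nValid <- ceiling(ratios[2L] * n)
    nTrain <- n - nValid - nTest
    ids <- sample(ids)
    tr <- c(tr, ids[seq_len(nTrain)])
    va <- c(va, ids[nTrain + seq_len(nValid)])
    te <- c(te, ids[nTrain + nValid + seq_len(nTest)])
  }
  new("DatasetSplit", trainIds = tr, validIds = va, testIds = te,
      ratios = as.numeric(ratios), seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Stack labeled multispectral ROI cubes into a SampleSet
#'
#' @param cubes list of \linkS4class{MultiCube}s with identical grids and
#'   spatial dimensions.
#' @param brix numeric Brix label per cube.
#' @param sampleId optional sample ids (defaults to s1, s2, ...).
#' @return a \linkS4class{SampleSet}; group ids are derived from the labels
#'   via \code{\link{assignBrixGroup}}.
#' @export
makeSampleSet <- function(cubes, brix, sampleId = NULL) {
  n <- length(cubes)
  stopifnot(n >= 1L, length(brix) == n)
  if (is.null(sampleId)) sampleId <- paste0("s", seq_len(n))
  d <- dim(cubes[[1L]]@values)
  arr <- array(0, c(d, n))
  spectra <- matrix(0, n, d[3L])
  for (i in seq_len(n)) {
    if (!identical(dim(cubes[[i]]@values), d))
      stop("cube ", i, " differs in shape from cube 1")
    arr[, , , i] <- cubes[[i]]@values
    spectra[i, ] <- toMeanSpectrum(cubes[[i]])
  }
  new("SampleSet", cubes = arr, spectra = spectra, brix = as.numeric(brix),
      group = assignBrixGroup(brix), sampleId = as.character(sampleId),
      grid = cubes[[1L]]@grid)
}

#' Subset a SampleSet by sample id
#'
#' @param x a \linkS4class{SampleSet}.
#' @param ids sample ids to keep, in the order given.
#' @return the subset \linkS4class{SampleSet}.
#' @export
subsetSamples <- function(x, ids) {
  pos <- match(ids, x@sampleId)
  if (any(is.na(pos))) stop("unknown sample ids: ",
                            paste(ids[is.na(pos)], collapse = ", "))
  new("SampleSet", cubes = x@cubes[, , , pos, drop = FALSE],
      spectra = x@spectra[pos, , drop = FALSE], brix = x@brix[pos],
      group = x@group[pos], sampleId = x@sampleId[pos], grid = x@grid)
}

#' Write / read a split as JSON
#'
#' @param split a \linkS4class{DatasetSplit}.
#' @param path JSON file path.
#' @return \code{readSplit}: a \linkS4class{DatasetSplit}.
#' @export
writeSplit <- function(split, path) {
  jsonlite::write_json(list(
    seed = split@seed, ratios = split@ratios,
    train = split@trainIds, valid = split@validIds, test = split@testIds
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DatasetSplit", trainIds = as.character(x$train),
      validIds = as.character(x$valid), testIds = as.character(x$test),
      ratios = as.numeric(x$ratios), seed = as.integer(x$seed))
}

#' Read a labels table
#'
#' CSV with columns \code{sample_id}, \code{brix} and optionally
#' \code{group}; the group is derived from the Brix value when absent.
#'
#' @param path CSV path.
#' @return data.frame with sample_id, brix, group.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "brix") %in% names(df)))
    stop("labels CSV needs columns sample_id and brix")
  if (is.null(df$group)) df$group <- assignBrixGroup(df$brix)
  df[, c("sample_id", "brix", "group")]
}
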