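#' Named spectral ranges
#'
#' VIS 400-700 nm, VISNIR 400-1000 nm, SWIR 900-1700 nm, VISWIR 400-1700 nm.
#'
#' @param range range label.
#' @return numeric length-2 vector (min, max) in nm.
#' @export
spectralRange <- function(range = c("VISWIR", "VISNIR", "VIS", "SWIR")) {
  if (length(range) == 1L && !range %in% c("VISWIR", "VISNIR", "VIS", "SWIR"))
    stop("unknown spectral range label: ", range)
  range <- match.arg(range)
  switch(range,
    VIS = c(400, 700),
    VISNIR = c(400, 1000),
    SWIR = c(900, 1700),
    VISWIR = c(400, 1700)
  )
}

#' Build a center-wavelength grid
#'
#' In the default \code{"inset"} mode the first center sits half a bandwidth
#' inside the lower range limit and subsequent centers step by the full
#' bandwidth \code{w = 2 * halfBandwidth}; every center whose wavelength lies
#' within the range is kept, so the count is
#' \code{floor((span - w/2) / w) + 1}. In \code{"edge"} mode centers are
#' anchored at both range limits with step \code{w} (count
#' \code{span/w + 1}), the layout that very narrow bandwidths follow.
#'
#' @param rangeMin,rangeMax spectral range limits in nm.
#' @param halfBandwidth half bandwidth w/2 in nm (e.g. 10 for a +/-10 nm,
#'   20 nm wide band).
#' @param mode "inset" (default) or "edge".
#' @return a \linkS4class{BandGrid}.
#' @examples
#' nBands(makeBandGrid(400, 1700, 10))   # 65
#' @export
makeBandGrid <- function(rangeMin, rangeMax, halfBandwidth,
                         mode = c("inset", "edge")) {
  mode <- match.arg(mode)
  w <- 2 * halfBandwidth
  if (rangeMax - rangeMin < w)
    stop(sprintf("range [%g, %g] narrower than one %g nm band",
                 rangeMin, rangeMax, w))
  centers <- if (mode == "inset") {
    k <- floor(((rangeMax - rangeMin) - halfBandwidth) / w + 1e-9)
    rangeMin + halfBandwidth + w * (0:k)
  } else {
    k <- floor((rangeMax - rangeMin) / w + 1e-9)
    rangeMin + w * (0:k)
  }
  new("BandGrid", rangeMin = as.numeric(rangeMin),
      rangeMax = as.numeric(rangeMax),
      halfBandwidth = as.numeric(halfBandwidth),
      centers = as.numeric(centers), mode = mode)
}

#' Grid for a named spectral range
#'
#' @param range range label, see \code{\link{spectralRange}}.
#' @param halfBandwidth half bandwidth in nm.
#' @param mode grid mode, see \code{\link{makeBandGrid}}.
#' @return a \linkS4class{BandGrid}.
#' @export
makeRangeGrid <- function(range, halfBandwidth, mode = "inset") {
  lim <- spectralRange(range)
  makeBandGrid(lim[1L], lim[2L], halfBandwidth, mode)
}

#' Resample a hypercube onto a band grid
#'
#' For each pixel and band window \code{[center - w/2, center + w/2]} the
#' band value is the integrated reflectance over the window divided by the
#' sampled span:
#' \deqn{R_M = \frac{1}{\lambda_b - \lambda_a} \sum_{i=a}^{b-1}
#'       \frac{R(\lambda_i) + R(\lambda_{i+1})}{2}
#'       (\lambda_{i+1}-\lambda_i)}
#' where \eqn{\lambda_a} and \eqn{\lambda_b} are the first and last cube
#' wavelengths inside the window (trapezoid rule over the intra-window
#' intervals). Constant spectra resample to themselves exactly and the
#' result agrees with the continuous window mean at second order in the
#' sampling step.
#'
#' @param cube a \linkS4class{HyperCube}.
#' @param grid a \linkS4class{BandGrid}; every window must contain at least
#'   two cube samples.
#' @param provenance character id recorded on the result.
#' @return a \linkS4class{MultiCube}.
#' @export
resampleToBands <- function(cube, grid, provenance = "cube") {
  stopifnot(is(cube, "HyperCube"), is(grid, "BandGrid"))
  wl <- cube@wavelengths
  d <- dim(cube@reflectance)
  x <- matrix(cube@reflectance, nrow = d[1L] * d[2L], ncol = d[3L])
  wt <- bandWeights(wl, grid)
  vals <- x %*% wt
  new("MultiCube", values = array(vals, c(d[1L], d[2L], nBands(grid))),
      grid = grid, mask = cube@mask, provenance = provenance)
}

#' Resample spectra held as matrix rows
#'
#' Same boxcar integration as \code{\link{resampleToBands}} but for 1-D
#' spectra (one per row), used on spatial-mean spectra where it commutes
#' exactly with the cube version.
#'
#' @param x numeric matrix, spectra in rows.
#' @param wl wavelength axis of the columns, nm.
#' @param grid a \linkS4class{BandGrid}.
#' @return matrix with one column per grid center.
#' @export
resampleRows <- function(x, wl, grid) {
  x %*% bandWeights(wl, grid)
}

# Weight matrix (n wavelengths x n bands) implementing the windowed
# trapezoid mean; shared by cube and row resampling. Each intra-window
# interval contributes half its width to both endpoints, so constants are
# preserved exactly and smooth spectra integrate at second order.
bandWeights <- function(wl, grid) {
  nb <- length(wl)
  centers <- grid@centers
  w2 <- grid@halfBandwidth
  wt <- matrix(0, nb, length(centers))
  for (j in seq_along(centers)) {
    lo <- centers[j] - w2
    hi <- centers[j] + w2
    idx <- which(wl >= lo - 1e-9 & wl <= hi + 1e-9)
    if (length(idx) == 0L)
      stop(sprintf("band at %g nm: no cube samples inside [%g, %g] nm",
                   centers[j], lo, hi))
    if (length(idx) == 1L)
      stop(sprintf("band at %g nm: only one cube sample inside the window",
                   centers[j]))
    a <- idx[1L]; b <- idx[length(idx)]
    dl <- diff(wl[a:b])                      # lambda_{i+1} - lambda_i
    wt[a:(b - 1L), j] <- wt[a:(b - 1L), j] + dl / 2
    wt[(a + 1L):b, j] <- wt[(a + 1L):b, j] + dl / 2
    wt[, j] <- wt[, j] / (wl[b] - wl[a])
  }
  wt
}

#' @describeIn subsetRange the grid is re-generated for the target range (the
#'   only convention whose band counts match across ranges); the original
#'   mode and bandwidth are kept.
#' @export
setMethod("subsetRange", "BandGrid", function(x, range) {
  lim <- spectralRange(range)
  makeBandGrid(lim[1L], lim[2L], x@halfBandwidth, x@mode)
})

#' @describeIn subsetRange only filtering is possible without the source
#'   spectra: bands whose full window lies inside the target range are kept.
#'   If the filtered centers differ from the re-generated grid for that
#'   range, a warning advises re-resampling from the hypercube.
#' @export
setMethod("subsetRange", "MultiCube", function(x, range) {
  lim <- spectralRange(range)
  ctr <- x@grid@centers
  w2 <- x@grid@halfBandwidth
  keep <- ctr - w2 >= lim[1L] - 1e-9 & ctr + w2 <= lim[2L] + 1e-9
  if (!any(keep)) stop("no bands lie inside the ", range, " range")
  sub <- new("BandGrid", rangeMin = lim[1L], rangeMax = lim[2L],
             halfBandwidth = w2, centers = ctr[keep], mode = x@grid@mode)
  regen <- makeBandGrid(lim[1L], lim[2L], w2, x@grid@mode)
  if (!isTRUE(all.equal(sub@centers, regen@centers)))
    warning("filtered centers differ from the re-generated ", range,
            " grid; re-resample the hypercube for an exact ", range, " cube")
  new("MultiCube", values = x@values[, , keep, drop = FALSE], grid = sub,
      mask = x@mask, provenance = x@provenance)
})
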