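#' Construct a RawFrames object
#'
#' @param sample,dark,white numeric arrays width x length x bands, raw counts.
#' @param wavelengths numeric band centers in nm, strictly increasing.
#' @return a \linkS4class{RawFrames}.
#' @export
RawFrames <- function(sample, dark, white, wavelengths) {
  new("RawFrames", sample = sample, dark = dark, white = white,
      wavelengths = as.numeric(wavelengths))
}

#' Construct a HyperCube
#'
#' @param reflectance numeric array width x length x bands.
#' @param wavelengths numeric band centers in nm.
#' @param smoothed logical, whether the cube has been denoised.
#' @param mask logical width x length validity mask; defaults to all valid.
#' @return a \linkS4class{HyperCube}.
#' @export
HyperCube <- function(reflectance, wavelengths, smoothed = FALSE,
                      mask = NULL) {
  d <- dim(reflectance)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  new("HyperCube", reflectance = reflectance,
      wavelengths = as.numeric(wavelengths),
      smoothed = smoothed, mask = mask)
}

#' Radiometric reflectance calibration
#'
#' Converts raw counts to reflectance against the dark-current and
#' white-reference frames:
#' \deqn{R = (I_S - I_D) / (I_w - I_D)}
#' elementwise. Pixels where the white and dark frames coincide to within
#' \code{eps} in any band carry no radiometric information; they are flagged
#' invalid in the returned cube's mask (their reflectance is set to 0, never
#' NaN) and all downstream spatial statistics skip them.
#'
#' @param raw a \linkS4class{RawFrames}.
#' @param eps positive tolerance on the white-minus-dark denominator.
#' @return an unsmoothed \linkS4class{HyperCube}.
#' @examples
#' wl <- seq(400, 410, by = 5)
#' a <- array(2, c(2, 2, 3)); d0 <- array(0, c(2, 2, 3))
#' calibrateReflectance(RawFrames(a, d0, a, wl))
#' @export
calibrateReflectance <- function(raw, eps = 1e-8) {
  stopifnot(is(raw, "RawFrames"))
  if (!(is.numeric(eps) && length(eps) == 1L && eps > 0))
    stop("'eps' must be a single positive number")
  denom <- raw@white - raw@dark
  bad <- abs(denom) <= eps
  r <- (raw@sample - raw@dark) / denom
  r[bad] <- 0
  d <- dim(r)
  # a pixel is invalid if ANY band's denominator degenerates
  mask <- !apply(bad, c(1L, 2L), any)
  if (!any(mask))
    stop("calibration failed: every pixel has a degenerate white-dark denominator")
  HyperCube(r, raw@wavelengths, smoothed = FALSE, mask = mask)
}

#' Savitzky-Golay convolution coefficients
#'
#' Central-point smoothing weights for a least-squares polynomial fit of
#' order \code{polyOrder} over an odd window of \code{windowLength} samples.
#' The weights sum to 1 for any valid configuration.
#'
#' @param windowLength odd integer >= 3.
#' @param polyOrder integer >= 0, strictly less than \code{windowLength}.
#' @return numeric vector of \code{windowLength} convolution weights.
#' @export
sgCoefficients <- function(windowLength = 11L, polyOrder = 2L) {
  if (windowLength < 3L || windowLength %% 2L == 0L)
    stop("'windowLength' must be an odd integer >= 3")
  if (polyOrder < 0L || polyOrder >= windowLength)
    stop("'polyOrder' must satisfy 0 <= polyOrder < windowLength")
  # central row of the SG projection matrix = smoothing weights
  f <- signal::sgolay(p = polyOrder, n = windowLength, m = 0)
  as.numeric(f[(windowLength + 1L) / 2L, ])
}

#' Savitzky-Golay spectral denoising
#'
#' Convolves every pixel's spectrum along the band axis with the
#' Savitzky-Golay least-squares smoothing weights. Edges are handled by
#' mirror-padding the spectrum by half a window on each side, so polynomials
#' up to the fit order are reproduced exactly in the interior and the output
#' length equals the input length.
#'
#' @param cube an unsmoothed \linkS4class{HyperCube}.
#' @param windowLength odd window width in samples (default 11).
#' @param polyOrder polynomial fit order (default 2).
#' @return the smoothed \linkS4class{HyperCube}.
#' @export
smoothSavitzkyGolay <- function(cube, windowLength = 11L, polyOrder = 2L) {
  stopifnot(is(cube, "HyperCube"))
  if (cube@smoothed) stop("cube is already smoothed")
  nb <- nBands(cube)
  if (nb < windowLength)
    stop(sprintf("window (%d) longer than the spectrum (%d bands)",
                 windowLength, nb))
  coef <- sgCoefficients(windowLength, polyOrder)
  d <- dim(cube@reflectance)
  # band axis last: flatten pixels to rows, smooth columnsets via matrix algebra
  x <- matrix(cube@reflectance, nrow = d[1L] * d[2L], ncol = nb)
  sm <- sgSmoothRows(x, coef)
  HyperCube(array(sm, d), cube@wavelengths, smoothed = TRUE, mask = cube@mask)
}

#' Savitzky-Golay smoothing of spectra held as matrix rows
#'
#' Workhorse behind \code{\link{smoothSavitzkyGolay}}, exposed for 1-D use on
#' mean spectra (spatial averaging and the band-axis convolution are both
#' linear, so they commute).
#'
#' @param x numeric matrix, one spectrum per row.
#' @param coef SG weights from \code{\link{sgCoefficients}}.
#' @return matrix of the same shape with each row smoothed.
#' @export
sgSmoothRows <- function(x, coef) {
  w <- length(coef)
  h <- (w - 1L) %/% 2L
  nb <- ncol(x)
  if (nb < w) stop("window longer than the spectrum")
  # mirror padding: reflect without repeating the edge sample
  padIdx <- c((h + 1L):2L, 1L:nb, (nb - 1L):(nb - h))
  xp <- x[, padIdx, drop = FALSE]
  out <- matrix(0, nrow(x), nb)
  for (k in seq_len(w)) {
    out <- out + coef[k] * xp[, k:(k + nb - 1L), drop = FALSE]
  }
  out
}
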