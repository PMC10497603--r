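#' Write a hypercube to an ENVI header + binary pair
#'
#' Values are stored as IEEE little-endian doubles (ENVI data type 5) so the
#' round trip is lossless; the wavelength axis goes into the header's
#' \code{wavelength} block in nm. The validity mask and the smoothed flag are
#' recorded in header comment-safe fields (\code{smoothed}, \code{mask}) so
#' \code{\link{readENVI}} restores the object exactly.
#'
#' @param cube a \linkS4class{HyperCube}.
#' @param path basename for the pair; writes \code{<path>.hdr} and
#'   \code{<path>.dat}.
#' @param interleave "bsq" (band-sequential) or "bil" (band-interleaved by
#'   line).
#' @return invisibly, the header path.
#' @export
writeENVI <- function(cube, path, interleave = c("bsq", "bil")) {
  stopifnot(is(cube, "HyperCube"))
  interleave <- match.arg(interleave)
  d <- dim(cube@reflectance)
  hdr <- paste0(path, ".hdr")
  dat <- paste0(path, ".dat")
  # ENVI axes: samples = columns (our length L), lines = rows (our width W)
  lines <- c(
    "ENVI",
    "description = {reflectance hypercube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("smoothed = %d", as.integer(cube@smoothed)),
    sprintf("mask = {%s}",
            paste(as.integer(cube@mask), collapse = ", ")),
    sprintf("wavelength = {%s}",
            paste(format(cube@wavelengths, digits = 15), collapse = ", "))
  )
  writeLines(lines, hdr)
  x <- cube@reflectance                       # dim (W, L, B), column-major
  vals <- switch(interleave,
    # BSQ: fastest samples (L), then lines (W), then bands
    bsq = as.numeric(aperm(x, c(2L, 1L, 3L))),
    # BIL: fastest samples (L), then bands, then lines (W)
    bil = as.numeric(aperm(x, c(2L, 3L, 1L)))
  )
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(hdr)
}

parseEnviHeader <- function(hdr) {
  raw <- readLines(hdr, warn = FALSE)
  if (!grepl("^ENVI", raw[1L])) stop("not an ENVI header: ", hdr)
  # fold multi-line { ... } blocks onto single lines, then split key = value
  lines <- character(0)
  buf <- ""
  for (ln in raw[-1L]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    nOpen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nClose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nOpen == nClose) {
      lines <- c(lines, buf)
      buf <- ""
    }
  }
  kv <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  keys <- vapply(kv, function(m) tolower(trimws(m[2L])), "")
  vals <- vapply(kv, function(m) trimws(m[3L]), "")
  getScalar <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) NA_character_ else vals[i]
  }
  getBlock <- function(key) {
    v <- getScalar(key)
    if (is.na(v)) return(NULL)
    v <- sub("^\\{", "", sub("\\}$", "", v))
    as.numeric(strsplit(v, ",")[[1L]])
  }
  list(
    samples = as.integer(getScalar("samples")),
    lines = as.integer(getScalar("lines")),
    bands = as.integer(getScalar("bands")),
    dtype = as.integer(getScalar("data type")),
    interleave = tolower(getScalar("interleave")),
    byteOrder = as.integer(getScalar("byte order")),
    smoothed = getScalar("smoothed"),
    mask = getBlock("mask"),
    wavelength = getBlock("wavelength")
  )
}

#' Read an ENVI hypercube
#'
#' Supports BSQ and BIL interleaves and data types 4 (float) and 5 (double).
#' A header without a wavelength block is rejected: the wavelength axis is
#' not optional in this package. If the header lists bands out of wavelength
#' order, the bands are re-sorted ascending and the data permuted to match.
#'
#' @param path the basename or the \code{.hdr} path written by
#'   \code{\link{writeENVI}} (the binary is looked up as \code{.dat},
#'   \code{.img} or \code{.bin}).
#' @return a \linkS4class{HyperCube}.
#' @export
readENVI <- function(path) {
  hdr <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  if (!file.exists(hdr)) stop("header not found: ", hdr)
  base <- sub("\\.hdr$", "", hdr)
  dat <- paste0(base, c(".dat", ".img", ".bin"))
  dat <- dat[file.exists(dat)][1L]
  if (is.na(dat)) stop("binary file not found for ", hdr)
  h <- parseEnviHeader(hdr)
  if (is.null(h$wavelength))
    stop("ENVI header has no wavelength block; the wavelength axis is required")
  if (!h$interleave %in% c("bsq", "bil"))
    stop("unsupported interleave: ", h$interleave)
  if (!h$dtype %in% c(4L, 5L)) stop("unsupported ENVI data type: ", h$dtype)
  n <- h$samples * h$lines * h$bands
  con <- file(dat, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = if (h$dtype == 4L) 4L else 8L,
                  endian = if (h$byteOrder == 1L) "big" else "little")
  if (length(vals) != n) stop("binary file shorter than the header promises")
  x <- switch(h$interleave,
    bsq = aperm(array(vals, c(h$samples, h$lines, h$bands)), c(2L, 1L, 3L)),
    bil = aperm(array(vals, c(h$samples, h$bands, h$lines)), c(3L, 1L, 2L))
  )
  wl <- h$wavelength
  if (length(wl) != h$bands)
    stop("wavelength block length disagrees with the band count")
  if (is.unsorted(wl, strictly = TRUE)) {
    ord <- order(wl)
    wl <- wl[ord]
    x <- x[, , ord, drop = FALSE]
  }
  mask <- if (!is.null(h$mask)) {
    matrix(as.logical(h$mask), h$lines, h$samples)
  } else matrix(TRUE, h$lines, h$samples)
  smoothed <- identical(h$smoothed, "1")
  HyperCube(x, wl, smoothed = smoothed, mask = mask)
}

#' Read or write a cube in a named format
#'
#' Thin format dispatcher; \code{"envi"} is the package's lossless native
#' format.
#'
#' @param path file basename.
#' @param format format name; only \code{"envi"} is recognized.
#' @return \code{readCube}: a \linkS4class{HyperCube}.
#' @export
readCube <- function(path, format = "envi") {
  switch(format,
    envi = readENVI(path),
    stop("unknown cube format: ", format)
  )
}

#' @rdname readCube
#' @param cube a \linkS4class{HyperCube} to write.
#' @param ... passed to the format writer.
#' @export
writeCube <- function(cube, path, format = "envi", ...) {
  switch(format,
    envi = writeENVI(cube, path, ...),
    stop("unknown cube format: ", format)
  )
}
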