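# Shared fixtures and independent oracles, all built in code.

# Random RawFrames with a well-conditioned denominator.
randomRawFrames <- function(w = 2L, l = 2L, nb = 3L, seed = 1L) {
  set.seed(seed)
  wl <- seq(400, by = 10, length.out = nb)
  dark <- array(runif(w * l * nb, 90, 110), c(w, l, nb))
  white <- dark + array(runif(w * l * nb, 500, 1500), c(w, l, nb))
  samp <- dark + array(runif(w * l * nb, 0, 1500), c(w, l, nb))
  RawFrames(samp, dark, white, wl)
}

# Scalar-loop calibration oracle (independent of the vectorized path).
calibrateOracle <- function(raw) {
  d <- dim(raw@sample)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    out[i, j, k] <- (raw@sample[i, j, k] - raw@dark[i, j, k]) /
      (raw@white[i, j, k] - raw@dark[i, j, k])
  }
  out
}

# Per-window least-squares Savitzky-Golay oracle for interior points of a
# single spectrum: polynomial fit per window, evaluated at the window center.
sgOracleCenter <- function(y, window, order) {
  h <- (window - 1) %/% 2
  n <- length(y)
  out <- rep(NA_real_, n)
  x <- seq(-h, h)
  X <- outer(x, 0:order, "^")
  proj <- solve(crossprod(X), t(X))[1, ]   # coefficient of x^0
  for (i in (h + 1):(n - h)) out[i] <- sum(proj * y[(i - h):(i + h)])
  out
}

# A small constant-valued HyperCube.
constantCube <- function(value = 0.5, w = 4L, l = 4L,
                         wl = seq(400, 700, by = 10)) {
  HyperCube(array(value, c(w, l, length(wl))), wl)
}

# Random smoothed HyperCube on a uniform wavelength grid.
randomCube <- function(w = 4L, l = 4L, wl = seq(400, 700, by = 5),
                       seed = 1L, smoothed = FALSE) {
  set.seed(seed)
  HyperCube(array(runif(w * l * length(wl)), c(w, l, length(wl))), wl,
            smoothed = smoothed)
}

# Brute-force greedy selection oracle: explicit rescan of the remaining
# bands at every step (independent of the package's ordered-pass version).
greedyOracle <- function(score, centers, nBands, radius) {
  chosen <- integer(0)
  repeat {
    best <- NA_integer_
    for (i in order(-score, centers)) {
      if (i %in% chosen) next
      ok <- TRUE
      for (j in chosen) if (abs(centers[i] - centers[j]) < radius - 1e-9) {
        ok <- FALSE
        break
      }
      if (ok) { best <- i; break }
    }
    if (is.na(best)) break
    chosen <- c(chosen, best)
    if (length(chosen) == nBands) break
  }
  sort(centers[chosen])
}

# Small band-resampled SampleSet built from synthetic spectra (FNN-ready,
# with 1x1 cubes so the spatial-mean invariant holds trivially).
spectraSampleSet <- function(params, grid, sgWindow = 11L, sgOrder = 2L) {
  gen <- generateSynthetic(params, return = "spectra")
  sm <- sgSmoothRows(gen$spectra, sgCoefficients(sgWindow, sgOrder))
  bands <- resampleRows(sm, params$wavelengths, grid)
  new("SampleSet", cubes = array(t(bands), c(1, 1, ncol(bands), nrow(bands))),
      spectra = bands, brix = gen$labels$brix, group = gen$labels$group,
      sampleId = gen$labels$sample_id, grid = grid)
}
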