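# Synthetic labeled hypercubes with planted band-to-Brix structure.
#
# Each sample is a 20x20-pixel ROI whose reflectance spectrum is a smooth
# deterministic baseline plus Gaussian-shaped planted bands whose amplitude
# is linear in the (centered, scaled) Brix label, plus a per-pixel spatial
# texture offset and iid pixel/band noise. Because the planted effect is
# linear in Brix and spectrally localized, a correctly working pipeline must
# place signature bands at (or next to) the planted centers, and the
# noiseless data are exactly label-identifiable.

#' Parameters of the synthetic hypercube generator
#'
#' Defaults emulate the study conditions the pipeline was designed around:
#' a 400-1700 nm wavelength axis, five Brix groups with sizes
#' 218/162/218/218/218 and the published per-group means and standard
#' deviations, and three planted bands at least 40 nm apart.
#'
#' @param wavelengths wavelength axis in nm (default 400-1700 nm, 1 nm
#'   step).
#' @param groupSizes samples per Brix group.
#' @param groupMeans,groupSds per-group Brix means and standard deviations.
#' @param plantedBands data.frame with columns \code{center} (nm) and
#'   \code{weight} (reflectance units per scaled Brix unit).
#' @param plantedWidth Gaussian spectral width (sd, nm) of planted bands.
#' @param noiseSd iid pixel/band reflectance noise sd.
#' @param textureSd per-pixel spatial offset sd (constant across bands).
#' @param roiSize spatial ROI side in pixels.
#' @param brixMid,brixScale centering and scale of the linear Brix effect:
#'   amplitude = weight * (Brix - brixMid) / brixScale.
#' @param seed generator RNG seed.
#' @return a list of class \code{SynthParams}.
#' @export
synthParams <- function(wavelengths = seq(400, 1700, by = 1),
                        groupSizes = c(218L, 162L, 218L, 218L, 218L),
                        groupMeans = c(8.65, 10.44, 11.48, 12.52, 14.01),
                        groupSds = c(0.82, 0.25, 0.23, 0.27, 0.88),
                        plantedBands = data.frame(
                          center = c(560, 660, 1170),
                          weight = c(0.30, -0.25, 0.20)),
                        plantedWidth = 10, noiseSd = 0.2, textureSd = 0.02,
                        roiSize = 20L, brixMid = 11.5, brixScale = 5,
                        seed = 1L) {
  wavelengths <- sort(as.numeric(wavelengths))
  if (any(groupSizes < 0)) stop("group sizes must be nonnegative")
  if (noiseSd < 0 || textureSd < 0) stop("noise sds must be nonnegative")
  if (nrow(plantedBands)) {
    off <- plantedBands$center < min(wavelengths) |
      plantedBands$center > max(wavelengths)
    if (any(off))
      stop("planted band center off the wavelength grid: ",
           paste(plantedBands$center[off], collapse = ", "))
  }
  structure(list(wavelengths = wavelengths,
                 groupSizes = as.integer(groupSizes),
                 groupMeans = groupMeans, groupSds = groupSds,
                 plantedBands = plantedBands, plantedWidth = plantedWidth,
                 noiseSd = noiseSd, textureSd = textureSd,
                 roiSize = as.integer(roiSize), brixMid = brixMid,
                 brixScale = brixScale, seed = as.integer(seed)),
            class = "SynthParams")
}

#' Tiny preset for unit tests
#'
#' Eight samples on a 400-700 nm, 5 nm-step axis with one planted band.
#'
#' @param seed generator seed.
#' @return a \code{SynthParams}.
#' @export
synthTinyParams <- function(seed = 1L) {
  synthParams(wavelengths = seq(400, 700, by = 5),
              groupSizes = c(2L, 2L, 2L, 1L, 1L),
              plantedBands = data.frame(center = 550, weight = 0.3),
              noiseSd = 0.05, seed = seed)
}

# deterministic smooth reflectance baseline: two broad reflectance humps and
# a mild absorption dip near 980 nm (water-like), all well within [0, 1]
synthBaseline <- function(wl) {
  0.40 + 0.22 * exp(-((wl - 560) / 120)^2) +
    0.18 * exp(-((wl - 1250) / 220)^2) -
    0.10 * exp(-((wl - 980) / 40)^2)
}

# truncated-normal draw at +/- 3 sd via the inverse CDF (one uniform per
# draw keeps the RNG stream aligned regardless of acceptance rates)
rtruncnorm3 <- function(n, mean, sd) {
  lo <- stats::pnorm(-3); hi <- stats::pnorm(3)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

#' Draw the per-sample Brix labels
#'
#' First stage of \code{\link{generateSynthetic}}: one truncated-normal
#' (+/- 3 sd) draw per sample from its group's distribution. Group ids are
#' re-derived from the drawn values via \code{\link{assignBrixGroup}}, so a
#' draw near a boundary may land in a neighboring group.
#'
#' @param params a \code{\link{synthParams}}.
#' @return data.frame with sample_id, brix, group, sourceGroup.
#' @export
synthLabels <- function(params) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  brix <- unlist(lapply(seq_along(params$groupSizes), function(g) {
    rtruncnorm3(params$groupSizes[g], params$groupMeans[g],
                params$groupSds[g])
  }))
  data.frame(
    sample_id = sprintf("syn%04d", seq_along(brix)),
    brix = brix,
    group = assignBrixGroup(brix),
    sourceGroup = rep(seq_along(params$groupSizes), params$groupSizes))
}

# Noise-free spectral part of sample with label `brix` (length = #wavelengths)
synthSpectrum <- function(params, brixValue) {
  wl <- params$wavelengths
  s <- synthBaseline(wl)
  amp <- (brixValue - params$brixMid) / params$brixScale
  pb <- params$plantedBands
  for (p in seq_len(nrow(pb))) {
    s <- s + pb$weight[p] * amp *
      exp(-((wl - pb$center[p])^2) / (2 * params$plantedWidth^2))
  }
  s
}

#' Generate one synthetic ROI hypercube
#'
#' Spectral part plus per-pixel texture offset plus iid noise, seeded
#' per-sample so cubes can be regenerated independently of one another.
#'
#' @param params a \code{\link{synthParams}}.
#' @param brixValue the sample's Brix label.
#' @param sampleSeed per-sample RNG seed.
#' @return an unsmoothed \linkS4class{HyperCube} of roiSize x roiSize x
#'   length(wavelengths).
#' @export
synthCube <- function(params, brixValue, sampleSeed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(sampleSeed))
  r <- params$roiSize
  nw <- length(params$wavelengths)
  spec <- synthSpectrum(params, brixValue)
  cube <- array(rep(spec, each = r * r), c(r, r, nw))
  if (params$textureSd > 0)
    cube <- cube + as.vector(matrix(stats::rnorm(r * r, 0, params$textureSd),
                                    r, r))
  if (params$noiseSd > 0)
    cube <- cube + array(stats::rnorm(r * r * nw, 0, params$noiseSd),
                         c(r, r, nw))
  HyperCube(cube, params$wavelengths, smoothed = FALSE)
}

#' Generate a synthetic labeled dataset
#'
#' Draws all Brix labels first (so the labels are identical whichever
#' \code{return} form is requested), then builds one ROI cube per sample.
#' Per-sample cube seeds are derived from the generator seed, making
#' generation bitwise-reproducible and order-independent.
#'
#' @param params a \code{\link{synthParams}}.
#' @param return \code{"cubes"} (list of \linkS4class{HyperCube}s; memory
#'   scales with n), \code{"spectra"} (stream each cube to its spatial-mean
#'   spectrum), or \code{"labels"} (labels and truth only).
#' @return list with \code{labels} (data.frame), \code{truth} (planted
#'   bands, generative coefficients, per-sample Brix), and \code{cubes} or
#'   \code{spectra} per \code{return}.
#' @export
generateSynthetic <- function(params,
                              return = c("cubes", "spectra", "labels")) {
  return <- match.arg(return)
  labels <- synthLabels(params)
  n <- nrow(labels)
  truth <- list(plantedBands = params$plantedBands,
                plantedWidth = params$plantedWidth,
                brixMid = params$brixMid, brixScale = params$brixScale,
                baseline = synthBaseline, brix = labels$brix,
                seed = params$seed)
  out <- list(labels = labels, truth = truth)
  if (return == "labels") return(out)
  sampleSeeds <- params$seed * 10000L + seq_len(n)
  if (return == "cubes") {
    out$cubes <- lapply(seq_len(n), function(i)
      synthCube(params, labels$brix[i], sampleSeeds[i]))
  } else {
    spectra <- matrix(0, n, length(params$wavelengths))
    for (i in seq_len(n)) {
      spectra[i, ] <- toMeanSpectrum(
        synthCube(params, labels$brix[i], sampleSeeds[i]))
    }
    out$spectra <- spectra
  }
  out
}

#' Planted-band recovery experiment
#'
#' For each seed: generate a synthetic dataset, run the multispectral
#' conversion (Savitzky-Golay smoothing + boxcar resampling), train a model,
#' score its bands by the absolute mean of integrated gradients, select six
#' signature bands, and count how many planted bands have a selected center
#' within one grid step (the full bandwidth) of their true center. The
#' chance level reported alongside is the expected number of planted bands
#' "recovered" by a uniformly random six-band subset (hypergeometric over
#' each planted band's qualifying grid centers).
#'
#' The feedforward path operates on spatial-mean spectra; smoothing,
#' resampling and spatial averaging are all linear, so averaging first is
#' exactly equivalent to smoothing the cube and averaging afterwards.
#'
#' @param params a \code{\link{synthParams}} with at least one planted band.
#' @param seeds integer seeds, one experiment per seed.
#' @param range spectral-range label for the band grid.
#' @param halfBandwidth grid half-bandwidth in nm.
#' @param family model family (\code{"fnn"} supported).
#' @param epochs,patience training budget per seed.
#' @param sgWindow,sgOrder Savitzky-Golay settings.
#' @param nBands,exclusionRadius selection settings.
#' @return list with \code{perSeed} (data.frame: seed, recovered, selected
#'   centers, test MAE), \code{chanceLevel} (random-subset expectation under
#'   the same one-grid-step tolerance), \code{chanceLevelExact} (nearest
#'   center only), \code{nPlanted}, \code{grid}.
#' @export
recoveryHarness <- function(params, seeds = 1:5, range = "VISWIR",
                            halfBandwidth = 10, family = "fnn",
                            epochs = 80L, patience = 20L,
                            sgWindow = 11L, sgOrder = 2L, nBands = 6L,
                            exclusionRadius = 20) {
  pb <- params$plantedBands
  if (nrow(pb) == 0L) stop("recovery harness needs at least one planted band")
  if (family != "fnn")
    stop("the recovery harness supports the FNN family")
  grid <- makeRangeGrid(range, halfBandwidth)
  w <- 2 * halfBandwidth
  if (nrow(pb) > 1L) {
    gaps <- abs(outer(pb$center, pb$center, "-"))
    if (any(gaps[upper.tri(gaps)] < exclusionRadius))
      warning("planted bands closer than the exclusion radius: at most one ",
              "band per cluster can be recovered")
  }
  coefs <- sgCoefficients(sgWindow, sgOrder)
  rows <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    p <- params
    p$seed <- as.integer(seeds[si])
    gen <- generateSynthetic(p, return = "spectra")
    sm <- sgSmoothRows(gen$spectra, coefs)
    bands <- resampleRows(sm, p$wavelengths, grid)
    cubes1 <- array(t(bands), c(1L, 1L, ncol(bands), nrow(bands)))
    ss <- new("SampleSet", cubes = cubes1, spectra = bands,
              brix = gen$labels$brix, group = gen$labels$group,
              sampleId = gen$labels$sample_id, grid = grid)
    split <- splitDataset(ss@sampleId, ss@group, seed = seeds[si])
    spec <- fnnMultiSpec(range)
    model <- buildFNN(spec, inputLength = nBands(grid), seed = seeds[si])
    fit <- trainModel(model, ss, split,
                      trainConfig(maxEpochs = epochs, patience = patience,
                                  seed = seeds[si]))
    sig <- extractSignatureBands(fit$model, subsetSamples(ss, split@trainIds),
                                 nBands = nBands,
                                 exclusionRadius = exclusionRadius,
                                 range = range, seed = seeds[si])
    hit <- vapply(pb$center, function(ctr)
      any(abs(sig@centers - ctr) <= w + 1e-9), TRUE)
    rows[[si]] <- data.frame(seed = seeds[si], recovered = sum(hit),
                             centers = paste(sig@centers, collapse = ";"),
                             testMae = fit$metrics$mae)
  }
  perSeed <- do.call(rbind, rows)
  # chance levels for a uniformly random nBands-subset of the grid:
  # chanceLevel counts a planted band as hit if ANY center within one full
  # bandwidth is selected (the same tolerance as `recovered`);
  # chanceLevelExact requires the single nearest center itself.
  C <- nBands(grid)
  chance <- sum(vapply(pb$center, function(ctr) {
    q <- sum(abs(grid@centers - ctr) <= w + 1e-9)
    1 - exp(lchoose(C - q, nBands) - lchoose(C, nBands))
  }, 1.0))
  list(perSeed = perSeed, chanceLevel = chance,
       chanceLevelExact = nrow(pb) * nBands / C, nPlanted = nrow(pb),
       grid = grid)
}
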