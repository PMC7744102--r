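# Synthetic connectome generator: dendrite centers tiling the eye lune
# with a midline density bias, axons converging into a cylindrical
# glomerulus with a tunable degree of retinotopy, presynapse clouds,
# distance-decayed neuron-to-neuron synapses, spatially biased target
# synapse counts, and synthetic calcium traces.

#' Construct a ConnectomeConfig
#'
#' Defaults emulate the LC6 system: 65 neurons drawn from a 6 x 11
#' jittered lattice on the lune (higher density near the visual midline),
#' about 1900 neuron-to-neuron synapses with a 20-degree eye-distance decay,
#' a 40 x 10 um cylindrical glomerulus, and two downstream targets whose
#' synapse totals echo the strongly and moderately connected target classes.
#'
#' @param nNeurons,gridShape,jitterSd,scramble,axisCoupling see
#'   [ConnectomeConfig-class].
#' @param presynPerNeuron,lcLcDecayScale,lcLcTotal,midlineSlope see
#'   [ConnectomeConfig-class].
#' @param glomLength,glomRadius,nodeSpacing,targetSpecs,seed see
#'   [ConnectomeConfig-class].
#' @return A validated [ConnectomeConfig-class].
#' @export
connectomeConfig <- function(nNeurons = 65, gridShape = c(6, 11),
                             jitterSd = 3, scramble = 0,
                             axisCoupling = 0.8, presynPerNeuron = 60,
                             lcLcDecayScale = 20, lcLcTotal = 1900,
                             midlineSlope = 0.5, glomLength = 40000,
                             glomRadius = 5000, nodeSpacing = 400,
                             targetSpecs = list(
                               list(center = c(0, 100), spread = 30,
                                    total = 900,
                                    transmitter = "excitatory"),
                               list(center = c(0, 55), spread = 30,
                                    total = 430,
                                    transmitter = "inhibitory")),
                             seed = 1) {
  new("ConnectomeConfig", nNeurons = as.integer(nNeurons),
      gridShape = as.integer(gridShape), jitterSd = jitterSd,
      scramble = scramble, axisCoupling = axisCoupling,
      presynPerNeuron = as.integer(presynPerNeuron),
      lcLcDecayScale = lcLcDecayScale, lcLcTotal = lcLcTotal,
      midlineSlope = midlineSlope, glomLength = glomLength,
      glomRadius = glomRadius, nodeSpacing = nodeSpacing,
      targetSpecs = targetSpecs, seed = as.integer(seed))
}

setMethod("show", "ConnectomeConfig", function(object) {
  cat(sprintf(paste0("ConnectomeConfig: %d neurons (%d x %d lattice), ",
                     "scramble %.2f, coupling %.2f, seed %d\n"),
              object@nNeurons, object@gridShape[1], object@gridShape[2],
              object@scramble, object@axisCoupling, object@seed))
})

#' Jittered lattice of dendrite centers on the eye lune
#'
#' A rows x cols lattice spanning the lune (rows along latitude), each
#' point perturbed by isotropic Gaussian jitter. Deterministic given the
#' seed.
#'
#' @param rows,cols lattice shape; rows * cols must be at least 3 (the
#'   Retinotopy Index is undefined below 3 points).
#' @param jitterSd jitter standard deviation, degrees.
#' @param seed integer seed.
#' @return (rows * cols) x 2 matrix of (lon, lat) degrees, rownames
#'   `p1`, `p2`, ...
#' @export
makeLobulaGrid <- function(rows, cols, jitterSd = 0, seed = NULL) {
  if (rows * cols < 3)
    stop("invalid size: Retinotopy Index is undefined below 3 points")
  lonStep <- 180 / cols; latStep <- 170 / rows
  lon <- -90 + lonStep * (seq_len(cols) - 0.5)
  lat <- -10 + latStep * (seq_len(rows) - 0.5)
  g <- as.matrix(expand.grid(lon = lon, lat = lat))
  if (jitterSd > 0)
    g <- g + withSeed(seed, matrix(stats::rnorm(length(g), 0, jitterSd),
                                   ncol = 2))
  rownames(g) <- paste0("p", seq_len(nrow(g)))
  g
}

# Warp lattice longitudes so dendrite density rises linearly toward the
# visual midline (lon 0): inverse-CDF of density 1 - slope * |lon| / 90.
warpMidline <- function(lon, slope) {
  if (slope == 0) return(lon)
  u <- abs(lon) / 90
  ut <- (1 - sqrt(1 - 2 * slope * u * (1 - slope / 2))) / slope
  sign(lon) * 90 * ut
}

#' Generate a synthetic connectome
#'
#' Builds the full synthetic data set the analysis stages consume:
#' \itemize{
#' \item dendrite centers from a jittered lattice, denser near the midline;
#' \item one skeleton per neuron: a star-shaped dendrite on a lobula sheet,
#'   an axon to the glomerulus entry, and an in-glomerulus stretch whose
#'   length follows the axis-coupling channel;
#' \item a 1-D glomerulus axis placement per axon that is a rank mixture of
#'   the neuron's latitude rank and a random rank, weighted by `scramble`
#'   (0 = latitude order, 1 = random order);
#' \item presynapses scattered uniformly along the distal in-glomerulus
#'   axon;
#' \item neuron-to-neuron synapse counts decaying with eye distance at
#'   scale `lcLcDecayScale`;
#' \item per-target synapse counts proportional to a Gaussian of the
#'   target's RF center evaluated at each neuron's eye center (multinomial,
#'   so they sum exactly to the configured total).
#' }
#' Randomness is split into named substreams of the single seed, so adding
#' one component never perturbs another; identical config and seed give
#' identical output.
#'
#' @param config a [ConnectomeConfig-class].
#' @return A [SyntheticConnectome-class].
#' @export
generateConnectome <- function(config) {
  validObject(config)
  n <- config@nNeurons
  seed <- config@seed
  # --- dendrite layout on the lune ----------------------------------------
  rows <- config@gridShape[1]; cols <- config@gridShape[2]
  lonStep <- 180 / cols; latStep <- 170 / rows
  lon <- warpMidline(-90 + lonStep * (seq_len(cols) - 0.5),
                     config@midlineSlope)
  lat <- -10 + latStep * (seq_len(rows) - 0.5)
  g <- as.matrix(expand.grid(lon = lon, lat = lat))
  if (config@jitterSd > 0)
    g <- g + withSeed(substreamSeed(seed, "layout"),
                      matrix(stats::rnorm(length(g), 0, config@jitterSd),
                             ncol = 2))
  keep <- withSeed(substreamSeed(seed, "census"),
                   sort(sample(nrow(g), n)))
  eye <- g[keep, , drop = FALSE]
  ids <- sprintf("n%02d", seq_len(n))
  rownames(eye) <- ids
  colnames(eye) <- c("lon", "lat")
  # --- axon placement along the glomerulus axis ---------------------------
  latRank <- rank(eye[, 2], ties.method = "first")
  randRank <- withSeed(substreamSeed(seed, "scramble"), sample(n))
  mixed <- (1 - config@scramble) * latRank + config@scramble * randRank
  axisRank <- rank(mixed, ties.method = "first")
  # axon length channel: correlation axisCoupling with the mixed rank
  zMix <- as.numeric(scale(axisRank))
  eps <- withSeed(substreamSeed(seed, "coupling"), stats::rnorm(n))
  zLen <- config@axisCoupling * zMix +
    sqrt(max(0, 1 - config@axisCoupling^2)) * eps
  tipQ <- (rank(zLen, ties.method = "first") - 0.5) / n
  tipX <- config@glomLength * (0.25 + 0.7 * tipQ)
  # --- skeletons ----------------------------------------------------------
  # scramble = 0 means perfect retinotopy of axon positions: the axon's
  # position in the cylinder cross-section mirrors its eye coordinate, and
  # blends toward a random disc position as scramble grows
  entryRet <- cbind(eye[, 1] / 90, (eye[, 2] - 75) / 85) *
    config@glomRadius * 0.8
  entryYZ <- withSeed(substreamSeed(seed, "entry"), {
    r <- config@glomRadius * 0.8 * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    (1 - config@scramble) * entryRet +
      config@scramble * cbind(r * cos(th), r * sin(th))
  })
  lobulaScale <- 250       # nm per degree on the synthetic lobula sheet
  dendRadius <- 30 * lobulaScale  # ~30 deg mean dendritic arbor radius
  neurons <- vector("list", n)
  names(neurons) <- ids
  for (i in seq_len(n)) {
    dend <- c(-30000, eye[i, 1] * lobulaScale, eye[i, 2] * lobulaScale)
    entry <- c(0, entryYZ[i, 1], entryYZ[i, 2])
    tip <- c(tipX[i], entryYZ[i, 1], entryYZ[i, 2])
    sp <- config@nodeSpacing
    seg <- function(a, b) {
      L <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2L, round(L / sp) + 1L))
      outer(1 - t, a) + outer(t, b)
    }
    axonPts <- rbind(seg(dend, entry), seg(entry, tip)[-1, , drop = FALSE])
    th <- seq(0, 2 * pi, length.out = 9)[-9]
    dendPts <- cbind(dend[1], dend[2] + dendRadius * cos(th),
                     dend[3] + dendRadius * sin(th))
    nodes <- data.frame(
      node_id = seq_len(1 + nrow(dendPts) + nrow(axonPts) - 1),
      parent_id = NA_integer_,
      x = c(dend[1], dendPts[, 1], axonPts[-1, 1]),
      y = c(dend[2], dendPts[, 2], axonPts[-1, 2]),
      z = c(dend[3], dendPts[, 3], axonPts[-1, 3]),
      radius = NA_real_,
      label = c(rep("dendrite", 1 + nrow(dendPts)),
                rep("axon", nrow(axonPts) - 1)))
    nd <- nrow(dendPts)
    nodes$parent_id[2:(1 + nd)] <- 1L          # dendrite star off the root
    axonIds <- (2 + nd):nrow(nodes)
    nodes$parent_id[axonIds] <- c(1L, axonIds[-length(axonIds)])
    neurons[[i]] <- skeleton(nodes, neuronId = ids[i])
  }
  # --- presynapses along the distal in-glomerulus axon --------------------
  presyn <- withSeed(substreamSeed(seed, "presynapses"), {
    do.call(rbind, lapply(seq_len(n), function(i) {
      x <- stats::runif(config@presynPerNeuron, 0.6 * tipX[i], tipX[i])
      data.frame(pre_id = ids[i], post_id = NA_character_,
                 x = x,
                 y = entryYZ[i, 1] + stats::rnorm(config@presynPerNeuron,
                                                  0, 300),
                 z = entryYZ[i, 2] + stats::rnorm(config@presynPerNeuron,
                                                  0, 300))
    }))
  })
  presynTable <- synapseTable(presyn)
  # --- neuron-to-neuron synapses with eye-distance decay ------------------
  lcLc <- withSeed(substreamSeed(seed, "lclc"), {
    D <- greatCircleDeg(eye)
    lam <- exp(-D / config@lcLcDecayScale)
    diag(lam) <- 0
    lam <- lam * config@lcLcTotal / sum(lam)
    cnt <- matrix(stats::rpois(n * n, lam), n, n)
    diag(cnt) <- 0L
    pairIdx <- which(cnt > 0, arr.ind = TRUE)
    k <- cnt[pairIdx]
    preI <- rep(pairIdx[, 1], k); postI <- rep(pairIdx[, 2], k)
    # each synapse sits at a random presynaptic site of the pre neuron
    m <- config@presynPerNeuron
    rows <- (preI - 1L) * m + sample.int(m, length(preI), replace = TRUE)
    data.frame(pre_id = ids[preI], post_id = ids[postI],
               x = presyn$x[rows], y = presyn$y[rows], z = presyn$z[rows])
  })
  # --- target synapse counts ----------------------------------------------
  nt <- length(config@targetSpecs)
  targetIds <- sprintf("t%02d", seq_len(nt))
  targetCounts <- matrix(0, nt, n, dimnames = list(targetIds, ids))
  trueCenters <- matrix(NA_real_, nt, 2,
                        dimnames = list(targetIds, c("lon", "lat")))
  withSeed(substreamSeed(seed, "targets"), {
    for (t in seq_len(nt)) {
      ts <- config@targetSpecs[[t]]
      trueCenters[t, ] <- ts$center
      d <- greatCircleDeg(eye, matrix(ts$center, 1))[, 1]
      if (ts$spread == 0) {
        w <- as.numeric(d == min(d))
      } else {
        w <- exp(-d^2 / (2 * ts$spread^2))
      }
      targetCounts[t, ] <- drop(stats::rmultinom(1, ts$total, w))
    }
  })
  truth <- list(scramble = config@scramble,
                axisCoupling = config@axisCoupling,
                latRank = stats::setNames(latRank, ids),
                axisRank = stats::setNames(axisRank, ids),
                axisCoord = stats::setNames(
                  config@glomLength * (0.15 + 0.7 * (axisRank - 0.5) / n),
                  ids),
                tipX = stats::setNames(tipX, ids),
                rfCenters = trueCenters,
                rfSpreads = vapply(config@targetSpecs, `[[`, numeric(1),
                                   "spread"),
                transmitters = vapply(config@targetSpecs, `[[`,
                                      character(1), "transmitter"))
  new("SyntheticConnectome", neurons = neurons, eyeCenters = eye,
      presynapses = presynTable, lcLcSynapses = synapseTable(lcLc),
      targetCounts = targetCounts, truth = truth, config = config)
}

setMethod("show", "SyntheticConnectome", function(object) {
  cat(sprintf(paste0("SyntheticConnectome: %d neurons, %d presynapses, ",
                     "%d neuron-neuron synapses, %d targets\n"),
              length(object@neurons), nrow(object@presynapses@synapses),
              nrow(object@lcLcSynapses@synapses),
              nrow(object@targetCounts)))
  cat(sprintf("  scramble %.2f, coupling %.2f\n",
              object@truth$scramble, object@truth$axisCoupling))
})

#' Eye centers of a synthetic connectome
#' @param connectome a [SyntheticConnectome-class].
#' @return matrix (lon, lat) with rownames = neuron ids.
#' @export
eyeCenters <- function(connectome) connectome@eyeCenters

#' Canonical lobula-to-glomerulus-axis mapping of a synthetic connectome
#'
#' The mapping whose retinotopy the `scramble` parameter controls: the
#' source is eye latitude (`source = "latitude"`, the axis the generator
#' scrambles; population RI approaches 1 at scramble 0 and 0 at scramble 1)
#' or the full 2-D eye position (`source = "eye"`); the target is the 1-D
#' axis placement of each axon.
#'
#' @param connectome a [SyntheticConnectome-class].
#' @param source `"latitude"` or `"eye"`.
#' @return A [PointMapping-class].
#' @export
axisMapping <- function(connectome, source = c("latitude", "eye")) {
  source <- match.arg(source)
  ids <- names(connectome@neurons)
  src <- if (source == "latitude")
    cbind(connectome@eyeCenters[, 2]) else connectome@eyeCenters
  pointMapping(src, cbind(connectome@truth$axisCoord[ids]), ids = ids,
               metric = c(if (source == "eye") "greatcircle" else
                 "euclidean", "euclidean"))
}

#' Synthetic calcium traces from a receptive field
#'
#' One fluorescence time series per stimulus location: a flat baseline plus
#' a triangular transient in the central third of the trace whose amplitude
#' is `gain` times the field value at the stimulus center, plus Gaussian
#' noise. The noiseless peak dF/F at the field peak is exactly
#' `gain * max(rf) / baseline`.
#'
#' @param rf an [RFGrid-class].
#' @param stimulusCenters two-column (lon, lat) matrix; centers outside the
#'   grid are an error.
#' @param gain transient amplitude per unit field value (fluorescence
#'   units).
#' @param noiseSd Gaussian noise standard deviation (fluorescence units).
#' @param framesPerEpoch frames in each of the pre/stimulus/post thirds.
#' @param baseline baseline fluorescence F0.
#' @param seed integer seed.
#' @return list with `traces` (frames x stimuli matrix), `epoch`
#'   (c(start, end) frames of the stimulus third), and `amplitudes`.
#' @export
makeTraces <- function(rf, stimulusCenters, gain = 5, noiseSd = 0,
                       framesPerEpoch = 30, baseline = 100, seed = NULL) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (any(rf@values < 0)) stop("rf must be non-negative")
  amp <- gain * rfValueAt(rf, stimulusCenters)   # errors if out of domain
  nf <- 3 * framesPerEpoch
  shape <- numeric(nf)
  on <- framesPerEpoch + 1L; off <- 2L * framesPerEpoch
  ramp <- seq_len(framesPerEpoch)
  half <- ceiling(framesPerEpoch / 2)
  shape[on:off] <- pmin(ramp / half, (framesPerEpoch - ramp + 1) /
                          (framesPerEpoch - half + 1))
  shape[on + half - 1L] <- 1   # exact unit peak
  traces <- baseline + outer(shape, amp)
  if (noiseSd > 0)
    traces <- traces + withSeed(seed, matrix(stats::rnorm(length(traces),
                                                          0, noiseSd),
                                             nrow = nf))
  list(traces = traces, epoch = c(on, off), amplitudes = amp)
}
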