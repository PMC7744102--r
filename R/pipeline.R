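# Run configuration and the end-to-end pipeline binding the analyses
# together, plus the remaining plain-text readers/writers.

#' Default run configuration
#'
#' Nested list of every tunable parameter with its conventional default:
#' 400 nm skeleton resampling, 1 um cross-section slabs, 10 glomerulus
#' compartments, 80 proximity slices, 30-degree Gaussian half-width, 70%
#' anatomical and 60% functional contours, 15-synapse connectivity
#' threshold, 300-frame 10th-percentile dF/F baseline, and 98th-percentile
#' per-fly normalization.
#'
#' @param seed global seed.
#' @return named list understood by [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1) {
  list(seed = seed,
       out = NULL,
       generator = list(),
       resampleSpacing = 400,
       slabThickness = 1000,
       nCompartments = 10,
       middleCompartments = c(4, 5, 6),
       proximitySlices = 80,
       rfHalfWidth = 30,
       rfGridStep = 1,
       anatomicalContour = 0.7,
       functionalContour = 0.6,
       synapseThreshold = 15,
       dffWindow = 300,
       dffPercentile = 10,
       normalizePercentile = 98,
       sweepAngles = seq(0, 170, by = 10),
       nShuffles = 1000)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected before any computation; missing keys take
#' their defaults from [defaultRunConfig()].
#'
#' @param path YAML file path.
#' @return resolved configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, user)
}

#' Write eye centers to CSV
#' @param eyeCenters matrix (lon, lat) with rownames = neuron ids.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEyeCenters <- function(eyeCenters, path) {
  utils::write.csv(data.frame(neuron_id = rownames(eyeCenters),
                              lon_deg = eyeCenters[, 1],
                              lat_deg = eyeCenters[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read eye centers from CSV
#' @param path CSV with columns neuron_id, lon_deg, lat_deg.
#' @return matrix (lon, lat) with rownames = neuron ids.
#' @export
readEyeCenters <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(neuron_id = "character"))
  out <- cbind(lon = tab$lon_deg, lat = tab$lat_deg)
  rownames(out) <- tab$neuron_id
  out
}

#' Write calcium traces to CSV
#' @param traces frames x stimuli matrix (as from [makeTraces()]).
#' @param path output CSV path (long format: stim_id, frame, F).
#' @return `path`, invisibly.
#' @export
writeTraces <- function(traces, path) {
  long <- data.frame(stim_id = rep(seq_len(ncol(traces)),
                                   each = nrow(traces)),
                     frame = rep(seq_len(nrow(traces)), ncol(traces)),
                     F = as.vector(traces))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read calcium traces from CSV
#' @param path CSV with columns stim_id, frame, F.
#' @return frames x stimuli matrix.
#' @export
readTraces <- function(path) {
  long <- utils::read.csv(path)
  stims <- sort(unique(long$stim_id))
  frames <- sort(unique(long$frame))
  out <- matrix(NA_real_, length(frames), length(stims))
  out[cbind(match(long$frame, frames), match(long$stim_id, stims))] <- long$F
  out
}

#' Export a synthetic connectome to plain-text files
#'
#' Writes one SWC per neuron, `synapses.csv` (presynapses and
#' neuron-to-neuron records pooled), `eye_centers.csv`, and `truth.json`.
#'
#' @param connectome a [SyntheticConnectome-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeConnectome <- function(connectome, dir) {
  dir.create(file.path(dir, "swc"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(connectome@neurons))
    writeSWC(connectome@neurons[[nm]],
             file.path(dir, "swc", paste0(nm, ".swc")))
  writeSynapses(synapseTable(rbind(connectome@presynapses@synapses,
                                   connectome@lcLcSynapses@synapses)),
                file.path(dir, "synapses.csv"))
  writeEyeCenters(connectome@eyeCenters, file.path(dir, "eye_centers.csv"))
  jsonlite::write_json(
    list(scramble = connectome@truth$scramble,
         axisCoupling = connectome@truth$axisCoupling,
         axisRank = as.list(connectome@truth$axisRank),
         rfCenters = connectome@truth$rfCenters,
         targetCounts = connectome@targetCounts),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline on a synthetic connectome
#'
#' Orchestrates the analyses in their natural order: generate (or accept) a
#' connectome; score the Retinotopy Index of axon positions at
#' cross-sections along the glomerulus; compute skeleton and presynapse
#' median positions and the lobula-to-median RI; sweep the idealized
#' projection axis; run the distance-weighted connectivity-bias shuffle
#' test; partition the glomerulus into equal-synapse compartments and score
#' the middle-compartment presynapse RI against its randomized control; and
#' estimate each target's anatomical receptive field with its
#' fraction-of-peak contour. Every stage draws from a named substream of
#' the global seed, so the run is reproducible end to end. If `config$out`
#' is set, CSV/JSON outputs and a machine-readable `summary.json` (carrying
#' the resolved configuration) are written there.
#'
#' @param config list as from [defaultRunConfig()] or [readRunConfig()].
#' @param connectome optional pre-built [SyntheticConnectome-class]; by
#'   default one is generated from `config$generator` and `config$seed`.
#' @return list of stage results (see the summary it writes).
#' @export
runPipeline <- function(config = defaultRunConfig(), connectome = NULL) {
  base <- defaultRunConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(base, config)
  if (is.null(connectome)) {
    gen <- config$generator
    gen$seed <- substreamSeed(config$seed, "generator")
    connectome <- generateConnectome(do.call(connectomeConfig, gen))
  }
  ids <- names(connectome@neurons)
  eye <- connectome@eyeCenters
  skels <- lapply(connectome@neurons, resampleSkeleton,
                  spacing = config$resampleSpacing)
  axis <- glomerulusLongAxis(connectome@presynapses)
  # --- RI at cross-sections along the glomerulus --------------------------
  presynXyz <- as.matrix(connectome@presynapses@synapses[, c("x", "y", "z")])
  sectionS <- stats::quantile(projectOntoAxis(presynXyz, axis),
                              c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  skelS <- lapply(skels, projectOntoAxis, axis = axis)
  sectionRI <- lapply(sectionS, function(s0) {
    planePoint <- axis@origin + s0 * axis@direction
    present <- names(skels)[vapply(skelS, function(s)
      any(abs(s - s0) <= config$slabThickness / 2), logical(1))]
    if (length(present) < 3) return(NULL)
    # reference pair: the two present neurons most distant in eye latitude
    refPair <- present[c(which.min(eye[present, 2]),
                         which.max(eye[present, 2]))]
    pos <- crossSectionPositions(skels[present], planePoint,
                                 axis@direction,
                                 thickness = config$slabThickness,
                                 refPair = refPair)
    if (nrow(pos) < 3) return(NULL)
    keep <- rownames(pos)
    r <- riPopulation(pointMapping(eye[keep, , drop = FALSE], pos,
                                   ids = keep,
                                   metric = c("greatcircle", "euclidean")))
    list(s = s0, n = nrow(pos), ri = r@populationRI, p = r@pValue)
  })
  # --- median positions and their RI --------------------------------------
  mask <- glomerulusMask(connectome@presynapses)
  glomSkels <- lapply(skels, function(sk)
    tryCatch(maskSkeleton(sk, mask), error = function(e) NULL))
  okSkel <- !vapply(glomSkels, is.null, logical(1))
  skelMed <- vapply(glomSkels[okSkel], medianAxisPosition, numeric(1),
                    axis = axis)
  presynByNeuron <- split(connectome@presynapses@synapses,
                          connectome@presynapses@synapses$pre_id)
  presynMed <- vapply(presynByNeuron, function(df)
    medianAxisPosition(as.matrix(df[, c("x", "y", "z")]), axis), numeric(1))
  riSkelMed <- riPopulation(pointMapping(
    eye[names(skelMed), , drop = FALSE], cbind(skelMed),
    ids = names(skelMed), metric = c("greatcircle", "euclidean")))
  riPresynMed <- riPopulation(pointMapping(
    eye[names(presynMed), , drop = FALSE], cbind(presynMed),
    ids = names(presynMed), metric = c("greatcircle", "euclidean")))
  # --- idealized projection sweep -----------------------------------------
  sweep <- projectionSweep(eye[names(skelMed), , drop = FALSE], skelMed,
                           angles = config$sweepAngles)
  # --- connectivity bias --------------------------------------------------
  lc <- connectome@lcLcSynapses@synapses
  cnt <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(lc)) {
    tab <- table(lc$pre_id, lc$post_id)
    cnt[rownames(tab), colnames(tab)] <- tab
  }
  bias <- lcLcDistanceBias(eye, cnt, nShuffles = config$nShuffles,
                           seed = substreamSeed(config$seed, "bias"))
  # --- compartments and middle-compartment RI -----------------------------
  part <- partitionCompartments(connectome@presynapses, axis,
                                k = config$nCompartments)
  presynDf <- data.frame(neuron_id = connectome@presynapses@synapses$pre_id,
                         connectome@presynapses@synapses[, c("x", "y", "z")],
                         compartment = part@assignment)
  compRI <- compartmentRI(presynDf, eye, config$middleCompartments)
  compRIControl <- compartmentRI(presynDf, eye, config$middleCompartments,
                                 randomize = TRUE,
                                 seed = substreamSeed(config$seed,
                                                      "compartment-control"))
  # --- anatomical receptive fields ----------------------------------------
  grid <- luneGrid(config$rfGridStep)
  rfs <- lapply(rownames(connectome@targetCounts), function(t) {
    rf <- anatomicalRF(eye, connectome@targetCounts[t, ],
                       halfWidth = config$rfHalfWidth, grid = grid)
    list(target = t, peak = rfArgmax(rf),
         contour = rfContour(rf, config$anatomicalContour))
  })
  result <- list(
    config = config[setdiff(names(config), "out")],  # parameters, not paths
    nNeurons = length(ids),
    sections = sectionRI,
    riSkeletonMedian = c(ri = riSkelMed@populationRI, p = riSkelMed@pValue),
    riPresynapseMedian = c(ri = riPresynMed@populationRI,
                           p = riPresynMed@pValue),
    sweep = sweep,
    bias = list(observed = bias$observed, nullMean = mean(bias$null),
                p = bias$p),
    compartmentRI = c(ri = compRI@populationRI, p = compRI@pValue),
    compartmentRIControl = c(ri = compRIControl@populationRI,
                             p = compRIControl@pValue),
    rfPeaks = do.call(rbind, lapply(rfs, function(r) r$peak)))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    writeConnectome(connectome, file.path(config$out, "connectome"))
    utils::write.csv(sweep, file.path(config$out, "projection_sweep.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(result[setdiff(names(result), "sweep")],
                         file.path(config$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  result
}
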