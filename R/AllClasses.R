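#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' PointMapping: paired positions of the same ids in two metric spaces
#'
#' The substrate of the Retinotopy Index. Each id has a position in a source
#' space (for example, dendrite centers on the eye sheet) and a position in a
#' target space (for example, axon positions along the glomerulus). Either
#' space may instead be described directly by a symmetric distance matrix,
#' which lets arbitrary metrics (such as the presynapse-based distance)
#' feed the same rank-inversion machinery.
#'
#' @slot ids character vector of at least three unique identifiers.
#' @slot source,target coordinate matrices (rows = ids) or `NULL` when the
#'   corresponding distance matrix was supplied directly.
#' @slot sourceDist,targetDist symmetric distance matrices with zero
#'   diagonal, rows/columns ordered as `ids`.
#' @slot metric length-2 character vector naming the metric used in each
#'   space (`"euclidean"`, `"greatcircle"`, or `"precomputed"`).
#' @seealso [pointMapping()], [riPopulation()]
#' @export
setClass("PointMapping",
  representation(ids = "character",
                 source = "matrixOrNULL", target = "matrixOrNULL",
                 sourceDist = "matrix", targetDist = "matrix",
                 metric = "character"),
  validity = function(object) {
    n <- length(object@ids)
    if (n < 3L) return("a PointMapping needs at least 3 ids")
    if (anyDuplicated(object@ids)) return("ids must be unique")
    for (nm in c("sourceDist", "targetDist")) {
      d <- slot(object, nm)
      if (!all(dim(d) == n)) return(sprintf("%s must be %d x %d", nm, n, n))
      if (!all(is.finite(d))) return(sprintf("%s has non-finite entries", nm))
      if (max(abs(d - t(d))) > 1e-8) return(sprintf("%s is not symmetric", nm))
      if (any(diag(d) != 0)) return(sprintf("%s diagonal must be zero", nm))
    }
    TRUE
  })

#' RIResult: per-point and population Retinotopy Index
#'
#' @slot perPointRI named numeric in [-1, 1], one value per reference point:
#'   RI_i = 1 - S_i / A.
#' @slot populationRI arithmetic mean of the per-point values.
#' @slot swaps named integer vector of inversion counts S_i.
#' @slot expectedSwaps the normalization A = (N-1)(N-2)/4.
#' @slot pValue two-sided p-value for the null that the RI population is
#'   centered at zero (approximate: per-point values share points and are
#'   therefore statistically dependent).
#' @slot n number of points in the mapping.
#' @seealso [riPopulation()]
#' @export
setClass("RIResult",
  representation(perPointRI = "numeric", populationRI = "numeric",
                 swaps = "numeric", expectedSwaps = "numeric",
                 pValue = "numeric", n = "integer"),
  validity = function(object) {
    if (any(object@perPointRI < -1 - 1e-9 | object@perPointRI > 1 + 1e-9))
      return("per-point RI values must lie in [-1, 1]")
    if (abs(object@populationRI - mean(object@perPointRI)) > 1e-9)
      return("populationRI must be the mean of perPointRI")
    TRUE
  })

#' Skeleton: a rooted tree of 3-D nodes for one neuron
#'
#' Node coordinates are in nanometres. Exactly one node is the root
#' (`parent_id` is `NA`); parent links must form a tree.
#'
#' @slot nodes data.frame with columns `node_id`, `parent_id`, `x`, `y`, `z`,
#'   `radius`, `label` (one of `dendrite`, `axon`, `soma`, `unlabeled`).
#' @slot neuronId character identifier of the neuron.
#' @seealso [skeleton()], [readSWC()], [resampleSkeleton()]
#' @export
setClass("Skeleton",
  representation(nodes = "data.frame", neuronId = "character"),
  validity = function(object) {
    nd <- object@nodes
    need <- c("node_id", "parent_id", "x", "y", "z", "radius", "label")
    if (!all(need %in% names(nd))) return("missing node columns")
    if (anyDuplicated(nd$node_id)) return("duplicate node ids")
    roots <- is.na(nd$parent_id)
    if (sum(roots) != 1L) return("a skeleton must have exactly one root")
    if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")]))))
      return("node coordinates must be finite")
    idx <- match(nd$parent_id, nd$node_id)
    if (any(is.na(idx) & !roots))
      return(paste("dangling parent reference at node",
                   nd$node_id[which(is.na(idx) & !roots)[1]]))
    if (any(!is.na(idx) & idx == seq_len(nrow(nd))))
      return(paste("node is its own parent:",
                   nd$node_id[which(!is.na(idx) & idx == seq_len(nrow(nd)))[1]]))
    # cycle check: every node must reach the root
    depth <- rep(NA_integer_, nrow(nd))
    depth[roots] <- 0L
    for (it in seq_len(nrow(nd))) {
      todo <- is.na(depth) & !is.na(depth[idx])
      if (!any(todo)) break
      depth[todo] <- depth[idx[todo]] + 1L
    }
    if (anyNA(depth))
      return(paste("cycle detected involving node ids:",
                   paste(nd$node_id[is.na(depth)], collapse = ", ")))
    TRUE
  })

#' SynapseTable: presynaptic sites and pre-to-post connection records
#'
#' `post_id` may be `NA` for bare presynaptic sites. Duplicated rows are
#' legitimate (synapses in the fly are commonly polyadic).
#'
#' @slot synapses data.frame with columns `pre_id`, `post_id`, `x`, `y`, `z`
#'   (coordinates in nm).
#' @seealso [synapseTable()], [readSynapses()]
#' @export
setClass("SynapseTable",
  representation(synapses = "data.frame"),
  validity = function(object) {
    sy <- object@synapses
    need <- c("pre_id", "post_id", "x", "y", "z")
    if (!all(need %in% names(sy))) return("missing synapse columns")
    if (nrow(sy) && !all(is.finite(as.matrix(sy[, c("x", "y", "z")]))))
      return("synapse coordinates must be finite")
    TRUE
  })

#' LongAxis: the long axis of a glomerulus
#'
#' First principal axis of a presynapse point cloud: positions throughout the
#' package are projected onto this axis before median, compartment, and
#' slice analyses.
#'
#' @slot origin centroid of the cloud (nm).
#' @slot direction unit 3-vector.
#' @slot extent range of projected presynapse positions (nm).
#' @slot eigenvalues PCA variances, descending.
#' @slot nearIsotropic TRUE when the top two eigenvalues are within 5%,
#'   i.e. the axis direction is poorly determined.
#' @seealso [glomerulusLongAxis()]
#' @export
setClass("LongAxis",
  representation(origin = "numeric", direction = "numeric",
                 extent = "numeric", eigenvalues = "numeric",
                 nearIsotropic = "logical"),
  validity = function(object) {
    if (abs(sum(object@direction^2) - 1) > 1e-8)
      return("direction must have unit norm")
    TRUE
  })

#' CompartmentPartition: equal-synapse compartments along the long axis
#'
#' @slot boundaries k - 1 non-decreasing scalars along the axis (nm).
#' @slot assignment integer compartment index per presynapse, 1..k.
#' @slot k number of compartments.
#' @slot degenerate TRUE when tied positions straddle a boundary (assignment
#'   is still deterministic: ties go to the lower compartment in input order).
#' @seealso [partitionCompartments()]
#' @export
setClass("CompartmentPartition",
  representation(boundaries = "numeric", assignment = "integer",
                 k = "integer", degenerate = "logical"),
  validity = function(object) {
    if (is.unsorted(object@boundaries)) return("boundaries must be non-decreasing")
    cnt <- tabulate(object@assignment, nbins = object@k)
    if (diff(range(cnt)) > 1L)
      return("compartment synapse counts may differ by at most 1")
    TRUE
  })

#' ConnectivityMatrix: grouped synapse-count matrix
#'
#' @slot counts numeric matrix of synapse totals, pre groups in rows, post
#'   groups in columns; cell-pair counts below `threshold` were zeroed
#'   before grouping.
#' @slot threshold minimum per cell-pair synapse count retained.
#' @slot cellCounts named integer, number of cells per group.
#' @slot raw data.frame of ungrouped per-cell-pair counts (archived,
#'   including below-threshold pairs).
#' @seealso [buildConnectivityMatrix()]
#' @export
setClass("ConnectivityMatrix",
  representation(counts = "matrix", threshold = "numeric",
                 cellCounts = "integer", raw = "data.frame"),
  validity = function(object) {
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  })

#' RFGrid: a receptive-field density on a regular eye-coordinate grid
#'
#' @slot lon,lat grid axis values in degrees (regular spacing).
#' @slot values non-negative matrix, `length(lon)` x `length(lat)`.
#' @slot provenance one of `anatomical`, `functional`, `compartment`,
#'   `population`.
#' @seealso [anatomicalRF()], [rfContour()]
#' @export
setClass("RFGrid",
  representation(lon = "numeric", lat = "numeric", values = "matrix",
                 provenance = "character"),
  validity = function(object) {
    if (!all(dim(object@values) == c(length(object@lon), length(object@lat))))
      return("values must be length(lon) x length(lat)")
    if (any(object@values < 0)) return("values must be non-negative")
    for (ax in list(object@lon, object@lat)) {
      if (length(ax) > 2 && diff(range(diff(ax))) > 1e-6)
        return("grid axes must be regularly spaced")
    }
    TRUE
  })

#' ConnectomeConfig: parameters of the synthetic connectome generator
#'
#' The generator emulates a population of visual projection neurons (by
#' default 65, the LC6 census) whose dendrites tile one eye's field of view
#' with higher density near the visual midline and whose axons converge into
#' an elongated glomerulus. `scramble` interpolates between perfect
#' retinotopy of the axon placement (0) and a fully random placement (1) by
#' rank mixing. See [generateConnectome()].
#'
#' @slot nNeurons number of projection neurons.
#' @slot gridShape c(rows, cols) of the dendrite lattice (rows span latitude).
#' @slot jitterSd isotropic Gaussian jitter of dendrite centers, degrees.
#' @slot scramble fraction in [0, 1] mixing latitude rank with a random rank.
#' @slot axisCoupling correlation in [-1, 1] between the (scramble-mixed)
#'   eye latitude rank and axon length in the glomerulus.
#' @slot presynPerNeuron presynaptic sites per neuron.
#' @slot lcLcDecayScale length scale (degrees of eye distance) of the
#'   distance-decayed neuron-to-neuron synapse probability.
#' @slot lcLcTotal expected total neuron-to-neuron synapse count.
#' @slot midlineSlope slope of the linear dendrite-density gradient in
#'   longitude (0 = uniform, 1 = density falling to zero at the lateral edge).
#' @slot glomLength,glomRadius cylinder model of the glomerulus, nm.
#' @slot nodeSpacing skeleton node spacing, nm.
#' @slot targetSpecs list of target neuron specs: each a list with `center`
#'   (lon, lat degrees), `spread` (degrees), `total` (synapse count),
#'   `transmitter` (`excitatory` or `inhibitory`).
#' @slot seed integer; identical config + seed gives byte-identical output.
#' @export
setClass("ConnectomeConfig",
  representation(nNeurons = "integer", gridShape = "integer",
                 jitterSd = "numeric", scramble = "numeric",
                 axisCoupling = "numeric", presynPerNeuron = "integer",
                 lcLcDecayScale = "numeric", lcLcTotal = "numeric",
                 midlineSlope = "numeric", glomLength = "numeric",
                 glomRadius = "numeric", nodeSpacing = "numeric",
                 targetSpecs = "list", seed = "integer"),
  validity = function(object) {
    if (object@nNeurons < 3L) return("need at least 3 neurons")
    if (prod(object@gridShape) < object@nNeurons)
      return("gridShape must provide at least nNeurons lattice points")
    if (object@scramble < 0 || object@scramble > 1)
      return("scramble must lie in [0, 1]")
    if (abs(object@axisCoupling) > 1) return("axisCoupling must lie in [-1, 1]")
    if (object@jitterSd < 0) return("jitterSd must be >= 0")
    if (object@presynPerNeuron < 1L) return("presynPerNeuron must be positive")
    if (object@midlineSlope < 0 || object@midlineSlope > 1)
      return("midlineSlope must lie in [0, 1]")
    for (ts in object@targetSpecs) {
      if (!all(c("center", "spread", "total", "transmitter") %in% names(ts)))
        return("each target spec needs center, spread, total, transmitter")
      if (ts$total < 1) return("target total_synapses must be positive")
      if (ts$spread < 0) return("target rf spread must be >= 0")
      if (!ts$transmitter %in% c("excitatory", "inhibitory"))
        return("transmitter must be excitatory or inhibitory")
    }
    TRUE
  })

#' SyntheticConnectome: a generated connectome with ground truth
#'
#' Container for everything the analysis stages consume, plus a `truth`
#' record of the generating parameters for parameter-recovery tests.
#'
#' @slot neurons named list of [Skeleton-class] objects.
#' @slot eyeCenters matrix (lon, lat degrees), one row per neuron.
#' @slot presynapses [SynapseTable-class] of presynaptic sites (post `NA`).
#' @slot lcLcSynapses [SynapseTable-class] of neuron-to-neuron synapses.
#' @slot targetCounts matrix of synapse counts, targets x neurons.
#' @slot truth list of generating parameters (axis ranks, axon tips, true RF
#'   centers, scramble, coupling).
#' @slot config the [ConnectomeConfig-class] used.
#' @seealso [generateConnectome()]
#' @export
setClass("SyntheticConnectome",
  representation(neurons = "list", eyeCenters = "matrix",
                 presynapses = "SynapseTable", lcLcSynapses = "SynapseTable",
                 targetCounts = "matrix", truth = "list",
                 config = "ConnectomeConfig"),
  validity = function(object) {
    ids <- names(object@neurons)
    if (!identical(rownames(object@eyeCenters), ids))
      return("eyeCenters rows must match neuron names")
    syn <- rbind(object@presynapses@synapses, object@lcLcSynapses@synapses)
    bad <- setdiff(stats::na.omit(c(syn$pre_id, syn$post_id)), ids)
    if (length(bad))
      return(paste("synapses reference unknown neurons:",
                   paste(utils::head(bad, 3), collapse = ", ")))
    TRUE
  })
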