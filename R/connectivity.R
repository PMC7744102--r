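# Synapse tables, connectivity matrices, and the connectivity-bias
# statistics: the distance-weighted neuron-to-neuron shuffle test, the
# presynapse-based distance metric, compartment RI, target-proximity
# profiles, and synapse density per unit cable.

#' Construct a SynapseTable
#'
#' @param synapses data.frame with columns `pre_id`, `post_id` (`NA`
#'   allowed for bare presynaptic sites), `x`, `y`, `z` (nm). Duplicate
#'   rows are preserved: synapses are commonly polyadic.
#' @return A [SynapseTable-class].
#' @export
synapseTable <- function(synapses) {
  synapses <- as.data.frame(synapses)
  if (is.null(synapses$post_id)) synapses$post_id <- NA_character_
  synapses$pre_id <- as.character(synapses$pre_id)
  synapses$post_id <- as.character(synapses$post_id)
  new("SynapseTable",
      synapses = synapses[, c("pre_id", "post_id", "x", "y", "z")])
}

setMethod("show", "SynapseTable", function(object) {
  sy <- object@synapses
  cat(sprintf("SynapseTable: %d sites (%d with postsynaptic partner), %d pre neurons\n",
              nrow(sy), sum(!is.na(sy$post_id)),
              length(unique(sy$pre_id))))
})

#' Read a synapse table from CSV
#'
#' Expects a header with columns `pre_id`, `post_id`, `x_nm`, `y_nm`,
#' `z_nm`; `post_id` may be empty for bare presynaptic sites.
#'
#' @param path CSV file path.
#' @return A [SynapseTable-class].
#' @export
readSynapses <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(pre_id = "character",
                                              post_id = "character"))
  need <- c("pre_id", "post_id", "x_nm", "y_nm", "z_nm")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("synapse CSV is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("x_nm", "y_nm", "z_nm")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v) && nrow(tab))
      stop(sprintf("non-numeric %s at line %d", cc, which(is.na(v))[1] + 1L))
    tab[[cc]] <- v
  }
  tab$post_id[tab$post_id %in% c("", "NA")] <- NA_character_
  synapseTable(data.frame(pre_id = tab$pre_id, post_id = tab$post_id,
                          x = tab$x_nm, y = tab$y_nm, z = tab$z_nm))
}

#' Write a synapse table to CSV
#' @param syn a [SynapseTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSynapses <- function(syn, path) {
  sy <- syn@synapses
  utils::write.csv(data.frame(pre_id = sy$pre_id,
                              post_id = ifelse(is.na(sy$post_id), "",
                                               sy$post_id),
                              x_nm = sy$x, y_nm = sy$y, z_nm = sy$z),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a grouped connectivity matrix
#'
#' Synapses are counted per pre/post cell pair, pairs below the threshold
#' are zeroed (but archived in the `raw` slot), and the surviving counts
#' are summed within (cell type, side) groups.
#'
#' @param synapses a [SynapseTable-class]; rows without a post partner are
#'   ignored.
#' @param typeMap data.frame with columns `id`, `type`, `side` covering
#'   every neuron id appearing in the synapse table.
#' @param threshold minimum per cell-pair synapse count retained
#'   (default 0; a common choice for target analyses is 15).
#' @return A [ConnectivityMatrix-class].
#' @export
buildConnectivityMatrix <- function(synapses, typeMap, threshold = 0) {
  sy <- synapses@synapses
  sy <- sy[!is.na(sy$post_id), , drop = FALSE]
  ids <- unique(c(sy$pre_id, sy$post_id))
  unknown <- setdiff(ids, typeMap$id)
  if (length(unknown))
    stop("ids missing from type map: ", paste(unknown, collapse = ", "))
  grp <- paste(typeMap$type, typeMap$side, sep = ":")
  names(grp) <- typeMap$id
  groups <- sort(unique(grp))
  raw <- if (nrow(sy)) {
    r <- as.data.frame(table(pre = sy$pre_id, post = sy$post_id),
                       stringsAsFactors = FALSE)
    names(r)[3] <- "count"
    r[r$count > 0, , drop = FALSE]
  } else {
    data.frame(pre = character(), post = character(), count = integer())
  }
  kept <- raw[raw$count >= threshold, , drop = FALSE]
  counts <- matrix(0, length(groups), length(groups),
                   dimnames = list(groups, groups))
  if (nrow(kept)) {
    agg <- stats::aggregate(count ~ preGrp + postGrp,
                            data = data.frame(preGrp = grp[kept$pre],
                                              postGrp = grp[kept$post],
                                              count = kept$count),
                            FUN = sum)
    counts[cbind(agg$preGrp, agg$postGrp)] <- agg$count
  }
  new("ConnectivityMatrix", counts = counts, threshold = threshold,
      cellCounts = vapply(split(typeMap$id, grp[typeMap$id]),
                          function(x) length(unique(x)), integer(1)),
      raw = raw)
}

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d groups, threshold %g synapses\n",
              nrow(object@counts), object@threshold))
  print(object@counts)
})

#' Distance-weighted neuron-to-neuron connectivity bias test
#'
#' Are neuron-to-neuron synapses biased toward partners with nearby eye
#' coordinates? For each presynaptic neuron, the distances between dendrite
#' centers (great-circle degrees by default) to its N-1 potential partners
#' are weighted by the pair's synapse count and averaged. The null
#' permutes each neuron's partner-distance vector (synapse counts fixed,
#' positions fixed -- only identity labels are scrambled, so the
#' non-uniform density of dendrite centers is preserved in the null).
#' The p-value is the one-sided fraction of null means at or below the
#' observed mean (biased connectivity means smaller weighted distances).
#'
#' @param eyeCenters matrix (lon, lat degrees) with rownames = neuron ids.
#' @param counts square synapse-count matrix (pre rows, post columns) over
#'   the same ids; the weight of a pair is the total count in both
#'   directions.
#' @param nShuffles number of shuffles (>= 100).
#' @param seed integer seed.
#' @param metric `"greatcircle"` (default) or `"euclidean"` (chordal
#'   fallback).
#' @return list with `observed` (mean over neurons of the weighted mean
#'   distance), `perNeuron`, `null` (vector of shuffled means), and `p`.
#' @export
lcLcDistanceBias <- function(eyeCenters, counts, nShuffles = 1000,
                             seed = NULL, metric = "greatcircle") {
  ids <- rownames(eyeCenters)
  if (is.null(ids) || !identical(rownames(counts), ids) ||
      !identical(colnames(counts), ids))
    stop("counts must be a square matrix over the eyeCenters ids")
  if (nrow(eyeCenters) < 2) stop("need at least 2 neurons")
  if (nShuffles < 100) stop("use at least 100 shuffles")
  W <- counts + t(counts)
  diag(W) <- 0
  if (all(W == 0)) stop("all synapse counts are zero: weighted mean undefined")
  D <- metricDist(eyeCenters, metric)
  n <- length(ids)
  wmean <- function(Dm) {
    num <- rowSums(Dm * W); den <- rowSums(W)
    num[den > 0] / den[den > 0]
  }
  perNeuron <- wmean(D)
  observed <- mean(perNeuron)
  null <- withSeed(seed, vapply(seq_len(nShuffles), function(s) {
    # permute each neuron's partner distances, keeping the diagonal at 0
    Dp <- D
    for (i in seq_len(n)) {
      oth <- setdiff(seq_len(n), i)
      Dp[i, oth] <- D[i, oth[sample(n - 1L)]]
    }
    mean(wmean(Dp))
  }, numeric(1)))
  # mid-p: ties between null and observed count half, so a weight-invariant
  # (uniform) connectivity gives p = 0.5 rather than 1
  list(observed = observed, perNeuron = perNeuron, null = null,
       p = mean(null < observed) + 0.5 * mean(null == observed))
}

#' Presynapse-based distance between two neurons
#'
#' For every presynapse of neuron A, the distance to the closest presynapse
#' of neuron B is found; the same is done from B into A, and the pooled
#' mean over all presynapses of both neurons is returned. Symmetric by
#' construction and zero for identical clouds; the triangle inequality is
#' not guaranteed.
#'
#' @param presynA,presynB non-empty 3-column coordinate matrices (nm).
#' @return scalar distance in nm.
#' @export
presynapseDistance <- function(presynA, presynB) {
  a <- as.matrix(presynA); b <- as.matrix(presynB)
  if (!nrow(a) || !nrow(b)) stop("empty presynapse set")
  D <- crossDist(a, b)
  mean(c(apply(D, 1, min), apply(D, 2, min)))
}

# Pairwise presynapse-distance matrix across a list of point clouds.
presynapseDistanceMatrix <- function(clouds) {
  n <- length(clouds)
  D <- matrix(0, n, n, dimnames = list(names(clouds), names(clouds)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- presynapseDistance(clouds[[i]], clouds[[j]])
  }
  D
}

#' Retinotopy Index of presynapse organization within compartments
#'
#' Tests for fine-scale retinotopy among presynapses: the source space is
#' the neurons' eye centers, the target space is the neurons under the
#' presynapse-based distance ([presynapseDistance()]) restricted to the
#' selected compartments. With `randomize = TRUE` the neuron identities of
#' the presynapse clouds are permuted first, giving the randomized control.
#'
#' @param presynapses data.frame with columns `neuron_id`, `x`, `y`, `z`
#'   and `compartment` (integer), e.g. presynapse coordinates joined with a
#'   [partitionCompartments()] assignment.
#' @param eyeCenters matrix (lon, lat) with rownames = neuron ids.
#' @param compartments integer vector of compartment indices to include.
#' @param randomize permute cloud identities first (control)?
#' @param seed integer seed for the control permutation.
#' @param eyeMetric metric for the eye space.
#' @return An [RIResult-class].
#' @export
compartmentRI <- function(presynapses, eyeCenters, compartments,
                          randomize = FALSE, seed = NULL,
                          eyeMetric = "greatcircle") {
  sel <- presynapses[presynapses$compartment %in% compartments, ,
                     drop = FALSE]
  clouds <- lapply(split(sel[, c("x", "y", "z")], sel$neuron_id), as.matrix)
  if (length(clouds) < 3)
    stop("invalid size: selected compartments cover fewer than 3 neurons")
  ids <- names(clouds)
  if (randomize)
    names(clouds) <- withSeed(seed, sample(ids))
  clouds <- clouds[ids]
  D <- presynapseDistanceMatrix(clouds)
  riPopulation(pointMapping(eyeCenters[ids, , drop = FALSE], D, ids = ids,
                            metric = c(eyeMetric, "euclidean"),
                            precomputed = c(FALSE, TRUE)))
}

#' Target-to-projection-neuron proximity profile along the glomerulus
#'
#' The glomerulus is divided into slices along its long axis. Within each
#' slice every projection neuron's axon is reduced to a unique position
#' (the mean of its in-slice nodes), all target nodes falling in the slice
#' are collected, and the mean distance over all projection-node x
#' target-node pairs is reported per group of projection neurons. Slices
#' without target nodes are reported as `NA`, not zero.
#'
#' @param targetSkel the target neuron [Skeleton-class] (resampled).
#' @param lcSkels named list of projection-neuron skeletons (resampled).
#' @param axis a [LongAxis-class]; slices start at `axis@extent[1]`.
#' @param sliceThickness slice thickness in nm (default 1000).
#' @param nSlices number of slices (default 80).
#' @param groups named list mapping group label to character vectors of
#'   `lcSkels` names; default puts every neuron in one group `all`.
#' @return data.frame with columns `slice`, `s0`, `s1`, one distance column
#'   per group, and `nTargetNodes`.
#' @export
targetProximityProfile <- function(targetSkel, lcSkels, axis,
                                   sliceThickness = 1000, nSlices = 80,
                                   groups = NULL) {
  if (is.null(groups)) groups <- list(all = names(lcSkels))
  breaks <- axis@extent[1] + sliceThickness * (0:nSlices)
  tXyz <- nodeCoords(targetSkel)
  tS <- projectOntoAxis(tXyz, axis)
  lcXyz <- lapply(lcSkels, nodeCoords)
  lcS <- lapply(lcSkels, projectOntoAxis, axis = axis)
  out <- lapply(seq_len(nSlices), function(k) {
    inT <- tS >= breaks[k] & tS < breaks[k + 1]
    row <- list(slice = k, s0 = breaks[k], s1 = breaks[k + 1])
    # unique position per projection neuron in this slice
    lcPos <- t(vapply(names(lcSkels), function(nm) {
      sel <- lcS[[nm]] >= breaks[k] & lcS[[nm]] < breaks[k + 1]
      if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
      colMeans(lcXyz[[nm]][sel, , drop = FALSE])
    }, numeric(3)))
    for (g in names(groups)) {
      pos <- lcPos[intersect(groups[[g]], rownames(lcPos)), , drop = FALSE]
      pos <- pos[!is.na(pos[, 1]), , drop = FALSE]
      row[[g]] <- if (!any(inT) || !nrow(pos)) NA_real_
      else mean(crossDist(pos, tXyz[inT, , drop = FALSE]))
    }
    row$nTargetNodes <- sum(inT)
    as.data.frame(row)
  })
  do.call(rbind, out)
}

#' Synapse density per unit cable along the glomerulus
#'
#' Synapses are assigned to the nearest skeleton node; cable length per
#' slice is computed by clipping each skeleton edge to the slice along the
#' long axis. Density is synapse count divided by cable length, and the
#' summary is the maximum relative deviation of the per-slice density from
#' its mean.
#'
#' @param targetSkel a resampled [Skeleton-class].
#' @param synapses 3-column coordinate matrix of synapse positions on this
#'   neuron (nm).
#' @param axis a [LongAxis-class].
#' @param nSlices number of slices spanning the skeleton's projected extent.
#' @return list with `profile` (data.frame: slice, cable_nm, count,
#'   density) and `maxRelDeviation`.
#' @export
synapseDensityPerCable <- function(targetSkel, synapses, axis,
                                   nSlices = 10) {
  xyz <- nodeCoords(targetSkel)
  nodeS <- projectOntoAxis(xyz, axis)
  breaks <- seq(min(nodeS), max(nodeS), length.out = nSlices + 1)
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  syn <- as.matrix(synapses)
  nearest <- apply(crossDist(syn, xyz), 1, which.min)
  synS <- nodeS[nearest]
  counts <- vapply(seq_len(nSlices), function(k)
    sum(synS >= breaks[k] & synS < breaks[k + 1]), numeric(1))
  # clip each edge's projected interval to the slices
  nd <- targetSkel@nodes
  pidx <- match(nd$parent_id, nd$node_id)
  keep <- !is.na(pidx)
  eLen <- sqrt(rowSums((xyz[keep, , drop = FALSE] -
                        xyz[pidx[keep], , drop = FALSE])^2))
  s1 <- pmin(nodeS[keep], nodeS[pidx[keep]])
  s2 <- pmax(nodeS[keep], nodeS[pidx[keep]])
  cable <- vapply(seq_len(nSlices), function(k) {
    ov <- pmax(0, pmin(s2, breaks[k + 1]) - pmax(s1, breaks[k]))
    span <- s2 - s1
    frac <- ifelse(span > 0, ov / span,
                   as.numeric(s1 >= breaks[k] & s1 < breaks[k + 1]))
    sum(eLen * frac)
  }, numeric(1))
  if (any(counts > 0 & cable == 0))
    stop("synapses assigned to a slice with zero cable")
  dens <- ifelse(cable > 0, counts / cable, NA_real_)
  m <- mean(dens, na.rm = TRUE)
  list(profile = data.frame(slice = seq_len(nSlices),
                            cable_nm = cable, count = counts,
                            density = dens),
       maxRelDeviation = max(abs(dens - m), na.rm = TRUE) / m)
}
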