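# Geometry of axons inside the glomerulus: cross-section positions with
# reference-pair normalization, the glomerulus long axis, median and
# axon-tip positions, and equal-synapse compartments.

#' Cross-section positions of axons with reference-pair normalization
#'
#' Each skeleton's position at a planar cross-section is the mean of its
#' nodes inside a slab of the given thickness around the plane, projected
#' onto the plane. The 2-D positions are then put in a canonical frame by
#' the similarity transform (translation, rotation, uniform scaling) that
#' sends the first reference neuron to (0, 0) and the second to (0, 1);
#' this removes any rigid transform of the raw coordinates. Skeletons not
#' intersecting the slab are omitted and reported in the `omitted`
#' attribute. Skeletons should be resampled first so the node mean is an
#' arclength-weighted position.
#'
#' @param skels named list of [Skeleton-class] objects.
#' @param planePoint,planeNormal a point on the plane and its normal (nm).
#' @param thickness slab thickness in nm (default 1000; membership uses the
#'   closed interval of half-thickness on either side).
#' @param refPair character vector of two skeleton names defining the
#'   (0, 0) / (0, 1) reference pair; both must intersect the slab.
#' @return matrix of normalized 2-D positions, one row per intersecting
#'   skeleton, with attribute `omitted` (names of skeletons missing from
#'   the slab).
#' @export
crossSectionPositions <- function(skels, planePoint, planeNormal,
                                  thickness = 1000, refPair) {
  n <- planeNormal / sqrt(sum(planeNormal^2))
  e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  pos <- t(vapply(skels, function(sk) {
    xyz <- nodeCoords(sk)
    d <- drop((xyz - matrix(planePoint, nrow(xyz), 3, byrow = TRUE)) %*% n)
    inSlab <- abs(d) <= thickness / 2
    if (!any(inSlab)) return(c(NA_real_, NA_real_))
    m <- colMeans(xyz[inSlab, , drop = FALSE]) - planePoint
    c(sum(m * e1), sum(m * e2))
  }, numeric(2)))
  rownames(pos) <- names(skels)
  omitted <- rownames(pos)[is.na(pos[, 1])]
  pos <- pos[!is.na(pos[, 1]), , drop = FALSE]
  miss <- setdiff(refPair, rownames(pos))
  if (length(miss))
    stop("reference neuron(s) absent from the slab: ",
         paste(miss, collapse = ", "))
  # similarity transform in the complex plane: ref1 -> 0, ref2 -> i
  z <- complex(real = pos[, 1], imaginary = pos[, 2])
  names(z) <- rownames(pos)
  denom <- z[refPair[2]] - z[refPair[1]]
  if (Mod(denom) == 0) stop("reference neurons coincide in this section")
  w <- (z - z[refPair[1]]) / denom * 1i
  out <- cbind(Re(w), Im(w))
  rownames(out) <- rownames(pos)
  colnames(out) <- c("u", "v")
  attr(out, "omitted") <- omitted
  out
}

#' Long axis of the glomerulus from its presynapse cloud
#'
#' The direction is the first principal axis of the presynapse positions,
#' the canonical elongation axis of a point cloud; the origin is the
#' centroid and the extent is the range of projected positions. The sign is
#' fixed so the direction's largest-magnitude component is positive. When
#' the top two eigenvalues are within 5% the cloud is nearly isotropic and
#' the axis direction is arbitrary; this is flagged.
#'
#' @param presynapses a [SynapseTable-class] or a 3-column coordinate
#'   matrix (nm).
#' @return A [LongAxis-class].
#' @export
glomerulusLongAxis <- function(presynapses) {
  xyz <- if (is(presynapses, "SynapseTable"))
    as.matrix(presynapses@synapses[, c("x", "y", "z")])
  else as.matrix(presynapses)
  if (nrow(xyz) < 3) stop("degenerate cloud: need at least 3 presynapses")
  pc <- stats::prcomp(xyz, center = TRUE)
  if (pc$sdev[1] == 0) stop("degenerate cloud: no spatial spread")
  dir <- pc$rotation[, 1]
  dir <- dir * sign(dir[which.max(abs(dir))])
  s <- drop((xyz - matrix(pc$center, nrow(xyz), 3, byrow = TRUE)) %*% dir)
  ev <- pc$sdev^2
  new("LongAxis", origin = pc$center, direction = unname(dir),
      extent = range(s), eigenvalues = unname(ev),
      nearIsotropic = length(ev) > 1 && ev[2] >= 0.95 * ev[1])
}

setMethod("show", "LongAxis", function(object) {
  cat(sprintf("LongAxis: direction (%.3f, %.3f, %.3f), extent %.1f um%s\n",
              object@direction[1], object@direction[2], object@direction[3],
              diff(object@extent) / 1000,
              if (object@nearIsotropic) " [near-isotropic]" else ""))
})

#' Project points onto a long axis
#' @param points 3-column coordinate matrix, [SynapseTable-class], or
#'   [Skeleton-class].
#' @param axis a [LongAxis-class].
#' @return numeric vector of scalar axis positions (nm).
#' @export
projectOntoAxis <- function(points, axis) {
  xyz <- if (is(points, "Skeleton")) nodeCoords(points)
  else if (is(points, "SynapseTable"))
    as.matrix(points@synapses[, c("x", "y", "z")])
  else as.matrix(points)
  if (!nrow(xyz)) return(numeric(0))
  drop((xyz - matrix(axis@origin, nrow(xyz), 3, byrow = TRUE)) %*%
         axis@direction)
}

#' Median position along the glomerulus long axis
#'
#' The median of the projections of either a skeleton's nodes (resample and
#' restrict to the glomerulus first, so node density reflects cable
#' density) or a set of presynapse positions.
#'
#' @param x a [Skeleton-class], [SynapseTable-class], or coordinate matrix.
#' @param axis a [LongAxis-class].
#' @return scalar median axis position (nm).
#' @export
medianAxisPosition <- function(x, axis) {
  s <- projectOntoAxis(x, axis)
  if (!length(s)) stop("empty node/synapse set")
  stats::median(s)
}

#' Axon tip position
#'
#' The mean position of the ceiling(fraction * n) skeleton nodes farthest
#' from the glomerulus entry. "Farthest" is measured by default along the
#' arbor (geodesic distance from the node nearest the entry point), which
#' is robust to curled axons; straight-line Euclidean distance from the
#' entry point is available via `distance = "euclidean"`. Restrict the
#' skeleton to the glomerulus and resample before calling.
#'
#' @param skel a [Skeleton-class] with at least 10 nodes.
#' @param entryPoint 3-D glomerulus entry landmark (nm).
#' @param fraction fraction of nodes to average (default 0.1).
#' @param distance `"geodesic"` or `"euclidean"`.
#' @return length-3 numeric tip position (nm).
#' @export
axonTipPosition <- function(skel, entryPoint, fraction = 0.1,
                            distance = c("geodesic", "euclidean")) {
  distance <- match.arg(distance)
  xyz <- nodeCoords(skel)
  n <- nrow(xyz)
  if (n < 10) stop("too few nodes: need at least 10")
  if (distance == "geodesic") {
    entryRow <- which.min(rowSums((xyz - matrix(entryPoint, n, 3,
                                                byrow = TRUE))^2))
    d <- geodesicDistances(skel, entryRow)
  } else {
    d <- sqrt(rowSums((xyz - matrix(entryPoint, n, 3, byrow = TRUE))^2))
  }
  k <- ceiling(fraction * n)
  top <- order(d, decreasing = TRUE)[seq_len(k)]
  unname(colMeans(xyz[top, , drop = FALSE]))
}

#' Partition presynapses into equal-count compartments along the long axis
#'
#' Boundaries sit at the j/k quantiles of the projected presynapse
#' positions, so each compartment holds floor(n/k) or ceiling(n/k)
#' presynapses. Positions tied at a boundary are assigned to the lower
#' compartment in input order; a partition where ties straddle a boundary
#' is flagged degenerate.
#'
#' @param presynapses a [SynapseTable-class] or 3-column coordinate matrix.
#' @param axis a [LongAxis-class].
#' @param k number of compartments (default 10).
#' @return A [CompartmentPartition-class].
#' @export
partitionCompartments <- function(presynapses, axis, k = 10) {
  s <- projectOntoAxis(presynapses, axis)
  n <- length(s)
  if (n < k) stop("invalid size: fewer presynapses than compartments")
  r <- rank(s, ties.method = "first")
  comp <- as.integer(ceiling(r * k / n))
  bnd <- stats::quantile(s, probs = seq_len(k - 1) / k, names = FALSE,
                         type = 1)
  degenerate <- any(vapply(seq_len(k - 1), function(j) {
    hi <- max(s[comp == j]); any(s[comp == j + 1L] == hi)
  }, logical(1)))
  new("CompartmentPartition", boundaries = bnd, assignment = comp,
      k = as.integer(k), degenerate = degenerate)
}

#' Glomerulus membership mask from the presynapse cloud
#'
#' The glomerulus volume is demarcated by the presynapse positions: the
#' mask is their principal-axes bounding box dilated by a margin. Returns a
#' predicate usable to restrict skeleton nodes to the glomerulus.
#'
#' @param presynapses a [SynapseTable-class] or 3-column coordinate matrix.
#' @param margin dilation in nm (default 1000).
#' @return function mapping an n x 3 coordinate matrix to a logical vector.
#' @export
glomerulusMask <- function(presynapses, margin = 1000) {
  xyz <- if (is(presynapses, "SynapseTable"))
    as.matrix(presynapses@synapses[, c("x", "y", "z")])
  else as.matrix(presynapses)
  pc <- stats::prcomp(xyz, center = TRUE)
  sc <- xyz %*% pc$rotation
  lo <- apply(sc, 2, min) - margin
  hi <- apply(sc, 2, max) + margin
  function(points) {
    p <- as.matrix(points) %*% pc$rotation
    apply(t(p) >= lo & t(p) <= hi, 2, all)
  }
}

#' Restrict a skeleton to nodes satisfying a mask
#'
#' Drops nodes outside the mask and reconnects the remaining nodes: a kept
#' node whose parent was dropped becomes a root of its connected piece; the
#' largest piece is returned.
#'
#' @param skel a [Skeleton-class].
#' @param mask predicate from [glomerulusMask()], or a logical vector over
#'   node rows.
#' @return A [Skeleton-class] containing the largest kept component.
#' @export
maskSkeleton <- function(skel, mask) {
  nd <- skel@nodes
  keep <- if (is.function(mask)) mask(nodeCoords(skel)) else mask
  if (!any(keep)) stop("mask removes every node")
  nd <- nd[keep, , drop = FALSE]
  nd$parent_id[!nd$parent_id %in% nd$node_id] <- NA_integer_
  # connected components over remaining parent links
  comp <- seq_len(nrow(nd))
  pidx <- match(nd$parent_id, nd$node_id)
  repeat {
    nxt <- ifelse(is.na(pidx), comp, comp[pidx])
    if (all(nxt == comp)) break
    comp <- nxt
  }
  big <- as.integer(names(which.max(table(comp))))
  skeleton(nd[comp == big, , drop = FALSE], neuronId = skel@neuronId)
}
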