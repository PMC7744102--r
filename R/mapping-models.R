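# Null and synthetic mappings of point sets, and the idealized 1-D
# glomerulus projection: rigid transforms, block/full randomization, and
# the projection-axis sweep.

#' Apply a rigid transform to a 2-D point set
#'
#' Rotation about the origin followed by translation; all pairwise
#' distances are preserved, so the Retinotopy Index against the original
#' point set is exactly 1.
#'
#' @param points two-column matrix.
#' @param rotationDeg rotation angle in degrees (counter-clockwise).
#' @param translation length-2 offset.
#' @return transformed matrix, rownames preserved.
#' @export
applyRigid <- function(points, rotationDeg = 0, translation = c(0, 0)) {
  p <- as.matrix(points)
  if (!all(is.finite(p))) stop("points must be finite")
  th <- deg2rad(rotationDeg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- p %*% t(R)
  out[, 1] <- out[, 1] + translation[1]
  out[, 2] <- out[, 2] + translation[2]
  dimnames(out) <- dimnames(p)
  out
}

#' Randomize point positions within local blocks
#'
#' Tiles the bounding rectangle of the points with `blockRows` x `blockCols`
#' blocks (anchored at the bounding-box minimum) and permutes positions
#' uniformly at random within each block, preserving the global block
#' layout. With one block this is a full randomization; with one point per
#' block it is the identity. Empty blocks are skipped.
#'
#' @param points two-column matrix.
#' @param blockRows,blockCols block tiling counts (rows along the second
#'   coordinate).
#' @param seed integer seed.
#' @return matrix of mapped positions, same rownames/order of ids.
#' @export
blockRandomize <- function(points, blockRows, blockCols, seed = NULL) {
  p <- as.matrix(points)
  rng <- apply(p, 2, range)
  eps <- 1e-9 * pmax(1, rng[2, ] - rng[1, ])
  col <- pmin(blockCols, 1L + floor((p[, 1] - rng[1, 1]) /
                                      ((rng[2, 1] - rng[1, 1] + eps[1]) / blockCols)))
  row <- pmin(blockRows, 1L + floor((p[, 2] - rng[1, 2]) /
                                      ((rng[2, 2] - rng[1, 2] + eps[2]) / blockRows)))
  block <- (row - 1L) * blockCols + col
  out <- p
  withSeed(seed, {
    for (b in sort(unique(block))) {
      idx <- which(block == b)
      if (length(idx) > 1) out[idx, ] <- p[idx[sample(length(idx))], ]
    }
  })
  out
}

#' Randomize point positions by a uniform random permutation
#'
#' The completely randomized null mapping: positions are reassigned among
#' ids uniformly at random, so the expected population Retinotopy Index is 0.
#'
#' @param points matrix of positions (any dimension).
#' @param seed integer seed.
#' @return matrix with permuted positions, ids (rownames) kept in place.
#' @export
fullRandomize <- function(points, seed = NULL) {
  p <- as.matrix(points)
  if (nrow(p) < 3) stop("need at least 3 points")
  perm <- withSeed(seed, sample(nrow(p)))
  out <- p[perm, , drop = FALSE]
  rownames(out) <- rownames(p)
  out
}

#' Project eye coordinates onto an idealized 1-D glomerulus axis
#'
#' Points on the eye sphere are rotated about the radial axis through a
#' pivot (default: longitude 73, latitude 0, the mid-point of the lobula)
#' by the projection-axis angle, and their new azimuthal positions are
#' returned. Angle 0 reproduces the anterior-posterior projection (the raw
#' longitudes); on a small patch around the pivot, angle 90 approaches a
#' projection onto latitude. Angles are taken modulo 180 degrees (a
#' line-space has no orientation).
#'
#' @param eyePoints two-column (lon, lat) matrix, degrees.
#' @param angleDeg projection-axis angle in degrees.
#' @param pivot (lon, lat) of the rotation pivot, degrees.
#' @return named numeric vector of 1-D positions (degrees of azimuth).
#' @export
axisProjection <- function(eyePoints, angleDeg, pivot = c(73, 0)) {
  p <- rbind2col(eyePoints)
  angleDeg <- angleDeg %% 180
  v <- eyeToVec(p)
  k <- drop(eyeToVec(pivot))
  rv <- rotateAboutAxis(v, k, -angleDeg)
  if (any(abs(rv[, 3]) > 1 - 1e-9))
    stop("point lands on a rotation pole: azimuth is degenerate")
  out <- vecToEye(rv)[, 1]
  names(out) <- rownames(p)
  out
}

#' Sweep the idealized glomerulus projection axis
#'
#' For each angle, builds the idealized 1-D mapping by [axisProjection()]
#' and scores two Retinotopy Indices: from the eye sheet to the idealized
#' line (how much order any 1-D projection could keep), and from the
#' idealized line to the observed 1-D glomerulus positions (how well that
#' axis explains the observed mapping).
#'
#' @param eyePoints two-column (lon, lat) matrix with rownames = ids.
#' @param glomPositions named numeric, observed 1-D positions along the
#'   glomerulus long axis.
#' @param angles projection angles in degrees.
#' @param pivot passed to [axisProjection()].
#' @param eyeMetric metric for the eye space, `"greatcircle"` (default) or
#'   `"euclidean"`.
#' @return data.frame with one row per angle: `angle`, `riEyeToLine`,
#'   `pEyeToLine`, `riLineToGlom`, `pLineToGlom`.
#' @export
projectionSweep <- function(eyePoints, glomPositions,
                            angles = seq(0, 170, by = 10), pivot = c(73, 0),
                            eyeMetric = "greatcircle") {
  p <- as.matrix(eyePoints)
  ids <- rownames(p)
  if (is.null(ids)) stop("eyePoints must carry ids as rownames")
  if (!all(ids %in% names(glomPositions)))
    stop("glomPositions must cover every eye point id")
  glom <- glomPositions[ids]
  out <- lapply(angles, function(a) {
    line <- axisProjection(p, a, pivot)
    r1 <- riPopulation(pointMapping(p, cbind(line), ids = ids,
                                    metric = c(eyeMetric, "euclidean")))
    r2 <- riPopulation(pointMapping(cbind(line), cbind(glom), ids = ids))
    data.frame(angle = a,
               riEyeToLine = r1@populationRI, pEyeToLine = r1@pValue,
               riLineToGlom = r2@populationRI, pLineToGlom = r2@pValue)
  })
  do.call(rbind, out)
}
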