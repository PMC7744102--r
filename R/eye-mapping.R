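# Mapping dendrites in the 3-D lobula onto eye coordinates: quadratic
# surface fit, geodesic-polar lune parameterization anchored by two
# reference columns, dendrite centers, and coverage polygons.

#' DendriteSurface: quadratic height field fitted through dendrites
#'
#' @slot center centroid of the fitted points (nm).
#' @slot basis 3 x 3 orthonormal frame (columns u, v, w); the surface is
#'   the height field w = f(u, v) over the u-v plane.
#' @slot coefficients the six quadratic coefficients
#'   (1, u, v, u^2, u*v, v^2).
#' @slot rms root-mean-square fit residual (nm).
#' @seealso [fitDendriteSurface()], [mapToEye()]
#' @export
setClass("DendriteSurface",
  representation(center = "numeric", basis = "matrix",
                 coefficients = "numeric", rms = "numeric"))

setMethod("show", "DendriteSurface", function(object) {
  cat(sprintf("DendriteSurface: quadratic fit, rms residual %.1f nm\n",
              object@rms))
})

quadDesign <- function(u, v) cbind(1, u, v, u^2, u * v, v^2)

#' Fit a second-order surface through dendrite nodes
#'
#' A least-squares quadratic height field over the best-fit plane of the
#' point cloud (plane frame from PCA). At least six non-degenerate points
#' are needed for the six coefficients.
#'
#' @param points n x 3 matrix of dendrite node positions (nm), n >= 6.
#' @return A [DendriteSurface-class].
#' @export
fitDendriteSurface <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 6) stop("need at least 6 points for a quadratic surface")
  pc <- stats::prcomp(p, center = TRUE)
  rot <- pc$rotation
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]  # fix frame handedness
  uvw <- sweep(p, 2, pc$center) %*% rot
  X <- quadDesign(uvw[, 1], uvw[, 2])
  if (qr(X)$rank < 6) stop("degenerate point configuration: rank-deficient fit")
  beta <- qr.coef(qr(X), uvw[, 3])
  resid <- uvw[, 3] - X %*% beta
  new("DendriteSurface", center = pc$center, basis = rot,
      coefficients = unname(beta), rms = sqrt(mean(resid^2)))
}

# Surface frame coordinates (u, v, w) of world points.
surfaceUVW <- function(surface, points) {
  sweep(rbind2col(points), 2, surface@center) %*% surface@basis
}

# 3-D world position of surface points given (u, v).
surfacePoint <- function(surface, u, v) {
  w <- drop(quadDesign(u, v) %*% surface@coefficients)
  cbind(u, v, w) %*% t(surface@basis) +
    matrix(surface@center, length(u), 3, byrow = TRUE)
}

# Arclength along the surface of the straight (u,v) path from a to b.
surfaceArclength <- function(surface, a, b, nSteps = 100) {
  t <- seq(0, 1, length.out = nSteps + 1)
  u <- a[1] + t * (b[1] - a[1])
  v <- a[2] + t * (b[2] - a[2])
  p <- surfacePoint(surface, u, v)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Map lobula positions onto eye coordinates
#'
#' Projects queries onto the fitted dendrite surface and maps the surface
#' onto the spherical lune by geodesic polar coordinates about the eye
#' center reference: the on-surface distance to a query becomes the angular
#' distance from the lune anchor, and the angular coordinate (zeroed at the
#' meridian reference, which therefore lands on the central meridian,
#' longitude 0) becomes the bearing. The global scale is set so the
#' meridian reference lands at its known eye position.
#'
#' @param surface a [DendriteSurface-class].
#' @param centerRef 3-D position of the medulla column marking the center
#'   of the eye; must lie near the surface.
#' @param meridianRef 3-D position of the column marking a point on the
#'   central meridian.
#' @param query n x 3 matrix of positions to map (e.g. dendrite centers).
#' @param centerEye eye coordinate the center reference maps to
#'   (default the lune center, lon 0, lat 75).
#' @param meridianEye known eye coordinate of the meridian reference; must
#'   have longitude 0 (default lon 0, lat 115).
#' @param flip mirror the angular coordinate (handedness convention for
#'   right-hemisphere data displayed left).
#' @return n x 2 matrix of (lon, lat) degrees; queries farther than three
#'   rms residuals off the surface trigger a warning with the distance.
#' @export
mapToEye <- function(surface, centerRef, meridianRef, query,
                     centerEye = c(0, 75), meridianEye = c(0, 115),
                     flip = FALSE) {
  if (meridianEye[1] != 0)
    stop("the meridian reference must map onto the central meridian (lon 0)")
  refs <- surfaceUVW(surface, rbind(centerRef, meridianRef))
  tol <- 3 * max(surface@rms, 1e-9)
  if (any(abs(refs[, 3] - drop(quadDesign(refs[, 1], refs[, 2]) %*%
                                 surface@coefficients)) > tol))
    stop("reference point lies farther than 3 rms residuals from the surface")
  q <- surfaceUVW(surface, query)
  off <- abs(q[, 3] - drop(quadDesign(q[, 1], q[, 2]) %*%
                             surface@coefficients))
  if (any(off > tol))
    warning(sprintf("%d query point(s) off-surface by up to %.0f nm",
                    sum(off > tol), max(off)))
  c0 <- refs[1, 1:2]; m0 <- refs[2, 1:2]
  sMer <- surfaceArclength(surface, c0, m0)
  if (sMer == 0) stop("center and meridian references coincide")
  scale <- greatCircleDeg(centerEye, meridianEye)[1, 1] / sMer
  angMer <- atan2(m0[2] - c0[2], m0[1] - c0[1])
  # spherical destination frame at the lune anchor
  cv <- drop(eyeToVec(centerEye))
  mv <- drop(eyeToVec(meridianEye))
  e1 <- mv - sum(mv * cv) * cv            # toward the meridian reference
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(cv[2] * e1[3] - cv[3] * e1[2],  # completes the tangent frame
          cv[3] * e1[1] - cv[1] * e1[3],
          cv[1] * e1[2] - cv[2] * e1[1])
  out <- t(vapply(seq_len(nrow(q)), function(i) {
    rho <- deg2rad(surfaceArclength(surface, c0, q[i, 1:2]) * scale)
    if (rho == 0) return(drop(eyeToVec(centerEye)))
    beta <- atan2(q[i, 2] - c0[2], q[i, 1] - c0[1]) - angMer
    if (flip) beta <- -beta
    cos(rho) * cv + sin(rho) * (cos(beta) * e1 + sin(beta) * e2)
  }, numeric(3)))
  res <- vecToEye(out)
  rownames(res) <- rownames(query)
  res
}

#' Center-of-mass of a skeleton's dendrite
#'
#' Mean position of the dendrite-labeled nodes. Resample the skeleton
#' first so the mean is arclength-weighted.
#'
#' @param skel a [Skeleton-class] with dendrite-labeled nodes.
#' @return length-3 numeric (nm).
#' @export
dendriteCenter <- function(skel) {
  sel <- skel@nodes$label == "dendrite"
  if (!any(sel)) stop("skeleton has no dendrite-labeled nodes")
  colMeans(nodeCoords(skel)[sel, , drop = FALSE])
}

#' Visual-field coverage polygon of a dendrite
#'
#' Convex hull of dendrite node positions mapped into eye coordinates.
#'
#' @param eyePoints n x 2 matrix of mapped (lon, lat) positions, n >= 3.
#' @return matrix of hull vertices in order (not closed).
#' @export
coveragePolygon <- function(eyePoints) {
  p <- as.matrix(eyePoints)
  if (nrow(p) < 3) stop("need at least 3 mapped nodes")
  h <- grDevices::chull(p)
  if (length(h) < 3 || polygonArea(p[h, , drop = FALSE]) == 0)
    stop("degenerate hull: nodes are collinear")
  p[h, , drop = FALSE]
}

#' Fraction of the lune covered by a union of polygons
#'
#' Rasterizes the lune at the given step and reports the fraction of cells
#' inside at least one polygon (used to check full-field dendritic tiling).
#'
#' @param polygons list of two-column vertex matrices.
#' @param step grid step in degrees.
#' @return fraction in [0, 1].
#' @export
luneCoverageFraction <- function(polygons, step = 2) {
  g <- as.matrix(expand.grid(lon = seq(-90, 90, by = step),
                             lat = seq(-10, 160, by = step)))
  covered <- rep(FALSE, nrow(g))
  for (poly in polygons) covered <- covered | pointInPolygon(g, poly)
  mean(covered)
}
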