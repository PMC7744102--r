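# Shared internal helpers: seeded substreams, spherical eye-coordinate
# algebra, and small numerical utilities used across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a global seed
#'
#' Deterministically maps (seed, component name) to a new 31-bit seed so each
#' component of a simulation draws from an independent stream; adding a
#' component never perturbs the draws of another.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substreamSeed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Convert eye coordinates to unit vectors
#'
#' Eye coordinates live on a spherical lune with longitude in
#' [-90, +90] degrees and latitude in [-10, +160] degrees (one eye's field of
#' view). Latitude is measured along meridians and may exceed 90 degrees, in
#' which case the point wraps over the pole; the parameterization stays
#' injective because the folded longitude would leave the lune.
#'
#' @param lonlat two-column matrix (or length-2 vector) of degrees.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
eyeToVec <- function(lonlat) {
  lonlat <- rbind2col(lonlat)
  lon <- deg2rad(lonlat[, 1]); lat <- deg2rad(lonlat[, 2])
  cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

#' Convert unit vectors back to eye coordinates
#'
#' Inverts [eyeToVec()], folding points that wrapped over the pole back into
#' the lune's longitude range.
#' @param v n x 3 matrix of unit vectors.
#' @return n x 2 matrix with columns `lon`, `lat` in degrees.
#' @keywords internal
vecToEye <- function(v) {
  v <- matrix(v, ncol = 3)
  lat <- rad2deg(asin(pmin(1, pmax(-1, v[, 3]))))
  lon <- rad2deg(atan2(v[, 2], v[, 1]))
  flip <- !is.na(lon) & abs(lon) > 90
  lon[flip] <- lon[flip] - sign(lon[flip]) * 180
  lat[flip] <- 180 - lat[flip]
  cbind(lon = lon, lat = lat)
}

# Coerce a length-2 vector to a 1 x 2 matrix, pass matrices through.
rbind2col <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = length(x)) else as.matrix(x)
}

#' Great-circle distances between eye coordinates, in degrees
#'
#' @param a,b two-column (lon, lat) matrices in degrees; `b` defaults to `a`.
#' @return matrix of central angles in degrees, `nrow(a)` x `nrow(b)`.
#' @keywords internal
greatCircleDeg <- function(a, b = a) {
  va <- eyeToVec(a); vb <- eyeToVec(b)
  d <- va %*% t(vb)
  d[] <- rad2deg(acos(pmin(1, pmax(-1, d))))
  d
}

# Pairwise Euclidean distance matrix between the rows of a and b.
crossDist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Distance matrix for one point set under a named metric.
metricDist <- function(x, metric = c("euclidean", "greatcircle")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (metric == "greatcircle") {
    if (ncol(x) != 2L)
      stop("great-circle metric requires two-column (lon, lat) coordinates")
    d <- greatCircleDeg(x)
  } else {
    d <- crossDist(x, x)
  }
  diag(d) <- 0   # guard against floating-point rounding
  d
}

# Rotate 3-vectors about a unit axis by an angle (Rodrigues' formula).
rotateAboutAxis <- function(v, axis, angleDeg) {
  k <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angleDeg)
  v <- matrix(v, ncol = 3)
  kx <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
              k[3] * v[, 1] - k[1] * v[, 3],
              k[1] * v[, 2] - k[2] * v[, 1])
  v * cos(th) + kx * sin(th) + outer(drop(v %*% k), k) * (1 - cos(th))
}

# Signed area of a polygon given as a two-column vertex matrix (shoelace).
polygonArea <- function(p) {
  p <- as.matrix(p)
  i <- seq_len(nrow(p)); j <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2])) / 2
}

# Ray-casting point-in-polygon test; poly is a two-column vertex matrix.
pointInPolygon <- function(pts, poly) {
  pts <- rbind2col(pts); poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
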