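# The Retinotopy Index: a rank-inversion statistic on distance-ordered
# neighbour lists of a mapping between two metric spaces.

#' Construct a PointMapping
#'
#' Pairs the positions of the same ids in two metric spaces. Each space can
#' be given either as a coordinate matrix (rows = points) or as a
#' precomputed symmetric distance matrix, so any metric -- Euclidean
#' positions, great-circle eye distances, or the presynapse-based distance
#' of [presynapseDistance()] -- can feed the Retinotopy Index.
#'
#' @param source,target coordinate matrices with one row per id (any number
#'   of columns), plain vectors (treated as 1-D positions), or square
#'   symmetric distance matrices when the matching entry of `precomputed`
#'   is `TRUE`.
#' @param ids character ids; default from rownames/names of `source`, else
#'   `p1`, `p2`, ...
#' @param metric metric per space, recycled to length 2: `"euclidean"` or
#'   `"greatcircle"` (central angle on the eye sphere; requires lon/lat
#'   columns).
#' @param precomputed logical, recycled to length 2: is the corresponding
#'   argument already a distance matrix?
#' @return A [PointMapping-class] object.
#' @examples
#' m <- pointMapping(cbind(c(0, 1, 3)), cbind(c(0, 3, 1)))
#' riPopulation(m)
#' @export
pointMapping <- function(source, target, ids = NULL,
                         metric = "euclidean", precomputed = FALSE) {
  metric <- rep_len(metric, 2L)
  precomputed <- rep_len(precomputed, 2L)
  asCoord <- function(x) if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  src <- asCoord(source); tgt <- asCoord(target)
  n <- nrow(src)
  if (is.null(ids)) {
    ids <- rownames(src)
    if (is.null(ids)) ids <- paste0("p", seq_len(n))
  }
  if (nrow(tgt) != n)
    stop("source and target must describe the same number of points")
  if (n < 3L) stop("Retinotopy Index is undefined below 3 points")
  if (!all(is.finite(src)) || !all(is.finite(tgt)))
    stop("positions must be finite")
  mkDist <- function(x, pre, met) {
    if (pre) {
      if (nrow(x) != ncol(x)) stop("precomputed distances must be square")
      unname(x)
    } else metricDist(x, met)
  }
  new("PointMapping", ids = as.character(ids),
      source = if (precomputed[1]) NULL else src,
      target = if (precomputed[2]) NULL else tgt,
      sourceDist = mkDist(src, precomputed[1], metric[1]),
      targetDist = mkDist(tgt, precomputed[2], metric[2]),
      metric = ifelse(precomputed, "precomputed", metric))
}

setMethod("show", "PointMapping", function(object) {
  cat("PointMapping of", length(object@ids), "points\n")
  cat("  source metric:", object@metric[1],
      "| target metric:", object@metric[2], "\n")
})

#' Order the other points by distance to a reference point
#'
#' All non-reference ids are sorted by ascending distance to the reference
#' in the chosen space. Exact distance ties are broken by ascending id --
#' identically in both spaces, so ties never contribute spurious inversions
#' -- and flagged.
#'
#' @param mapping a [PointMapping-class].
#' @param space `"source"` or `"target"`.
#' @param referenceId id of the reference point.
#' @return list with `referenceId`, `orderedIds` (length N-1), `distances`,
#'   and `tieFlags` (length N-2 logical: is the pair (i, i+1) exactly tied?).
#' @export
rankByDistance <- function(mapping, space = c("source", "target"),
                           referenceId) {
  space <- match.arg(space)
  ids <- mapping@ids
  ri <- match(referenceId, ids)
  if (is.na(ri)) stop("unknown reference id: ", referenceId)
  D <- if (space == "source") mapping@sourceDist else mapping@targetDist
  d <- D[ri, -ri]
  others <- ids[-ri]
  ord <- order(d, others)
  ds <- d[ord]
  list(referenceId = referenceId,
       orderedIds = others[ord],
       distances = ds,
       tieFlags = if (length(ds) > 1) diff(ds) == 0 else logical(0))
}

#' Count inversions between two orderings of the same ids
#'
#' The minimal number of adjacent transpositions (bubble-sort swaps) turning
#' `listB` into `listA`; equivalently the number of discordant pairs.
#' Computed by merge counting in O(n log n).
#'
#' @param listA,listB vectors that are permutations of each other.
#' @return integer swap count S.
#' @examples
#' countInversions(1:4, c(4, 3, 2, 1))  # 6 = (N-1)(N-2)/2 at N = 5 points
#' @export
countInversions <- function(listA, listB) {
  if (length(listA) != length(listB) ||
      !all(sort(as.character(listA)) == sort(as.character(listB))))
    stop("inputs must be permutations of each other")
  p <- match(as.character(listB), as.character(listA))
  n <- length(p)
  if (n < 2L) return(0L)
  # bottom-up merge sort, counting cross-half inversions at each merge
  inv <- 0
  width <- 1L
  x <- p
  while (width < n) {
    y <- x
    start <- 1L
    while (start <= n - width) {
      mid <- start + width - 1L
      end <- min(start + 2L * width - 1L, n)
      i <- start; j <- mid + 1L; k <- start
      while (i <= mid && j <= end) {
        if (x[i] <= x[j]) { y[k] <- x[i]; i <- i + 1L }
        else { y[k] <- x[j]; j <- j + 1L; inv <- inv + (mid - i + 1L) }
        k <- k + 1L
      }
      while (i <= mid) { y[k] <- x[i]; i <- i + 1L; k <- k + 1L }
      while (j <= end) { y[k] <- x[j]; j <- j + 1L; k <- k + 1L }
      start <- end + 1L
    }
    x <- y
    width <- 2L * width
  }
  as.integer(inv)
}

#' Expected inversion count under a random permutation
#'
#' For N points (including the reference), the distance-ordered list of the
#' other N-1 points takes at most (N-1)(N-2)/2 swaps to reverse completely;
#' by symmetry a uniformly random permutation needs half that on average:
#' A = (N-1)(N-2)/4.
#'
#' @param nPoints N, including the reference point; must be >= 3.
#' @return A, the RI normalization constant.
#' @export
expectedSwaps <- function(nPoints) {
  if (nPoints < 3) stop("Retinotopy Index is undefined below 3 points (A = 0)")
  (nPoints - 1) * (nPoints - 2) / 4
}

#' Per-reference-point Retinotopy Index
#'
#' RI_i = 1 - S/A, where S is the inversion count between the
#' distance-ordered neighbour lists of reference point i in the two spaces
#' and A = (N-1)(N-2)/4. RI_i is 1 for order-preserving mappings, about 0
#' for random ones, and -1 when every distance ranking is reversed.
#'
#' @inheritParams rankByDistance
#' @return scalar RI_i in [-1, 1].
#' @export
riPoint <- function(mapping, referenceId) {
  s <- countInversions(rankByDistance(mapping, "source", referenceId)$orderedIds,
                       rankByDistance(mapping, "target", referenceId)$orderedIds)
  1 - s / expectedSwaps(length(mapping@ids))
}

#' Population Retinotopy Index of a mapping
#'
#' Computes RI_i for every point as reference and averages; the population
#' RI is 1 for mappings that preserve all distance orderings, near 0 for
#' random mappings, and negative for order-inverting ones. A p-value against
#' a population centered at zero is attached via [riSignificance()].
#'
#' @param mapping a [PointMapping-class].
#' @param significance passed to [riSignificance()] as `method`;
#'   use `"none"` to skip the test.
#' @return An [RIResult-class].
#' @examples
#' g <- makeLobulaGrid(4, 5, jitterSd = 2, seed = 1)
#' riPopulation(pointMapping(g, g))@populationRI  # identity mapping: 1
#' @export
riPopulation <- function(mapping, significance = "wilcoxon") {
  ids <- mapping@ids
  n <- length(ids)
  A <- expectedSwaps(n)
  s <- vapply(ids, function(id) {
    countInversions(rankByDistance(mapping, "source", id)$orderedIds,
                    rankByDistance(mapping, "target", id)$orderedIds)
  }, numeric(1))
  ri <- 1 - s / A
  p <- if (identical(significance, "none")) NA_real_
       else riSignificance(ri, method = significance)
  new("RIResult", perPointRI = ri, populationRI = mean(ri), swaps = s,
      expectedSwaps = A, pValue = p, n = n)
}

setMethod("show", "RIResult", function(object) {
  cat(sprintf("RIResult: population RI = %.4f over %d points\n",
              object@populationRI, object@n))
  cat(sprintf("  per-point range [%.3f, %.3f], A = %.2f, p (vs 0) = %.3g\n",
              min(object@perPointRI), max(object@perPointRI),
              object@expectedSwaps, object@pValue))
})

#' Significance of a per-point RI population against zero
#'
#' Two-sided test of the null that the RI population is centered at zero.
#' The default is the Wilcoxon signed-rank test against 0; `"mannwhitney"`
#' runs a two-sample Mann-Whitney U test against a supplied null sample
#' (for example, per-point RIs of randomized mappings), which reproduces the
#' same population-versus-zero semantics. Per-point RI values of one mapping
#' share points and are therefore dependent; treat the p-value as
#' approximate.
#'
#' @param values per-point RI values (>= 3).
#' @param method `"wilcoxon"` or `"mannwhitney"`.
#' @param null numeric null sample, required for `"mannwhitney"`.
#' @return two-sided p-value.
#' @export
riSignificance <- function(values, method = c("wilcoxon", "mannwhitney"),
                           null = NULL) {
  method <- match.arg(method)
  if (length(values) < 3) stop("need at least 3 RI values")
  if (all(values == 0)) return(1)
  if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(values, mu = 0, exact = FALSE)$p.value)
  } else {
    if (is.null(null)) stop("mannwhitney method needs a null sample")
    suppressWarnings(stats::wilcox.test(values, null, exact = FALSE)$p.value)
  }
}
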