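# Synapse-weighted Gaussian receptive-field estimation on the eye lune:
# per-neuron Gaussians scaled by synapse count and summed, population sums,
# fraction-of-peak contours, and per-compartment fields.

#' Construct an RFGrid
#'
#' @param lon,lat regular grid axis values in degrees.
#' @param values `length(lon)` x `length(lat)` non-negative matrix.
#' @param provenance one of `anatomical`, `functional`, `compartment`,
#'   `population`.
#' @return An [RFGrid-class].
#' @export
rfGrid <- function(lon, lat, values, provenance = "anatomical") {
  new("RFGrid", lon = lon, lat = lat, values = values,
      provenance = provenance)
}

#' Default 1-degree grid over the eye lune
#' @param step grid step in degrees.
#' @return list with `lon` and `lat` axis vectors.
#' @export
luneGrid <- function(step = 1) {
  list(lon = seq(-90, 90, by = step), lat = seq(-10, 160, by = step))
}

setMethod("show", "RFGrid", function(object) {
  cat(sprintf("RFGrid (%s): %d x %d at %.2f deg, peak %.4g\n",
              object@provenance, length(object@lon), length(object@lat),
              if (length(object@lon) > 1) diff(object@lon[1:2]) else NA,
              max(object@values)))
})

#' Synapse-weighted Gaussian anatomical receptive field
#'
#' For each neuron a 2-D Gaussian is placed at its eye center; its height is
#' proportional to the neuron's synapse count onto the target of interest,
#' and all Gaussians share the same half-width (the averaged dendritic
#' arbor radius, about 30 degrees). The summed multi-Gaussian field is the
#' feed-forward anatomical receptive-field estimate; absolute field values
#' are in arbitrary units (the proportionality constant does not affect
#' contours or peak locations).
#'
#' The half-width is interpreted as the half-width at half-maximum, so
#' sigma = halfWidth / sqrt(2 ln 2). Distances are planar lon/lat degrees
#' by default (fields are drawn on the flattened lune); a great-circle
#' variant is available for sensitivity analysis.
#'
#' @param eyeCenters matrix (lon, lat) with rownames = neuron ids.
#' @param weights named non-negative synapse counts, at least one positive.
#' @param halfWidth Gaussian half-width at half-maximum, degrees.
#' @param grid list with `lon`, `lat` axes (default [luneGrid()]).
#' @param distance `"planar"` or `"greatcircle"`.
#' @param provenance provenance tag for the result.
#' @return An [RFGrid-class].
#' @export
anatomicalRF <- function(eyeCenters, weights, halfWidth = 30,
                         grid = luneGrid(), distance = c("planar",
                                                         "greatcircle"),
                         provenance = "anatomical") {
  distance <- match.arg(distance)
  ids <- rownames(eyeCenters)
  w <- if (!is.null(names(weights)) && !is.null(ids)) weights[ids] else weights
  if (any(is.na(w) | w < 0)) stop("weights must be non-negative for every id")
  if (all(w == 0)) stop("all-zero weights: empty field")
  sigma <- halfWidth / sqrt(2 * log(2))
  g <- as.matrix(expand.grid(lon = grid$lon, lat = grid$lat))
  vals <- numeric(nrow(g))
  for (i in seq_len(nrow(eyeCenters))) {
    if (w[i] == 0) next
    d2 <- if (distance == "planar")
      (g[, 1] - eyeCenters[i, 1])^2 + (g[, 2] - eyeCenters[i, 2])^2
    else greatCircleDeg(g, eyeCenters[i, , drop = FALSE])^2
    vals <- vals + w[i] * exp(-d2 / (2 * sigma^2))
  }
  rfGrid(grid$lon, grid$lat,
         matrix(vals, length(grid$lon), length(grid$lat)),
         provenance = provenance)
}

#' Sum receptive fields across cells
#'
#' Pointwise sum over identical grids, mimicking the summed response of a
#' calcium indicator expressed in a population of cells of one type. By
#' linearity this equals [anatomicalRF()] on the pooled weights.
#'
#' @param cellRFs list of [RFGrid-class] objects on the same grid.
#' @return An [RFGrid-class] with provenance `population`.
#' @export
populationRF <- function(cellRFs) {
  g1 <- cellRFs[[1]]
  for (g in cellRFs[-1]) {
    if (!identical(g@lon, g1@lon) || !identical(g@lat, g1@lat))
      stop("grids differ: cannot sum")
  }
  rfGrid(g1@lon, g1@lat,
         Reduce(`+`, lapply(cellRFs, function(g) g@values)),
         provenance = "population")
}

#' Fraction-of-peak contours of a receptive field
#'
#' Level set at `fraction` of the field maximum, traced with
#' bilinear-interpolated marching on the grid. Contours that run into the
#' grid boundary are returned open and flagged.
#'
#' @param grid an [RFGrid-class] with a positive maximum.
#' @param fraction fraction of the peak in (0, 1) (70% and 60% are the
#'   conventional choices for anatomical and functional fields).
#' @return list of contour polylines, each a data.frame with `lon`, `lat`
#'   and attribute `closed`.
#' @export
rfContour <- function(grid, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  mx <- max(grid@values)
  if (mx <= 0) stop("grid has no positive values")
  cl <- grDevices::contourLines(grid@lon, grid@lat, grid@values,
                                levels = fraction * mx)
  lapply(cl, function(cc) {
    df <- data.frame(lon = cc$x, lat = cc$y)
    attr(df, "closed") <- isTRUE(all.equal(c(cc$x[1], cc$y[1]),
                                           c(cc$x[length(cc$x)],
                                             cc$y[length(cc$y)])))
    df
  })
}

#' Receptive field of one glomerulus compartment
#'
#' [anatomicalRF()] with the Gaussian heights proportional to each neuron's
#' presynapse count within the selected compartment.
#'
#' @param presynapses data.frame with columns `neuron_id` and `compartment`
#'   (e.g. from [partitionCompartments()]).
#' @param eyeCenters matrix (lon, lat) with rownames = neuron ids.
#' @param compartment compartment index.
#' @inheritParams anatomicalRF
#' @return An [RFGrid-class] with provenance `compartment`.
#' @export
compartmentRF <- function(presynapses, eyeCenters, compartment,
                          halfWidth = 30, grid = luneGrid()) {
  sel <- presynapses$compartment == compartment
  if (!any(sel)) stop("empty compartment: no presynapses")
  tab <- table(presynapses$neuron_id[sel])
  w <- stats::setNames(rep(0, nrow(eyeCenters)), rownames(eyeCenters))
  w[names(tab)] <- as.numeric(tab)
  anatomicalRF(eyeCenters, w, halfWidth = halfWidth, grid = grid,
               provenance = "compartment")
}

#' Peak location of a receptive field
#' @param grid an [RFGrid-class].
#' @return length-2 numeric (lon, lat) of the grid cell with maximal value.
#' @export
rfArgmax <- function(grid) {
  idx <- arrayInd(which.max(grid@values), dim(grid@values))
  c(lon = grid@lon[idx[1]], lat = grid@lat[idx[2]])
}

#' Bilinear sample of a receptive field
#' @param grid an [RFGrid-class].
#' @param at two-column (lon, lat) matrix or length-2 vector.
#' @return numeric vector of interpolated values; out-of-domain points are
#'   an error.
#' @export
rfValueAt <- function(grid, at) {
  at <- rbind2col(at)
  lon <- grid@lon; lat <- grid@lat
  if (any(at[, 1] < lon[1] | at[, 1] > lon[length(lon)] |
          at[, 2] < lat[1] | at[, 2] > lat[length(lat)]))
    stop("point outside the receptive-field grid")
  i <- pmin(findInterval(at[, 1], lon), length(lon) - 1L)
  j <- pmin(findInterval(at[, 2], lat), length(lat) - 1L)
  tx <- (at[, 1] - lon[i]) / (lon[i + 1] - lon[i])
  ty <- (at[, 2] - lat[j]) / (lat[j + 1] - lat[j])
  v <- grid@values
  v[cbind(i, j)] * (1 - tx) * (1 - ty) +
    v[cbind(i + 1L, j)] * tx * (1 - ty) +
    v[cbind(i, j + 1L)] * (1 - tx) * ty +
    v[cbind(i + 1L, j + 1L)] * tx * ty
}
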