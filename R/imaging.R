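# Calcium-imaging summary statistics: dF/F with a sliding-percentile
# baseline, per-fly percentile normalization, peak responses, functional
# receptive-field maps with per-location tests under FDR control, tuning
# regression, and the bilateral-suppression test.

#' Relative fluorescence change (dF/F)
#'
#' dF/F = (F - F0) / F0. In `sliding` mode F0 is a low percentile (default
#' the 10th, a robust baseline estimator) of the fluorescence within a
#' sliding window (default 300 frames) centered on each frame and clipped
#' at the trace edges. In `epoch` mode a single global percentile of the
#' whole trace (e.g. of the stimulation protocol period) is used.
#'
#' @param f numeric fluorescence trace (arbitrary units).
#' @param window sliding window length in frames.
#' @param percentile baseline percentile (0-100).
#' @param mode `"sliding"` or `"epoch"`.
#' @return numeric dF/F trace of the same length.
#' @export
deltaFOverF <- function(f, window = 300, percentile = 10,
                        mode = c("sliding", "epoch")) {
  mode <- match.arg(mode)
  if (!all(is.finite(f))) stop("fluorescence must be finite")
  if (mode == "epoch") {
    f0 <- stats::quantile(f, percentile / 100, names = FALSE)
    if (f0 <= 0) stop("non-positive baseline F0")
    return((f - f0) / f0)
  }
  if (length(f) < window)
    stop("trace shorter than the sliding window; use mode = 'epoch'")
  f0 <- zoo::rollapply(zoo::zoo(f), width = window,
                       FUN = stats::quantile, probs = percentile / 100,
                       names = FALSE, partial = TRUE, align = "center")
  f0 <- as.numeric(f0)
  if (any(f0 <= 0)) stop("non-positive baseline F0")
  (f - f0) / f0
}

#' Normalize responses to each fly's 98th percentile
#'
#' Dividing each fly's dF/F values by that fly's 98th percentile (a robust
#' estimator of peak levels) removes per-animal gain before responses are
#' combined across animals.
#'
#' @param perFly list of numeric vectors, one per fly, each with at least
#'   50 values (below that the 98th percentile is not meaningful).
#' @param percentile normalization percentile (default 98).
#' @return list of normalized vectors (each fly's 98th percentile becomes 1).
#' @export
normalizeResponses <- function(perFly, percentile = 98) {
  if (!is.list(perFly)) perFly <- list(perFly)
  lapply(perFly, function(v) {
    if (length(v) < 50)
      stop("need at least 50 values per fly for a stable percentile")
    p <- stats::quantile(v, percentile / 100, names = FALSE)
    if (p <= 0) stop("non-positive normalization percentile")
    v / p
  })
}

#' Peak response within a stimulus epoch
#'
#' Maximum dF/F within the epoch, optionally extended by a post-epoch grace
#' window for slow indicators.
#'
#' @param dff numeric dF/F trace.
#' @param epoch integer c(start, end) frame indices (inclusive).
#' @param grace extra frames after the epoch end.
#' @return scalar peak dF/F.
#' @export
peakResponse <- function(dff, epoch, grace = 0) {
  idx <- seq(epoch[1], min(epoch[2] + grace, length(dff)))
  if (!length(idx) || epoch[1] < 1 || epoch[1] > length(dff))
    stop("empty epoch")
  max(dff[idx])
}

#' Functional receptive field from per-location peak responses
#'
#' Mean normalized peak response per stimulus location, interpolated
#' bilinearly over the stimulus grid onto a finer eye-coordinate grid, with
#' a per-location one-sided one-sample t-test against zero (responses
#' significantly larger than zero) under Benjamini-Hochberg FDR control,
#' and a fraction-of-peak contour (default 60%).
#'
#' @param peaks flies x locations matrix of normalized peak responses (at
#'   least 3 flies); columns ordered as `locations` rows.
#' @param locations two-column (lon, lat) matrix of stimulus centers; must
#'   form a complete rectangular grid.
#' @param alpha FDR level (default 0.05).
#' @param step output grid step in degrees (default 1).
#' @param contourFraction fraction of peak for the attached contour.
#' @return list with `grid` (an [RFGrid-class] over the stimulus bounding
#'   box), `mean` (per-location means), `pRaw`, `pAdj`, `sigMask` (logical,
#'   BH-adjusted p < alpha), and `contour`.
#' @export
functionalRF <- function(peaks, locations, alpha = 0.05, step = 1,
                         contourFraction = 0.6) {
  peaks <- as.matrix(peaks)
  locations <- as.matrix(locations)
  if (ncol(peaks) != nrow(locations))
    stop("peaks columns must align with stimulus locations")
  if (nrow(peaks) < 3) stop("need at least 3 flies")
  ulon <- sort(unique(locations[, 1]))
  ulat <- sort(unique(locations[, 2]))
  if (nrow(locations) != length(ulon) * length(ulat) ||
      anyDuplicated(locations))
    stop("stimulus locations must form a complete rectangular grid")
  n <- nrow(peaks)
  m <- colMeans(peaks)
  sd <- apply(peaks, 2, stats::sd)
  tstat <- m / (sd / sqrt(n))
  pRaw <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  pRaw[is.na(pRaw)] <- 1   # zero-variance locations carry no evidence
  pAdj <- stats::p.adjust(pRaw, method = "BH")
  sig <- pAdj < alpha
  # mean responses arranged on the stimulus grid
  M <- matrix(NA_real_, length(ulon), length(ulat))
  M[cbind(match(locations[, 1], ulon), match(locations[, 2], ulat))] <- m
  glon <- seq(min(ulon), max(ulon), by = step)
  glat <- seq(min(ulat), max(ulat), by = step)
  coarse <- rfGrid(ulon, ulat, pmax(M, 0), provenance = "functional")
  fine <- rfValueAt(coarse, as.matrix(expand.grid(glon, glat)))
  grid <- rfGrid(glon, glat, matrix(fine, length(glon), length(glat)),
                 provenance = "functional")
  list(grid = grid, mean = m, pRaw = pRaw, pAdj = pAdj, sigMask = sig,
       contour = if (max(fine) > 0) rfContour(grid, contourFraction)
                 else list())
}

#' Log-log tuning comparison between two response sets
#'
#' Log-normalizes paired peak responses (for example, a projection-neuron
#' type and its downstream target across the same stimuli) and reports the
#' least-squares slope, Pearson correlation, and its p-value; a slope of 1
#' means the downstream tuning follows the input tuning.
#'
#' @param peaksA,peaksB paired positive response values.
#' @return list with `slope`, `intercept`, `r`, `p`, and `deviation`
#'   (per-stimulus residual from the identity line in log space).
#' @export
tuningComparison <- function(peaksA, peaksB) {
  if (length(peaksA) != length(peaksB)) stop("responses must be paired")
  if (any(peaksA <= 0) || any(peaksB <= 0))
    stop("log normalization requires positive responses")
  x <- log10(peaksA); y <- log10(peaksB)
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value,
       deviation = y - x)
}

#' Bilateral suppression test
#'
#' Two-sided paired t-test of per-fly peak responses to an ipsilateral
#' stimulus alone against the same stimulus with a simultaneous
#' contralateral stimulus; a negative effect means suppression.
#'
#' @param ipsiPeaks,bothPeaks per-fly peak responses, paired by fly, n >= 3.
#' @return list with `p`, `effect` (mean of both - ipsi), and `n`.
#' @export
bilateralSuppressionTest <- function(ipsiPeaks, bothPeaks) {
  if (length(ipsiPeaks) != length(bothPeaks))
    stop("responses must be paired by fly")
  if (length(ipsiPeaks) < 3) stop("need at least 3 flies")
  d <- bothPeaks - ipsiPeaks
  p <- if (stats::sd(d) == 0) {
    if (mean(d) == 0) 1 else 0
  } else stats::t.test(bothPeaks, ipsiPeaks, paired = TRUE)$p.value
  list(p = p, effect = mean(d), n = length(d))
}
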