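#' Intensity histogram of a volume
#'
#' @param volume A [ct_volume()].
#' @param n_bins Number of equal-width bins (>= 2) spanning the intensity
#'   range. A constant volume yields a single-bin histogram with the
#'   `degenerate` flag set; such a histogram cannot be thresholded.
#'
#' @return An object of class `intensity_histogram` with fields `bin_edges`
#'   (length `n_bins + 1`), `counts` (length `n_bins`) and `degenerate`.
#' @export
intensity_histogram <- function(volume, n_bins = 256L) {
  stopifnot(inherits(volume, "ct_volume"))
  if (n_bins < 2L) {
    abort_femurfe("`n_bins` must be >= 2.", "femurfe_parameter_error")
  }
  v <- as.numeric(volume$intensities)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    return(structure(
      list(bin_edges = c(lo - 0.5, lo + 0.5), counts = length(v),
           degenerate = TRUE),
      class = "intensity_histogram"))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bins <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts, degenerate = FALSE),
            class = "intensity_histogram")
}

#' Kittler-Illingworth minimum-error threshold
#'
#' Models the histogram as a mixture of two Gaussians split at a candidate
#' threshold t and minimizes the classification-error criterion
#' \deqn{J(t) = 1 + 2[P_1 \ln\sigma_1 + P_2 \ln\sigma_2]
#'            - 2[P_1 \ln P_1 + P_2 \ln P_2]}
#' where \eqn{P_k, \sigma_k} are the weight and standard deviation of the
#' sub-histogram on each side of t. The returned threshold is the center of
#' the last bin of the lower class; ties are broken towards the lower
#' threshold. Zero within-class variances are floored at the single-bin
#' variance (bin width squared over 12) so spike histograms remain valid.
#'
#' @param hist An [intensity_histogram()].
#' @return The threshold intensity (scalar).
#' @export
ki_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  if (isTRUE(hist$degenerate)) {
    abort_femurfe("Histogram is degenerate (constant volume); no threshold exists.",
                  "femurfe_threshold_error")
  }
  counts <- as.numeric(hist$counts)
  B <- length(counts)
  centers <- (hist$bin_edges[-1] + hist$bin_edges[-(B + 1L)]) / 2
  bw <- diff(hist$bin_edges)[1]
  n <- sum(counts)
  if (n <= 0) {
    abort_femurfe("Histogram has no counts.", "femurfe_threshold_error")
  }
  c0 <- cumsum(counts)
  c1 <- cumsum(counts * centers)
  c2 <- cumsum(counts * centers^2)
  # candidate t = 1 .. B-1 splits bins [1..t] | [t+1..B]
  t <- seq_len(B - 1L)
  P1 <- c0[t] / n
  P2 <- 1 - P1
  valid <- c0[t] > 0 & c0[t] < n
  if (!any(valid)) {
    abort_femurfe("No valid threshold candidate: all mass in one bin.",
                  "femurfe_threshold_error")
  }
  m1 <- c1[t] / pmax(c0[t], 1)
  v1 <- c2[t] / pmax(c0[t], 1) - m1^2
  m2 <- (c1[B] - c1[t]) / pmax(n - c0[t], 1)
  v2 <- (c2[B] - c2[t]) / pmax(n - c0[t], 1) - m2^2
  vfloor <- bw^2 / 12
  v1 <- pmax(v1, vfloor)
  v2 <- pmax(v2, vfloor)
  J <- 1 + P1 * log(v1) + P2 * log(v2) - 2 * (P1 * log(P1) + P2 * log(P2))
  J[!valid] <- Inf
  centers[t[which.min(J)]]
}

#' Segmentation method descriptors
#'
#' The four approaches are the full Kittler-Illingworth threshold (`KI`,
#' retained fraction p = 1) and its narrowed variants `KI-99.0`, `KI-97.5`
#' and `KI-95.0`, which keep the central 99.0%, 97.5% and 95.0% of the
#' KI-derived bone intensity range — i.e. intensity-range variations of
#' 1.0%, 2.5% and 5.0%.
#'
#' @param name One of `"KI"`, `"KI-99.0"`, `"KI-97.5"`, `"KI-95.0"`.
#' @return A list with fields `name` and retained fraction `p`.
#' @export
seg_method <- function(name = c("KI", "KI-99.0", "KI-97.5", "KI-95.0")) {
  name <- match.arg(name)
  p <- c("KI" = 1, "KI-99.0" = 0.99, "KI-97.5" = 0.975, "KI-95.0" = 0.95)[[name]]
  structure(list(name = name, p = p), class = "seg_method")
}

#' All four segmentation methods
#' @return A named list of [seg_method()] objects.
#' @export
seg_methods_all <- function() {
  ms <- lapply(c("KI", "KI-99.0", "KI-97.5", "KI-95.0"), seg_method)
  names(ms) <- vapply(ms, `[[`, "", "name")
  ms
}

#' Central narrowing of an intensity range
#'
#' Returns the central fraction `p` of `[low, high]`: each end is trimmed by
#' `(1 - p) / 2 * (high - low)`, so the width ratio is exactly `p`. A
#' zero-width range is returned unchanged.
#'
#' @param range List or numeric pair `(low, high)` with `low <= high`.
#' @param p Retained fraction, `0 < p <= 1`.
#' @return A list with fields `low` and `high`.
#' @export
narrowed_range <- function(range, p) {
  if (is.numeric(range)) range <- list(low = range[1], high = range[2])
  stopifnot(range$low <= range$high, p > 0, p <= 1)
  d <- (1 - p) / 2 * (range$high - range$low)
  list(low = range$low + d, high = range$high - d)
}

#' Segment a volume with a Kittler-Illingworth-based method
#'
#' Computes the KI threshold, forms the full bone intensity range
#' `[threshold, max(volume)]`, narrows it to the method's central fraction,
#' keeps voxels whose intensity falls inside the narrowed range and (by
#' default) retains only the largest 26-connected component — the voxel-space
#' analog of isolated-piece removal. Provenance (specimen, method, threshold,
#' range) is recorded on the mask.
#'
#' With `mode = "percentile"` the narrowing is applied to the empirical
#' distribution of above-threshold voxel intensities instead of to the range
#' endpoints (central p mass rather than central p width).
#'
#' @param volume A [ct_volume()].
#' @param method A [seg_method()] or a method name.
#' @param n_bins Histogram bins for the KI criterion.
#' @param largest_component Keep only the largest 26-connected component?
#' @param mode `"range"` (default) or `"percentile"`; see Details.
#' @return A [binary_mask()].
#' @export
segment_volume <- function(volume, method = seg_method("KI"), n_bins = 256L,
                           largest_component = TRUE,
                           mode = c("range", "percentile")) {
  mode <- match.arg(mode)
  if (is.character(method)) method <- seg_method(method)
  hist <- intensity_histogram(volume, n_bins)
  thr <- ki_threshold(hist)
  vmax <- max(volume$intensities)
  full <- list(low = thr, high = vmax)
  rng <- if (mode == "range") {
    narrowed_range(full, method$p)
  } else {
    above <- volume$intensities[volume$intensities >= thr]
    q <- (1 - method$p) / 2
    qs <- stats::quantile(above, c(q, 1 - q), names = FALSE, type = 7)
    list(low = qs[1], high = qs[2])
  }
  vals <- volume$intensities >= rng$low & volume$intensities <= rng$high
  if (!any(vals)) {
    abort_femurfe(
      sprintf("Segmentation produced an empty mask (specimen %s, method %s).",
              volume$specimen_id, method$name),
      "femurfe_segmentation_empty")
  }
  if (largest_component) {
    vals <- largest_component3d(vals, connectivity = 26L)
  }
  binary_mask(vals, spacing = volume$spacing, origin = volume$origin,
              provenance = list(specimen_id = volume$specimen_id,
                                side = volume$side,
                                method = method, threshold = thr,
                                range = rng, full_range = full))
}
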