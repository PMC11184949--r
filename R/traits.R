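#' Normalised difference vegetation index
#'
#' `NDVI = (NIR - red)/(NIR + red)` per pixel, using the red (~669 nm) and
#' near-infrared (~820 nm) reflectance bands. Masks are intersected;
#' pixels where `NIR + red = 0` are flagged invalid.
#'
#' @param red,nir [trait_raster()]s of matching shape and GSD.
#' @return An NDVI [trait_raster()] with values in `[-1, 1]`.
#' @export
compute_ndvi <- function(red, nir) {
  stopifnot(inherits(red, "trait_raster"), inherits(nir, "trait_raster"))
  if (!all(dim(red$values) == dim(nir$values)))
    stop("red and NIR rasters must have identical dimensions")
  denom <- nir$values + red$values
  mask <- red$mask & nir$mask & denom != 0
  vals <- matrix(NA_real_, nrow(denom), ncol(denom))
  vals[mask] <- (nir$values[mask] - red$values[mask]) / denom[mask]
  trait_raster(vals, mask, gsd_m = red$gsd_m, trait = "NDVI",
               plot_id = red$plot_id, stage = red$stage)
}

#' Valley threshold of bimodal NDVI histograms
#'
#' For each growth stage's NDVI map, builds a histogram over `[-1, 1]`,
#' smooths it with a centred moving average, locates the two highest local
#' maxima (soil and vegetation modes) and takes the bin centre of the
#' lowest count strictly between them as that stage's valley. The
#' segmentation threshold is the arithmetic mean of the per-stage valleys.
#'
#' @param ndvi_rasters a single NDVI [trait_raster()] or a list of them
#'   (one per stage).
#' @param hist_bin histogram bin width in NDVI units.
#' @param smooth_window moving-average window, in bins (odd).
#' @return Object of class `threshold_result`: list with `threshold` and
#'   `per_stage_valleys`.
#' @export
find_valley_threshold <- function(ndvi_rasters, hist_bin = 0.02,
                                  smooth_window = 5) {
  if (inherits(ndvi_rasters, "trait_raster")) ndvi_rasters <- list(ndvi_rasters)
  if (length(ndvi_rasters) < 1L) stop("at least one NDVI raster is required")
  valleys <- vapply(seq_along(ndvi_rasters), function(i) {
    r <- ndvi_rasters[[i]]
    stage <- if (is.na(r$stage)) as.character(i) else r$stage
    histogram_valley(raster_values(r), hist_bin, smooth_window, stage)
  }, numeric(1))
  structure(list(threshold = mean(valleys), per_stage_valleys = valleys),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> NDVI threshold %.4f (mean of %d stage valleys)\n",
              x$threshold, length(x$per_stage_valleys)))
  invisible(x)
}

histogram_valley <- function(values, hist_bin, smooth_window, stage) {
  edges <- seq(-1, 1, by = hist_bin)
  if (edges[length(edges)] < 1) edges <- c(edges, edges[length(edges)] + hist_bin)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  centers <- edges[-length(edges)] + hist_bin / 2
  # centred moving average with shrinking window at the edges
  half <- smooth_window %/% 2L
  n <- length(counts)
  sm <- vapply(seq_len(n), function(i)
    mean(counts[max(1L, i - half):min(n, i + half)]), numeric(1))
  # local maxima, robust to plateaus: compress ties, compare run neighbours
  rl <- rle(sm)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  vals <- c(-Inf, rl$values, -Inf)
  is_peak <- vals[2:(length(vals) - 1)] > vals[1:(length(vals) - 2)] &
    vals[2:(length(vals) - 1)] > vals[3:length(vals)]
  peaks <- floor((starts[is_peak] + ends[is_peak]) / 2)
  if (length(peaks) < 2L)
    stop("NDVI histogram for stage ", stage,
         " is unimodal after smoothing; supply a threshold manually")
  top2 <- sort(peaks[order(sm[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1] + 1L, top2[2] - 1L)
  if (length(between) == 0L)
    stop("no bins strictly between the two modes for stage ", stage)
  # tie-break: centre of the lowest-count plateau between the modes
  lows <- between[sm[between] == min(sm[between])]
  centers[lows[ceiling(length(lows) / 2)]]
}

#' Fractional vegetation cover from an NDVI map
#'
#' Vegetation is defined strictly as `NDVI > threshold` (ties are
#' background); FVC is the vegetation pixel count over the total pixel
#' count inside the plot ROI. The binary crop mask is returned for
#' downstream masking of the continuous traits.
#'
#' @param ndvi an NDVI [trait_raster()].
#' @param threshold segmentation threshold in `(-1, 1)` (a number or a
#'   [find_valley_threshold()] result).
#' @param roi optional plot polygon (two-column matrix, metres); `NULL`
#'   uses the whole raster.
#' @return List with `fvc` (fraction in `[0, 1]`) and `veg_mask` (an FVC
#'   [trait_raster()] of 0/1 values, valid over the ROI).
#' @export
compute_fvc <- function(ndvi, threshold, roi = NULL) {
  stopifnot(inherits(ndvi, "trait_raster"))
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  if (threshold <= -1 || threshold >= 1)
    stop("`threshold` must lie strictly inside (-1, 1)")
  inroi <- roi_mask(ndvi, roi) & ndvi$mask
  if (!any(inroi)) stop("plot ROI contains no valid pixels")
  veg <- ndvi$values > threshold & inroi
  veg[is.na(veg)] <- FALSE
  fvc <- sum(veg) / sum(inroi)
  list(
    fvc = fvc,
    veg_mask = trait_raster(veg + 0, inroi, gsd_m = ndvi$gsd_m, trait = "FVC",
                            plot_id = ndvi$plot_id, stage = ndvi$stage)
  )
}

#' Plant height from a ground-normalised point cloud
#'
#' Returns a high percentile (by default the 97th) of the point heights,
#' under the linear-interpolation order-statistic convention
#' ([stats::quantile()] type 7). Robust to point order and monotone in the
#' percentile.
#'
#' @param points data frame with a `z` column, or a numeric vector of
#'   heights (already normalised to the ground plane).
#' @param percentile percentile in `[0, 100]`.
#' @return Plant height in the units of `z`.
#' @export
estimate_plant_height <- function(points, percentile = 97) {
  z <- if (is.data.frame(points)) points$z else as.numeric(points)
  if (length(z) < 1L) stop("point cloud is empty")
  if (percentile < 0 || percentile > 100)
    stop("`percentile` must be in [0, 100]")
  unname(stats::quantile(z, percentile / 100, type = 7, names = FALSE))
}

#' Subtract a ground plane from a point cloud
#'
#' Helper for clouds whose `z` is absolute elevation: subtracts a supplied
#' ground elevation (a constant or per-point vector) and clamps negative
#' residuals to zero.
#'
#' @param points data frame with `z`.
#' @param ground ground elevation(s) in the same units.
#' @return The point cloud with ground-normalised `z`.
#' @export
normalize_ground <- function(points, ground) {
  stopifnot(is.data.frame(points), "z" %in% names(points))
  points$z <- pmax(points$z - ground, 0)
  points
}
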