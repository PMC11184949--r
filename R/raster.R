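#' Plot-level trait raster
#'
#' A `trait_raster` holds one trait's values on a regular grid over a single
#' plot, together with a validity mask and the ground sampling distance
#' (GSD). Row 1 is the north edge of the plot; pixels are registered at
#' their centres. The mask uses `TRUE` = valid (for vegetation masks,
#' `TRUE`/1 = vegetation).
#'
#' @param values numeric matrix of trait values.
#' @param mask logical matrix of the same shape; `TRUE` marks valid pixels.
#'   Defaults to all valid.
#' @param gsd_m ground sampling distance in metres per pixel (> 0).
#' @param trait trait tag, one of `"LAI"`, `"SPAD"`, `"PH"`, `"FVC"`,
#'   `"NDVI"`, `"red"`, `"NIR"`.
#' @param plot_id plot identifier.
#' @param stage growth-stage tag (one of [growth_stages()]) or `NA`.
#' @return An object of class `trait_raster`.
#' @export
trait_raster <- function(values, mask = NULL, gsd_m, trait,
                         plot_id = NA_character_, stage = NA_character_) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  if (!all(dim(as.matrix(mask)) == dim(values)))
    stop("`values` and `mask` must have identical dimensions")
  mask <- matrix(as.logical(mask), nrow(values), ncol(values))
  if (!is.numeric(gsd_m) || length(gsd_m) != 1L || !is.finite(gsd_m) || gsd_m <= 0)
    stop("`gsd_m` must be a single positive number")
  trait <- match.arg(trait, c("LAI", "SPAD", "PH", "FVC", "NDVI", "red", "NIR"))
  if (!is.na(stage)) stage <- match.arg(stage, growth_stages())
  if (any(!is.finite(values[mask])))
    stop("trait values must be finite wherever the mask is TRUE")
  structure(
    list(values = values, mask = mask, gsd_m = gsd_m, trait = trait,
         plot_id = plot_id, stage = stage),
    class = "trait_raster"
  )
}

#' Growth-stage vocabulary
#'
#' The seven wheat growth stages used throughout: tillering (TS), jointing
#' (JS), heading (HS), flowering (FS), and early/middle/late grain filling
#' (EFS/MFS/LFS).
#'
#' @return Character vector of stage tags in phenological order.
#' @export
growth_stages <- function() c("TS", "JS", "HS", "FS", "EFS", "MFS", "LFS")

#' @export
print.trait_raster <- function(x, ...) {
  cat(sprintf("<trait_raster> %s  plot=%s stage=%s\n", x$trait,
              as.character(x$plot_id), as.character(x$stage)))
  cat(sprintf("  %d x %d pixels @ %.3g m GSD (%d valid)\n",
              nrow(x$values), ncol(x$values), x$gsd_m, sum(x$mask)))
  v <- x$values[x$mask]
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' Valid pixel values of a trait raster
#'
#' @param r a [trait_raster()].
#' @param crop_mask optional logical matrix (or `trait_raster` whose values
#'   are 0/1) restricting to vegetation pixels.
#' @return Numeric vector of the values at valid (and, if given, vegetated)
#'   pixels.
#' @export
raster_values <- function(r, crop_mask = NULL) {
  stopifnot(inherits(r, "trait_raster"))
  keep <- r$mask
  if (!is.null(crop_mask)) {
    m <- if (inherits(crop_mask, "trait_raster")) crop_mask$values > 0 else crop_mask
    if (!all(dim(m) == dim(keep)))
      stop("crop mask dimensions do not match the raster")
    keep <- keep & m
  }
  r$values[keep]
}

#' Pixel-centre coordinates of a raster
#'
#' Returns planar coordinates (metres, local frame) of every pixel centre.
#' The origin is the south-west plot corner; row 1 is the north edge.
#'
#' @param r a [trait_raster()].
#' @return A two-column matrix `(x, y)` in row-major (matrix element) order,
#'   i.e. `cbind(x, y)[i + (j-1)*nrow]` corresponds to `values[i, j]`.
#' @export
pixel_centers <- function(r) {
  stopifnot(inherits(r, "trait_raster"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  x <- (col(r$values) - 0.5) * r$gsd_m
  y <- (nr - row(r$values) + 0.5) * r$gsd_m
  cbind(x = as.vector(x), y = as.vector(y))
}

#' Test raster pixels against a plot ROI polygon
#'
#' A pixel belongs to the plot iff its centre lies inside the polygon
#' (even-odd rule, via [mgcv::in.out()]).
#'
#' @param r a [trait_raster()].
#' @param roi two-column matrix of polygon vertices (metres, local frame),
#'   or `NULL` for the whole raster.
#' @return Logical matrix, `TRUE` where the pixel centre is inside the ROI.
#' @export
roi_mask <- function(r, roi = NULL) {
  if (is.null(roi)) return(matrix(TRUE, nrow(r$values), ncol(r$values)))
  roi <- as.matrix(roi)
  if (ncol(roi) != 2L || nrow(roi) < 3L)
    stop("`roi` must be a two-column matrix with at least 3 vertices")
  # close the ring if needed
  if (any(roi[1L, ] != roi[nrow(roi), ])) roi <- rbind(roi, roi[1L, ])
  inside <- mgcv::in.out(roi, pixel_centers(r))
  matrix(inside, nrow(r$values), ncol(r$values))
}

#' Rectangular ROI covering a whole plot
#'
#' @param width_m,height_m plot dimensions in metres.
#' @return Four-vertex polygon matrix (open ring) in the local frame.
#' @export
plot_roi <- function(width_m = 1.5, height_m = 1.25) {
  cbind(x = c(0, width_m, width_m, 0), y = c(0, 0, height_m, height_m))
}

#' Degrade the spatial resolution of a raster
#'
#' Aggregates non-overlapping `factor` x `factor` pixel blocks by the mean
#' of their valid pixels, emulating image acquisition at a coarser ground
#' sampling distance. Trailing partial blocks are dropped; a block with no
#' valid pixel becomes invalid. With a fully valid raster and evenly
#' dividing dimensions the overall mean is preserved exactly.
#'
#' @param r a [trait_raster()].
#' @param factor positive integer aggregation factor; 1 returns `r`
#'   unchanged.
#' @return A [trait_raster()] with `gsd_m` multiplied by `factor`.
#' @export
degrade_resolution <- function(r, factor) {
  stopifnot(inherits(r, "trait_raster"))
  if (length(factor) != 1L || factor != as.integer(factor) || factor < 1)
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(r)
  nr <- nrow(r$values) %/% factor
  nc <- ncol(r$values) %/% factor
  if (nr < 1L || nc < 1L)
    stop("aggregation factor exceeds the raster dimensions")
  vals <- r$values[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  msk <- r$mask[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  v <- vals
  v[!msk] <- 0
  # block sums via row/column group aggregation
  gi <- rep(seq_len(nr), each = factor)
  gj <- rep(seq_len(nc), each = factor)
  sum_v <- rowsum(t(rowsum(v, gi)), gj)            # nc x nr
  cnt <- rowsum(t(rowsum(msk + 0, gi)), gj)
  newv <- t(sum_v) / t(cnt)
  newm <- t(cnt) > 0
  newv[!newm] <- NA_real_
  trait_raster(newv, newm, gsd_m = r$gsd_m * factor, trait = r$trait,
               plot_id = r$plot_id, stage = r$stage)
}
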