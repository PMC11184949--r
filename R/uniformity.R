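#' Discretise trait values into classes
#'
#' The classification parameter (bin width) turns a continuous trait map
#' into a class distribution: value `v` falls into class
#' `floor((v - origin)/bin_width)`, bins are half-open
#' `[edge, edge + width)`, empty bins are dropped, and class proportions
#' `P_i` are the class counts over the total pixel count. The number of
#' nonempty classes is the abundance `S`.
#'
#' @param values numeric vector of valid-pixel trait values.
#' @param bin_width positive bin width in trait units.
#' @param origin left-edge anchor of the binning grid (trait units).
#' @return An object of class `class_distribution` with elements
#'   `bin_width`, `origin`, `bins` (integer bin indices), `counts`, `S`,
#'   `p` (proportions summing to 1) and `n`.
#' @export
bin_values <- function(values, bin_width, origin = 0) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number")
  values <- as.numeric(values)
  if (length(values) < 1L) stop("at least one value is required")
  if (any(!is.finite(values))) stop("values must be finite")
  idx <- floor((values - origin) / bin_width)
  tab <- table(idx)
  counts <- as.integer(tab)
  structure(
    list(bin_width = bin_width, origin = origin,
         bins = as.integer(names(tab)), counts = counts,
         S = length(counts), p = counts / sum(counts),
         n = length(values)),
    class = "class_distribution"
  )
}

#' Two-class distribution of a binary vegetation map
#'
#' Fractional vegetation cover has only two pixel classes, 0 (background)
#' and 1 (vegetation), so it bypasses the bin-width machinery:
#' `P = (1 - FVC, FVC)`, with empty classes dropped (an all-vegetation or
#' all-soil plot has abundance S = 1).
#'
#' @param veg logical/0-1 vector or matrix of vegetation indicators, or a
#'   [trait_raster()] of 0/1 values (its validity mask is honoured).
#' @return A `class_distribution` over the observed classes.
#' @export
fvc_distribution <- function(veg) {
  v <- if (inherits(veg, "trait_raster")) raster_values(veg) else as.numeric(veg)
  if (length(v) < 1L) stop("empty vegetation map")
  if (!all(v %in% c(0, 1))) stop("vegetation map must be binary (0/1)")
  bin_values(v, bin_width = 1, origin = 0)
}

#' @export
print.class_distribution <- function(x, ...) {
  cat(sprintf("<class_distribution> S = %d classes over n = %d values (bin width %g)\n",
              x$S, x$n, x$bin_width))
  invisible(x)
}

check_dist <- function(dist) {
  stopifnot(inherits(dist, "class_distribution"))
  if (abs(sum(dist$p) - 1) > 1e-12) stop("class proportions must sum to 1")
  invisible(dist)
}

#' Shannon entropy of a class distribution
#'
#' `H' = -sum(P_i log P_i)` in nats; 0 for a single class, `log S` for a
#' perfectly even distribution.
#'
#' @param dist a [bin_values()] result.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(dist) {
  check_dist(dist)
  -sum(dist$p * log(dist$p))
}

#' Pielou's evenness index
#'
#' `J' = H'/log(S)`, in `[0, 1]`. For S = 1 (all pixels in one class —
#' perfectly uniform growth) the ratio is 0/0 and is defined as 0 so that
#' perfect uniformity sits at the low end of the index.
#'
#' @inheritParams shannon_entropy
#' @return Evenness in `[0, 1]`.
#' @export
pielou_index <- function(dist) {
  check_dist(dist)
  if (dist$S == 1L) return(0)
  shannon_entropy(dist) / log(dist$S)
}

#' Alatalo's evenness index
#'
#' `E = (1/sum(P_i^2) - 1) / (exp(H') - 1)`, in `[0, 1]`; 1 for any
#' perfectly even distribution with S >= 2, and 0 by the continuity
#' convention when S = 1.
#'
#' @inheritParams shannon_entropy
#' @return Evenness in `[0, 1]`.
#' @export
alatalo_index <- function(dist) {
  check_dist(dist)
  if (dist$S == 1L) return(0)
  (1 / sum(dist$p^2) - 1) / (exp(shannon_entropy(dist)) - 1)
}

#' Sheldon's evenness index
#'
#' `E_s = exp(H')/S` (natural logarithm throughout).
#'
#' @inheritParams shannon_entropy
#' @return Evenness in `(0, 1]`.
#' @export
sheldon_index <- function(dist) {
  check_dist(dist)
  exp(shannon_entropy(dist)) / dist$S
}

#' Heip's evenness index
#'
#' `E_h = (exp(H') - 1)/(S - 1)`; requires S >= 2.
#'
#' @inheritParams shannon_entropy
#' @return Evenness in `(0, 1]`.
#' @export
heip_index <- function(dist) {
  check_dist(dist)
  if (dist$S < 2L) stop("Heip's index requires at least two classes")
  (exp(shannon_entropy(dist)) - 1) / (dist$S - 1)
}

#' Mean, variance and dispersion statistics of trait values
#'
#' Computes the classical dispersion battery: mean, sample variance
#' (n - 1 denominator), coefficient of variation `CV = sd/mean`, and
#' optionally Lloyd's mean crowding `m* = mean + var/mean - 1` and the
#' clustering index `I = var/mean - 1`. Statistics that divide by a zero
#' mean are returned as `NA` (explicit undefined marker), never dropped.
#'
#' @param values numeric vector (length >= 1; variance needs >= 2).
#' @param extras include mean crowding and the clustering index?
#' @return Named list `mean`, `variance`, `cv` (and `mean_crowding`,
#'   `clustering` when `extras = TRUE`).
#' @export
dispersion_stats <- function(values, extras = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("values must be a non-empty finite vector")
  m <- mean(values)
  v <- if (length(values) >= 2L) stats::var(values) else NA_real_
  cv <- if (!is.na(v) && m != 0) sqrt(v) / m else NA_real_
  if (!is.na(v) && v == 0) cv <- 0
  out <- list(mean = m, variance = v, cv = cv)
  if (extras) {
    out$mean_crowding <- if (!is.na(v) && m != 0) m + v / m - 1 else NA_real_
    out$clustering <- if (!is.na(v) && m != 0) v / m - 1 else NA_real_
  }
  out
}

#' Default classification parameter per trait
#'
#' LAI 0.5, SPAD 2, PH 2 cm; FVC is binary and has no bin width.
#'
#' @param trait trait tag.
#' @return Bin width in trait units (`NA` for FVC).
#' @export
default_bin_width <- function(trait) {
  switch(trait, LAI = 0.5, SPAD = 2, PH = 2, FVC = NA_real_,
         stop("no default bin width for trait '", trait, "'"))
}

#' Compute the per-plot uniformity index battery
#'
#' For one trait raster, emits the six per-trait statistics: mean,
#' variance, coefficient of variation, Shannon entropy, Pielou's index and
#' Alatalo's index, as long-format records. Continuous traits (LAI, SPAD,
#' PH) are first discretised with the classification parameter; an FVC
#' raster (binary values) uses its native two classes. Run over the four
#' traits of a plot this yields 24 statistics: 20 uniformity indices plus
#' the 4 trait means.
#'
#' @param raster a [trait_raster()].
#' @param bin_width classification parameter in trait units; default per
#'   trait via [default_bin_width()]. Ignored for FVC.
#' @param origin binning grid anchor.
#' @param crop_mask optional vegetation mask (logical matrix or 0/1
#'   [trait_raster()]) restricting continuous traits to crop pixels.
#' @param use_crop_mask apply `crop_mask` (if supplied)?
#' @return Data frame `plot_id, stage, trait, index, abbrev, value`.
#' @export
uniformity_battery <- function(raster, bin_width = NULL, origin = 0,
                               crop_mask = NULL, use_crop_mask = TRUE) {
  stopifnot(inherits(raster, "trait_raster"))
  is_fvc <- raster$trait == "FVC"
  vals <- raster_values(raster,
                        if (use_crop_mask && !is_fvc) crop_mask else NULL)
  if (length(vals) == 0L)
    stop(sprintf("no valid pixels in plot %s stage %s",
                 raster$plot_id, raster$stage))
  if (is_fvc) {
    dist <- fvc_distribution(vals)
  } else {
    if (is.null(bin_width)) bin_width <- default_bin_width(raster$trait)
    dist <- bin_values(vals, bin_width, origin)
  }
  ds <- dispersion_stats(vals)
  idx <- c(mean = ds$mean, variance = ds$variance, cv = ds$cv,
           shannon = shannon_entropy(dist), pielou = pielou_index(dist),
           alatalo = alatalo_index(dist))
  data.frame(
    plot_id = raster$plot_id, stage = raster$stage, trait = raster$trait,
    index = names(idx),
    abbrev = index_abbrev(raster$trait, names(idx)),
    value = unname(idx),
    row.names = NULL
  )
}

#' Canonical abbreviation of a (trait, index) pair
#'
#' The field's short labels: trait prefix F/L/S/P (FVC, LAI, SPAD, plant
#' height) plus index suffix M/V/CV/H/J/E; plant-height Shannon entropy is
#' `PHH` to avoid clashing with the pH-like `PH` tag.
#'
#' @param trait trait tag(s).
#' @param index index name(s) among mean, variance, cv, shannon, pielou,
#'   alatalo.
#' @return Character vector of abbreviations (e.g. `FM`, `LJ`, `PE`).
#' @export
index_abbrev <- function(trait, index) {
  pre <- c(FVC = "F", LAI = "L", SPAD = "S", PH = "P")[trait]
  suf <- c(mean = "M", variance = "V", cv = "CV", shannon = "H",
           pielou = "J", alatalo = "E")[index]
  ab <- paste0(pre, suf)
  ab[trait == "PH" & index == "shannon"] <- "PHH"
  unname(ab)
}
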