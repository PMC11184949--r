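#' Configuration of the synthetic field simulator
#'
#' Describes a simulated small-plot trial: plot geometry, row structure,
#' per-trait mean levels and within-plot heterogeneity, the two NDVI modes
#' of the soil/vegetation scene, and the coefficients linking yield and
#' biomass to trait means and uniformity. Defaults mirror a dense-sown
#' wheat trial imaged at 3 cm GSD: 1.5 x 1.25 m plots with 0.25 m row
#' spacing.
#'
#' `heterogeneity` gives, per trait, the standard deviation of the
#' spatially correlated within-plot field and its correlation length in
#' metres. `field_sd` may be a vector (recycled over plots) so that
#' heterogeneity varies across the trial — the situation the uniformity
#' indices are designed to detect.
#'
#' @param n_plots number of plots.
#' @param plot_width_m,plot_height_m plot dimensions in metres.
#' @param gsd_m ground sampling distance, metres per pixel.
#' @param row_spacing_m centre-to-centre row spacing in metres.
#' @param row_structure logical; render inter-row soil stripes (and flag
#'   inter-row pixels invalid in trait rasters)?
#' @param trait_means named list of mean trait levels (`LAI`
#'   dimensionless, `SPAD` dimensionless, `PH` in cm).
#' @param heterogeneity named list; per trait a list
#'   `list(field_sd =, corr_length_m =)`.
#' @param soil_ndvi_mean,veg_ndvi_mean NDVI modes of soil and vegetation
#'   pixels.
#' @param noise_sd independent per-pixel noise sd (trait units for trait
#'   rasters, NDVI units for spectral scenes).
#' @param yield_coeffs,biomass_coeffs lists `list(a_mean =, b_uniformity =,
#'   noise_sd =)`: outcome = a_mean * trait mean - b_uniformity * index +
#'   Gaussian noise (Mg/ha).
#' @param seed integer RNG seed; identical config + seed gives
#'   bit-identical output.
#' @return An object of class `field_sim_config`.
#' @export
field_sim_config <- function(n_plots = 12,
                             plot_width_m = 1.5, plot_height_m = 1.25,
                             gsd_m = 0.03, row_spacing_m = 0.25,
                             row_structure = TRUE,
                             trait_means = list(LAI = 3, SPAD = 45, PH = 80),
                             heterogeneity = list(
                               LAI = list(field_sd = 0.5, corr_length_m = 0.2),
                               SPAD = list(field_sd = 3, corr_length_m = 0.2),
                               PH = list(field_sd = 5, corr_length_m = 0.2)),
                             soil_ndvi_mean = 0.1, veg_ndvi_mean = 0.8,
                             noise_sd = 0.05,
                             yield_coeffs = list(a_mean = 1.5, b_uniformity = 3,
                                                 noise_sd = 0.3),
                             biomass_coeffs = list(a_mean = 3.5,
                                                   b_uniformity = 6,
                                                   noise_sd = 0.6),
                             seed = 1L) {
  stopifnot(n_plots >= 1, gsd_m > 0, row_spacing_m > 0,
            plot_width_m >= 2 * gsd_m, plot_height_m >= 2 * gsd_m)
  for (tr in names(heterogeneity)) {
    h <- heterogeneity[[tr]]
    if (any(h$field_sd < 0)) stop("heterogeneity field_sd must be >= 0")
    if (h$corr_length_m <= 0) stop("heterogeneity corr_length_m must be > 0")
  }
  structure(
    list(n_plots = as.integer(n_plots), plot_width_m = plot_width_m,
         plot_height_m = plot_height_m, gsd_m = gsd_m,
         row_spacing_m = row_spacing_m, row_structure = row_structure,
         trait_means = trait_means, heterogeneity = heterogeneity,
         soil_ndvi_mean = soil_ndvi_mean, veg_ndvi_mean = veg_ndvi_mean,
         noise_sd = noise_sd, yield_coeffs = yield_coeffs,
         biomass_coeffs = biomass_coeffs, seed = as.integer(seed)),
    class = "field_sim_config"
  )
}

# deterministic sub-stream seed for (plot, purpose); kept < 2^31
sim_seed <- function(seed, plot_id, what) {
  code <- sum(utf8ToInt(what)) %% 1009L
  (abs(as.integer(seed)) %% 1000003L) * 2011L +
    (as.integer(plot_id) %% 100003L) * 17L + code
}

raster_dims <- function(cfg) {
  c(nr = max(2L, round(cfg$plot_height_m / cfg$gsd_m)),
    nc = max(2L, round(cfg$plot_width_m / cfg$gsd_m)))
}

# stripe mask: TRUE on crop rows. Rows run east-west (along plot width),
# repeating north-south with period row_spacing_m; the vegetated band is
# half the period wide, centred on the row.
row_mask <- function(cfg) {
  d <- raster_dims(cfg)
  y <- (d["nr"] - seq_len(d["nr"]) + 0.5) * cfg$gsd_m
  on_row <- (y %% cfg$row_spacing_m) < cfg$row_spacing_m / 2
  matrix(on_row, d["nr"], d["nc"])
}

# separable Gaussian smoothing with edge renormalisation
gauss_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    out <- stats::convolve(c(rep(0, half), v, rep(0, half)), rev(k),
                           type = "filter")
    wt <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), rev(k),
                          type = "filter")
    out / wt
  }
  m <- apply(m, 2L, conv1)
  t(apply(t(m), 2L, conv1))
}

# zero-mean spatially correlated field with population sd = field_sd
correlated_field <- function(nr, nc, field_sd, corr_length_px) {
  if (field_sd == 0) return(matrix(0, nr, nc))
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- gauss_smooth(z, corr_length_px)
  s <- stats::sd(as.vector(z)) * sqrt((nr * nc - 1) / (nr * nc))
  if (s == 0) return(matrix(0, nr, nc))
  (z - mean(z)) / s * field_sd
}

plot_field_sd <- function(cfg, trait, plot_id) {
  sds <- cfg$heterogeneity[[trait]]$field_sd
  sds[((as.integer(plot_id) - 1L) %% length(sds)) + 1L]
}

#' Simulate a plot-level trait raster
#'
#' Draws a stationary, spatially correlated trait surface (Gaussian-kernel
#' smoothed white noise with the configured correlation length) around the
#' trait mean, adds independent per-pixel noise, clips to the nonnegative
#' range, and — when row structure is enabled — flags inter-row pixels
#' invalid.
#'
#' @param cfg a [field_sim_config()].
#' @param trait one of `"LAI"`, `"SPAD"`, `"PH"`.
#' @param plot_id integer plot index in `1:cfg$n_plots`.
#' @param stage growth-stage tag for book-keeping.
#' @return A [trait_raster()].
#' @export
simulate_trait_raster <- function(cfg, trait, plot_id, stage = "FS") {
  stopifnot(inherits(cfg, "field_sim_config"))
  if (!trait %in% c("LAI", "SPAD", "PH"))
    stop("unknown trait '", trait, "'; valid tags: LAI, SPAD, PH")
  if (plot_id < 1 || plot_id > cfg$n_plots)
    stop("plot_id out of range for this configuration")
  d <- raster_dims(cfg)
  h <- cfg$heterogeneity[[trait]]
  set.seed(sim_seed(cfg$seed, plot_id, paste0("trait.", trait)))
  fld <- correlated_field(d["nr"], d["nc"], plot_field_sd(cfg, trait, plot_id),
                          h$corr_length_m / cfg$gsd_m)
  noise <- if (cfg$noise_sd > 0)
    matrix(stats::rnorm(prod(d), sd = cfg$noise_sd), d["nr"], d["nc"])
  else matrix(0, d["nr"], d["nc"])
  vals <- pmax(cfg$trait_means[[trait]] + fld + noise, 0)
  mask <- if (cfg$row_structure) row_mask(cfg)
          else matrix(TRUE, d["nr"], d["nc"])
  trait_raster(vals, mask, gsd_m = cfg$gsd_m, trait = trait,
               plot_id = as.character(plot_id), stage = stage)
}

#' Simulate a two-band (red/NIR) reflectance scene
#'
#' Vegetation (crop-row) and soil (inter-row) pixels are drawn around their
#' respective NDVI modes so the scene's NDVI histogram is bimodal; the two
#' reflectance bands are then back-computed so that
#' `(NIR - red)/(NIR + red)` reproduces the drawn NDVI exactly. The
#' ground-truth vegetation mask and true fractional cover are attached.
#'
#' @inheritParams simulate_trait_raster
#' @param full_cover logical; `TRUE` renders a closed canopy (all
#'   vegetation, the post-heading situation), `FALSE` the striped row
#'   scene.
#' @return List with `trait_raster` elements `red` and `nir`, logical
#'   matrix `veg_mask` (truth), and number `fvc_true` (exact mask pixel
#'   fraction).
#' @export
simulate_spectral_scene <- function(cfg, plot_id, stage = "FS",
                                    full_cover = !cfg$row_structure) {
  stopifnot(inherits(cfg, "field_sim_config"))
  d <- raster_dims(cfg)
  sep <- cfg$veg_ndvi_mean - cfg$soil_ndvi_mean
  if (sep <= 4 * cfg$noise_sd)
    warning("soil and vegetation NDVI modes closer than 4 x noise sd; ",
            "valley detection is not guaranteed")
  veg <- if (full_cover) matrix(TRUE, d["nr"], d["nc"]) else row_mask(cfg)
  set.seed(sim_seed(cfg$seed, plot_id, "spectral"))
  ndvi <- matrix(0, d["nr"], d["nc"])
  ndvi[veg] <- stats::rnorm(sum(veg), cfg$veg_ndvi_mean, cfg$noise_sd)
  ndvi[!veg] <- stats::rnorm(sum(!veg), cfg$soil_ndvi_mean, cfg$noise_sd)
  ndvi <- pmin(pmax(ndvi, -0.999), 0.999)
  total <- 0.6  # red + NIR reflectance sum, arbitrary positive scale
  nir <- total * (1 + ndvi) / 2
  red <- total - nir
  list(
    red = trait_raster(red, gsd_m = cfg$gsd_m, trait = "red",
                       plot_id = as.character(plot_id), stage = stage),
    nir = trait_raster(nir, gsd_m = cfg$gsd_m, trait = "NIR",
                       plot_id = as.character(plot_id), stage = stage),
    veg_mask = veg,
    fvc_true = mean(veg)
  )
}

#' Simulate a ground-normalised plant point cloud
#'
#' Plant points are scattered uniformly over the crop rows; `z` (height
#' above the ground plane, metres) is Gaussian around the configured mean
#' plant height with the plot's PH field sd, truncated at zero. The 97th
#' percentile of the generated heights is recorded as ground truth.
#'
#' @inheritParams simulate_trait_raster
#' @param points_per_m2 sampling density of the cloud.
#' @return Data frame with columns `x`, `y`, `z` (metres) and attributes
#'   `ph_true_p97` (metres) and `plot_id`.
#' @export
simulate_point_cloud <- function(cfg, plot_id, points_per_m2 = 2000) {
  stopifnot(inherits(cfg, "field_sim_config"))
  n <- max(10L, round(points_per_m2 * cfg$plot_width_m * cfg$plot_height_m))
  set.seed(sim_seed(cfg$seed, plot_id, "cloud"))
  x <- stats::runif(n, 0, cfg$plot_width_m)
  y <- stats::runif(n, 0, cfg$plot_height_m)
  mean_m <- cfg$trait_means$PH / 100
  sd_m <- plot_field_sd(cfg, "PH", plot_id) / 100
  z <- pmax(stats::rnorm(n, mean_m, sd_m), 0)
  cloud <- data.frame(x = x, y = y, z = z)
  attr(cloud, "ph_true_p97") <- unname(stats::quantile(z, 0.97, type = 7))
  attr(cloud, "plot_id") <- as.character(plot_id)
  cloud
}

#' Simulate a per-plot yield and biomass table
#'
#' Outcomes are affine in the plot's trait mean and uniformity index:
#' `yield = a_mean * trait_mean - b_uniformity * index + noise` (and
#' analogously for biomass with its own coefficients). With
#' `b_uniformity > 0` the entropy-based index — which is *high* for
#' heterogeneous plots — is negatively related to yield, i.e. uniform
#' growth pays.
#'
#' @param cfg a [field_sim_config()].
#' @param uniformity_values numeric vector, one uniformity index value per
#'   plot.
#' @param trait_means numeric vector, one trait mean per plot.
#' @return Data frame `plot_id, yield_mg_ha, biomass_mg_ha` with the
#'   generating coefficients attached as attribute `truth`.
#' @export
simulate_yield_table <- function(cfg, uniformity_values, trait_means) {
  stopifnot(inherits(cfg, "field_sim_config"),
            length(uniformity_values) == length(trait_means))
  n <- length(trait_means)
  set.seed(sim_seed(cfg$seed, 0L, "yield"))
  yc <- cfg$yield_coeffs; bc <- cfg$biomass_coeffs
  yield <- yc$a_mean * trait_means - yc$b_uniformity * uniformity_values +
    stats::rnorm(n, 0, yc$noise_sd)
  biomass <- bc$a_mean * trait_means - bc$b_uniformity * uniformity_values +
    stats::rnorm(n, 0, bc$noise_sd)
  out <- data.frame(plot_id = as.character(seq_len(n)),
                    yield_mg_ha = yield, biomass_mg_ha = biomass)
  attr(out, "truth") <- list(yield = yc, biomass = bc)
  out
}

#' Simulate the canonical uniformity-versus-yield study
#'
#' Convenience wrapper generating the synthetic experiment used throughout
#' the package's examples and checks: `n_plots` closed-canopy plots whose
#' within-plot LAI heterogeneity is graded across the trial (field sd from
#' `sd_range[1]` to `sd_range[2]`), plus yield/biomass generated from each
#' plot's LAI mean and Pielou index so that uniform plots out-yield
#' heterogeneous ones.
#'
#' @param n_plots number of plots (default 100).
#' @param seed RNG seed.
#' @param sd_range range of the per-plot LAI field sd.
#' @param bin_width classification parameter used for the LAI Pielou index.
#' @return List with `cfg`, `rasters` (list of LAI [trait_raster()]s),
#'   `battery` (long-format uniformity records), and `outcomes` (yield
#'   table).
#' @export
sim_uniformity_study <- function(n_plots = 100, seed = 1L,
                                 sd_range = c(0.1, 1.0), bin_width = 0.5) {
  cfg <- field_sim_config(
    n_plots = n_plots, row_structure = FALSE, seed = seed,
    heterogeneity = list(
      LAI = list(field_sd = seq(sd_range[1], sd_range[2], length.out = n_plots),
                 corr_length_m = 0.2),
      SPAD = list(field_sd = 3, corr_length_m = 0.2),
      PH = list(field_sd = 5, corr_length_m = 0.2)))
  rasters <- lapply(seq_len(n_plots), function(p)
    simulate_trait_raster(cfg, "LAI", p, stage = "FS"))
  bat <- do.call(rbind, lapply(rasters, uniformity_battery,
                               bin_width = bin_width))
  pj <- bat$value[bat$index == "pielou"]
  mu <- bat$value[bat$index == "mean"]
  outcomes <- simulate_yield_table(cfg, pj, mu)
  list(cfg = cfg, rasters = rasters, battery = bat, outcomes = outcomes)
}
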