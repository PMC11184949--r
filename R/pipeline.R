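#' End-to-end pipeline configuration
#'
#' Bundles everything a reproducible `simulate -> traits -> battery ->
#' assoc` run needs: the simulator configuration, the growth stages to
#' render, per-trait classification parameters, the NDVI threshold policy,
#' the plant-height percentile, and the seed of the model validation
#' split.
#'
#' @param sim a [field_sim_config()].
#' @param stages subset of [growth_stages()] to simulate.
#' @param bin_widths named list of classification parameters for LAI,
#'   SPAD and PH.
#' @param ndvi_threshold `"auto"` (valley detection across stages) or a
#'   fixed number in `(-1, 1)`.
#' @param percentile plant-height percentile.
#' @param split_seed seed of the 7:3 train/validation split of the fitted
#'   models.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = field_sim_config(),
                            stages = growth_stages(),
                            bin_widths = list(LAI = 0.5, SPAD = 2, PH = 2),
                            ndvi_threshold = "auto",
                            percentile = 97,
                            split_seed = 1L) {
  stopifnot(inherits(sim, "field_sim_config"),
            all(stages %in% growth_stages()), length(stages) >= 1)
  if (!identical(ndvi_threshold, "auto") &&
      (!is.numeric(ndvi_threshold) || abs(ndvi_threshold) >= 1))
    stop("`ndvi_threshold` must be \"auto\" or a number in (-1, 1)")
  structure(list(sim = sim, stages = stages, bin_widths = bin_widths,
                 ndvi_threshold = ndvi_threshold, percentile = percentile,
                 split_seed = as.integer(split_seed)),
            class = "pipeline_config")
}

#' Run the full uniformity pipeline on a simulated field
#'
#' For every plot and stage: renders the two-band reflectance scene,
#' computes NDVI and (with the valley or fixed threshold) the FVC map;
#' simulates the LAI, SPAD and PH rasters; and emits the 24-statistic
#' uniformity battery (6 statistics x 4 traits). Yield and biomass are
#' then generated from the flowering-stage LAI mean and Pielou index,
#' correlated with every index, and an index-based multiple linear
#' regression is fitted with a seeded 7:3 split. Every table is written
#' to `out_dir` together with a log of the package version, seeds and
#' full configuration; reruns with the same configuration reproduce every
#' output.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `battery`, `outcomes`, `correlations`,
#'   `model` and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$sim
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("canopyuniformity %s",
       as.character(utils::packageVersion("canopyuniformity")))
  logf("sim_seed=%d split_seed=%d", sim$seed, cfg$split_seed)
  logf("config=%s", jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE,
                                     digits = NA))

  # threshold: auto = valley detection on stage-wise NDVI of plot 1
  scenes <- lapply(cfg$stages, function(st)
    simulate_spectral_scene(sim, 1L, stage = st))
  ndvis <- lapply(scenes, function(sc) compute_ndvi(sc$red, sc$nir))
  threshold <- if (identical(cfg$ndvi_threshold, "auto"))
    find_valley_threshold(ndvis)$threshold else cfg$ndvi_threshold
  logf("ndvi_threshold=%.6f", threshold)

  battery <- list()
  for (p in seq_len(sim$n_plots)) {
    for (st in cfg$stages) {
      recs <- tryCatch({
        sc <- simulate_spectral_scene(sim, p, stage = st,
                                      full_cover = FALSE)
        fv <- compute_fvc(compute_ndvi(sc$red, sc$nir), threshold)
        rows <- list(uniformity_battery(fv$veg_mask))
        for (tr in c("LAI", "SPAD", "PH")) {
          r <- simulate_trait_raster(sim, tr, p, stage = st)
          rows[[tr]] <- uniformity_battery(r,
                                           bin_width = cfg$bin_widths[[tr]])
        }
        do.call(rbind, rows)
      }, error = function(e)
        stop("stage '", st, "', plot ", p, ": ", conditionMessage(e),
             call. = FALSE))
      battery[[paste(p, st)]] <- recs
    }
  }
  battery <- do.call(rbind, battery)
  rownames(battery) <- NULL

  # outcomes from the flowering-stage LAI mean and Pielou index
  fs <- battery[battery$stage == "FS" & battery$trait == "LAI", ]
  pj <- fs$value[fs$index == "pielou"][order(as.integer(fs$plot_id[fs$index == "pielou"]))]
  mu <- fs$value[fs$index == "mean"][order(as.integer(fs$plot_id[fs$index == "mean"]))]
  outcomes <- simulate_yield_table(sim, pj, mu)
  correlations <- correlate_uniformity(battery, outcomes)

  wide <- data.frame(plot_id = outcomes$plot_id,
                     yield_mg_ha = outcomes$yield_mg_ha,
                     LJ_FS = pj, LM_FS = mu)
  model <- fit_mlr(yield_mg_ha ~ LJ_FS + LM_FS, wide, split = 0.7,
                   seed = cfg$split_seed)

  utils::write.csv(battery, file.path(out_dir, "uniformity.csv"),
                   row.names = FALSE)
  utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  write_model_json(model$model, file.path(out_dir, "model.json"))
  logf("records=%d plots=%d stages=%d", nrow(battery), sim$n_plots,
       length(cfg$stages))
  invisible(list(battery = battery, outcomes = outcomes,
                 correlations = correlations, model = model,
                 out_dir = out_dir))
}

# recursively strip S3 classes so a config serialises as plain JSON
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
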