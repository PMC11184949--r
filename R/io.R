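#' Write a trait raster to disk
#'
#' Two plain formats are supported, chosen by extension:
#' * `.tsv` — tab-separated value grid preceded by `#key=value` header
#'   lines (trait, plot, stage, gsd_m); invalid pixels are `NA`. Fully
#'   lossless for doubles (written at 17 significant digits).
#' * `.tif` — single-band 32-bit float TIFF (via the tiff package);
#'   invalid pixels are stored as NaN. Round-trips within float32
#'   precision.
#'
#' @param r a [trait_raster()].
#' @param path output file ending in `.tsv` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_trait_raster <- function(r, path) {
  stopifnot(inherits(r, "trait_raster"))
  ext <- tolower(tools::file_ext(path))
  v <- r$values
  v[!r$mask] <- NA_real_
  if (ext == "tsv") {
    hdr <- sprintf("#%s=%s",
                   c("trait", "plot_id", "stage", "gsd_m"),
                   c(r$trait, as.character(r$plot_id), as.character(r$stage),
                     format(r$gsd_m, digits = 17)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
                       con, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE, na = "NA")
  } else if (ext %in% c("tif", "tiff")) {
    vv <- v
    vv[is.na(vv)] <- NaN
    tiff::writeTIFF(vv, path, bits.per.sample = 32L, reduce = FALSE)
    # sidecar metadata so the round-trip restores tags and GSD
    meta <- list(trait = r$trait, plot_id = as.character(r$plot_id),
                 stage = as.character(r$stage), gsd_m = r$gsd_m)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported raster extension '", ext, "' (use .tsv or .tif)")
  invisible(path)
}

#' Read a trait raster written by [write_trait_raster()]
#'
#' @param path file ending in `.tsv` or `.tif`/`.tiff`.
#' @return A [trait_raster()].
#' @export
read_trait_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    lines <- readLines(path)
    hdr_n <- sum(startsWith(lines, "#"))
    meta <- list()
    for (h in lines[seq_len(hdr_n)]) {
      kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
      meta[[kv[1]]] <- kv[2]
    }
    v <- as.matrix(utils::read.table(text = lines[-seq_len(hdr_n)],
                                     sep = "\t", na.strings = "NA"))
    dimnames(v) <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    v[is.nan(v)] <- NA_real_
    meta <- jsonlite::fromJSON(paste0(path, ".json"))
  } else stop("unsupported raster extension '", ext, "'")
  stage <- as.character(meta$stage)
  trait_raster(v, !is.na(v), gsd_m = as.numeric(meta$gsd_m),
               trait = meta$trait, plot_id = meta$plot_id,
               stage = if (stage == "NA") NA_character_ else stage)
}

#' Write / read plot ROI polygons as GeoJSON
#'
#' Coordinates are planar metres in the local plot frame (no CRS); each
#' feature carries a `plot_id` property.
#'
#' @param rois named list of two-column vertex matrices (names = plot
#'   ids).
#' @param path GeoJSON file path.
#' @return `path` (write) / named list of matrices (read).
#' @export
write_roi_geojson <- function(rois, path) {
  feats <- lapply(names(rois), function(id) {
    ring <- as.matrix(rois[[id]])
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(plot_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_geojson
#' @export
read_roi_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (f in g$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    out[[as.character(f$properties$plot_id)]] <- ring
  }
  out
}

#' Write / read a point cloud as XYZ text
#'
#' Three whitespace-separated columns `x y z` in metres, no header.
#'
#' @param cloud data frame with `x`, `y`, `z`.
#' @param path file path.
#' @return `path` (write) / data frame (read).
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  utils::write.table(format(cloud[c("x", "y", "z")], digits = 17,
                            trim = TRUE, scientific = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  d <- utils::read.table(path, col.names = c("x", "y", "z"))
  d
}

#' Read a per-plot outcome table
#'
#' CSV with header `plot_id,yield_mg_ha,biomass_mg_ha` (yield and biomass
#' in Mg/ha); a malformed header raises an error listing the expected
#' columns.
#'
#' @param path CSV file path.
#' @return Data frame with character `plot_id`.
#' @export
read_outcomes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "yield_mg_ha", "biomass_mg_ha")
  if (!all(need %in% names(d)))
    stop("malformed outcomes CSV; expected columns: ",
         paste(need, collapse = ", "))
  d$plot_id <- as.character(d$plot_id)
  d
}

#' Write / read a linear model as JSON
#'
#' Stores predictor names, coefficients, intercept, response and
#' provenance; the round-trip is exact for doubles.
#'
#' @param model a [linear_model()].
#' @param path JSON file path.
#' @return `path` (write) / [linear_model()] (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "linear_model"))
  jsonlite::write_json(
    list(response = model$response, provenance = model$provenance,
         intercept = model$intercept,
         coefficients = as.list(stats::setNames(model$coefficients,
                                                model$predictor_names))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::fromJSON(path)
  linear_model(names(m$coefficients), unlist(m$coefficients), m$intercept,
               response = m$response, provenance = m$provenance)
}
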