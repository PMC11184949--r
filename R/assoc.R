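#' Correlate uniformity indices with yield and biomass
#'
#' Joins long-format uniformity records to a per-plot outcome table and
#' computes a Pearson correlation for every (trait, index, stage)
#' combination, against each outcome column. Pairs with missing values are
#' dropped pairwise and the effective n is reported; a zero-variance
#' variable yields `NA` (undefined marker).
#'
#' @param records data frame from [uniformity_battery()] (columns
#'   `plot_id, stage, trait, index, value`).
#' @param outcomes data frame with `plot_id` and one or more outcome
#'   columns (default `yield_mg_ha`, `biomass_mg_ha`).
#' @param outcome_cols names of the outcome columns to use.
#' @return Data frame with one row per (trait, index, stage, outcome):
#'   `r`, `n`.
#' @export
correlate_uniformity <- function(records, outcomes,
                                 outcome_cols = c("yield_mg_ha",
                                                  "biomass_mg_ha")) {
  stopifnot(all(c("plot_id", "stage", "trait", "index", "value") %in%
                  names(records)),
            "plot_id" %in% names(outcomes),
            all(outcome_cols %in% names(outcomes)))
  keys <- unique(records[c("trait", "index", "stage")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    rec <- records[records$trait == k$trait & records$index == k$index &
                     (records$stage == k$stage |
                        (is.na(records$stage) & is.na(k$stage))), ]
    m <- merge(rec[c("plot_id", "value")], outcomes, by = "plot_id")
    do.call(rbind, lapply(outcome_cols, function(oc) {
      r <- pearson_r(m$value, m[[oc]])
      data.frame(trait = k$trait, index = k$index, stage = k$stage,
                 outcome = oc, r = r$r, n = r$n)
    }))
  }))
  rownames(out) <- NULL
  out
}

pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x)))
  list(r = stats::cor(x, y), n = length(x))
}

#' Linear prediction model container
#'
#' A minimal, immutable representation of a multiple linear regression
#' model: named predictors, their coefficients, and an intercept. Both
#' freshly fitted models and the shipped frozen reference equations use
#' this container, so they can be evaluated interchangeably.
#'
#' @param predictor_names character vector of predictor tags (e.g.
#'   `"LJ_FS"`).
#' @param coefficients numeric vector aligned with `predictor_names`.
#' @param intercept intercept term.
#' @param response `"yield"` or `"biomass"`.
#' @param provenance free-form provenance tag (e.g. `"fitted"`).
#' @return Object of class `linear_model`.
#' @export
linear_model <- function(predictor_names, coefficients, intercept,
                         response = c("yield", "biomass"),
                         provenance = "fitted") {
  response <- match.arg(response)
  if (length(predictor_names) != length(coefficients))
    stop("one coefficient per predictor is required")
  structure(list(predictor_names = as.character(predictor_names),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 response = response, provenance = provenance),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model> %s (%s)\n", x$response, x$provenance))
  cat(sprintf("  intercept %.4g + %d terms\n", x$intercept,
              length(x$coefficients)))
  invisible(x)
}

#' Load a frozen reference prediction equation
#'
#' Returns one of the four shipped wheat yield/biomass equations: multiple
#' linear regressions over three key stages (jointing JS, flowering FS,
#' late filling LFS), either on the four trait means (FM, LM, SM, PM) or
#' on the selected uniformity indices (FE, LJ, SJ) plus the plant-height
#' mean PM. Coefficients are stored as package data and are immutable;
#' they apply to raw (unstandardised) predictor values.
#'
#' @param name one of `"yield_mean"`, `"biomass_mean"`, `"yield_index"`,
#'   `"biomass_index"`.
#' @return A [linear_model()].
#' @export
reference_model <- function(name = c("yield_mean", "biomass_mean",
                                     "yield_index", "biomass_index")) {
  name <- match.arg(name)
  path <- system.file("extdata", "reference_models.json",
                      package = "canopyuniformity", mustWork = TRUE)
  all <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  m <- all[[name]]
  linear_model(names(m$coefficients), unlist(m$coefficients), m$intercept,
               response = m$response, provenance = paste0("reference_", name))
}

#' Evaluate a linear model on named predictor values
#'
#' `intercept + sum(coefficient * value)`, exact arithmetic; every
#' predictor named by the model must be present.
#'
#' @param model a [linear_model()] or fitted [fit_mlr()] object.
#' @param predictors named numeric vector, one-row data frame, or named
#'   list of predictor values.
#' @return Predicted response (Mg/ha for the shipped models).
#' @export
evaluate_model <- function(model, predictors) {
  if (inherits(model, "uniformity_mlr")) model <- model$model
  stopifnot(inherits(model, "linear_model"))
  p <- unlist(predictors)
  missing <- setdiff(model$predictor_names, names(p))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  model$intercept +
    sum(model$coefficients * as.numeric(p[model$predictor_names]))
}

#' Fit a multiple linear regression with a held-out validation split
#'
#' Ordinary least squares on a seeded random training subset (default
#' 70%), with R-squared and RMSE reported on both the training and the
#' untouched validation rows. The design must be full rank; collinear
#' columns are reported by name.
#'
#' @param formula model formula, e.g. `yield_mg_ha ~ LJ_FS + FE_FS`.
#' @param data data frame with the response and predictors (wide format).
#' @param split training fraction in `(0, 1]`; `1` uses all rows.
#' @param seed RNG seed for the split (logged in the result).
#' @return Object of class `uniformity_mlr`: the underlying [stats::lm()]
#'   fit, a [linear_model()] snapshot, and a `report` with per-split R2
#'   and RMSE. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`.
#' @export
fit_mlr <- function(formula, data, split = 0.7, seed = 1L) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data),
            split > 0, split <= 1)
  n <- nrow(data)
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  if (nrow(X) <= ncol(X))
    stop("too few rows: need more observations than predictors + 1")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  n_train <- if (split == 1) n else max(ncol(X) + 1L, round(split * n))
  train_idx <- sort(sample.int(n, n_train))
  valid_idx <- setdiff(seq_len(n), train_idx)
  fit <- stats::lm(formula, data = data[train_idx, , drop = FALSE])
  cf <- stats::coef(fit)
  response <- all.vars(formula)[1]
  lmod <- linear_model(
    names(cf)[-1], unname(cf[-1]), unname(cf[1]),
    response = if (grepl("biomass", response)) "biomass" else "yield",
    provenance = "fitted")
  perf <- function(idx) {
    if (!length(idx)) return(list(r2 = NA_real_, rmse = NA_real_, n = 0L))
    obs <- stats::model.response(stats::model.frame(formula,
                                                    data[idx, , drop = FALSE]))
    pred <- stats::predict(fit, newdata = data[idx, , drop = FALSE])
    f <- r2_rmse(obs, pred)
    list(r2 = unname(f["r2"]), rmse = unname(f["rmse"]), n = length(idx))
  }
  structure(list(fit = fit, model = lmod, formula = formula,
                 report = list(train = perf(train_idx),
                               validation = perf(valid_idx),
                               split = split, seed = as.integer(seed),
                               train_idx = train_idx,
                               validation_idx = valid_idx)),
            class = "uniformity_mlr")
}

#' @export
print.uniformity_mlr <- function(x, ...) {
  r <- x$report
  cat("<uniformity_mlr> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  train:      R2 = %.3f, RMSE = %.4g (n = %d)\n",
              r$train$r2, r$train$rmse, r$train$n))
  if (r$validation$n > 0)
    cat(sprintf("  validation: R2 = %.3f, RMSE = %.4g (n = %d)\n",
                r$validation$r2, r$validation$rmse, r$validation$n))
  invisible(x)
}

#' @export
summary.uniformity_mlr <- function(object, ...) summary(object$fit, ...)

#' @export
coef.uniformity_mlr <- function(object, ...) stats::coef(object$fit)

#' @export
predict.uniformity_mlr <- function(object, newdata, ...)
  stats::predict(object$fit, newdata = newdata, ...)

#' @export
residuals.uniformity_mlr <- function(object, ...) stats::residuals(object$fit)

#' Cluster cultivars by yield and biomass
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances of z-scored yield and biomass), cut at `k` clusters. Clusters
#' are relabelled `C1..Ck` by descending mean yield, so C1 is always the
#' high-yield group.
#'
#' @param data data frame with columns `cultivar`, `yield` and `biomass`
#'   (per-cultivar means).
#' @param k number of clusters.
#' @return List with `labels` (factor `C1..Ck` per cultivar), `means`
#'   (per-cluster yield/biomass means), and the `hclust` tree.
#' @export
cluster_cultivars <- function(data, k = 3) {
  stopifnot(all(c("cultivar", "yield", "biomass") %in% names(data)))
  n <- nrow(data)
  if (k > n) stop("cannot form ", k, " clusters from ", n, " cultivars")
  z <- scale(as.matrix(data[c("yield", "biomass")]))
  z[is.nan(z)] <- 0
  tree <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  ord <- order(tapply(data$yield, raw, mean), decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- factor(paste0("C", relabel[raw]),
                   levels = paste0("C", seq_len(k)))
  means <- do.call(rbind, lapply(levels(labels), function(l) {
    sel <- labels == l
    data.frame(cluster = l, n = sum(sel), yield = mean(data$yield[sel]),
               biomass = mean(data$biomass[sel]))
  }))
  list(labels = stats::setNames(labels, data$cultivar), means = means,
       tree = tree)
}

#' One- and two-way analysis of variance
#'
#' Classical sums-of-squares F tests via [stats::aov()]. The two-way
#' layout is fitted with main effects only by default (one replicate per
#' cell, e.g. cultivar-by-year means, leaves no degrees of freedom for an
#' interaction); set `interaction = TRUE` when replicates exist.
#'
#' @param values numeric response vector.
#' @param groups factor (one-way) — or, for two-way, pass `groups` and
#'   `groups2`.
#' @param groups2 optional second factor.
#' @param interaction include the interaction term (two-way only)?
#' @return Data frame with one row per model term: `term`, `df`, `F`,
#'   `p_value`.
#' @export
anova_effects <- function(values, groups, groups2 = NULL,
                          interaction = FALSE) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("`groups` must have at least two levels")
  if (is.null(groups2)) {
    fit <- stats::aov(values ~ groups)
  } else {
    groups2 <- factor(groups2)
    if (nlevels(groups2) < 2L) stop("`groups2` must have at least two levels")
    fit <- if (interaction) stats::aov(values ~ groups * groups2)
           else stats::aov(values ~ groups + groups2)
  }
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df = tab$Df[keep],
             F = tab$`F value`[keep], p_value = tab$`Pr(>F)`[keep])
}

#' Sensitivity of index-outcome correlations to the classification parameter
#'
#' Recomputes the entropy-based indices (Shannon, Pielou, Alatalo) of one
#' trait's plot rasters at each candidate bin width, and correlates each
#' index with yield and biomass across plots. Widths so coarse that every
#' plot collapses into one class give zero-variance indices and an `NA`
#' correlation (degenerate, flagged not dropped).
#'
#' @param rasters list of [trait_raster()]s, one per plot (same trait).
#' @param outcomes per-plot outcome table (`plot_id, yield_mg_ha,
#'   biomass_mg_ha`).
#' @param widths increasing vector of bin widths; defaults per trait via
#'   [default_sweep_widths()].
#' @return Data frame `axis, axis_value, index, outcome, r, n`
#'   (`axis = "bin_width"`).
#' @export
sweep_bin_width <- function(rasters, outcomes, widths = NULL) {
  stopifnot(length(rasters) >= 3)
  trait <- rasters[[1]]$trait
  if (is.null(widths)) widths <- default_sweep_widths(trait)
  if (is.unsorted(widths, strictly = TRUE))
    stop("`widths` must be strictly increasing")
  out <- do.call(rbind, lapply(widths, function(w) {
    bat <- do.call(rbind, lapply(rasters, uniformity_battery, bin_width = w))
    bat <- bat[bat$index %in% c("shannon", "pielou", "alatalo"), ]
    cc <- correlate_uniformity(bat, outcomes)
    data.frame(axis = "bin_width", axis_value = w, index = cc$index,
               outcome = cc$outcome, r = cc$r, n = cc$n)
  }))
  rownames(out) <- NULL
  out
}

#' Default bin-width grids for the sensitivity sweep
#'
#' LAI: 0.25-7.5 (9 values); SPAD: 1-40 (10 values); PH: 1-50 cm
#' (11 values).
#'
#' @param trait trait tag.
#' @return Increasing numeric vector of bin widths.
#' @export
default_sweep_widths <- function(trait) {
  switch(trait,
         LAI = c(0.25, 0.5, 1, 1.5, 2, 2.5, 3.75, 5, 7.5),
         SPAD = c(1, 2, 4, 6, 8, 10, 15, 20, 30, 40),
         PH = c(1, 2, 4, 6, 8, 10, 15, 20, 30, 40, 50),
         stop("no sweep grid for trait '", trait, "'"))
}

#' Sensitivity of index-outcome correlations to spatial resolution
#'
#' Degrades every plot raster by each aggregation factor (emulating
#' coarser ground sampling distances), recomputes the entropy-based
#' indices at a fixed bin width, and correlates them with yield and
#' biomass.
#'
#' @inheritParams sweep_bin_width
#' @param factors increasing integer aggregation factors (1 = native
#'   resolution).
#' @param bin_width classification parameter held fixed across
#'   resolutions.
#' @return Data frame `axis, axis_value, index, outcome, r, n`
#'   (`axis = "gsd"`, `axis_value` in metres).
#' @export
sweep_resolution <- function(rasters, outcomes, factors = c(1, 2, 4, 8),
                             bin_width = NULL) {
  stopifnot(length(rasters) >= 3)
  if (is.unsorted(factors, strictly = TRUE))
    stop("`factors` must be strictly increasing")
  if (is.null(bin_width)) bin_width <- default_bin_width(rasters[[1]]$trait)
  out <- do.call(rbind, lapply(factors, function(f) {
    bat <- do.call(rbind, lapply(rasters, function(r)
      uniformity_battery(degrade_resolution(r, f), bin_width = bin_width)))
    bat <- bat[bat$index %in% c("shannon", "pielou", "alatalo"), ]
    cc <- correlate_uniformity(bat, outcomes)
    data.frame(axis = "gsd", axis_value = f * rasters[[1]]$gsd_m,
               index = cc$index, outcome = cc$outcome, r = cc$r, n = cc$n)
  }))
  rownames(out) <- NULL
  out
}
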