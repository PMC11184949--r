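#' Configuration of the feed-forward trait regressor
#'
#' Hyperparameters of the single-hidden-layer back-propagation network
#' used to map spectral features to LAI or SPAD: hidden layer size (10 for
#' LAI, 20 for SPAD), number of full-batch gradient steps (5,000),
#' learning rate (0.005) and the train fraction of the seeded 2:1
#' train/test split.
#'
#' @param hidden_units hidden-layer width.
#' @param iterations gradient-descent steps.
#' @param learning_rate step size.
#' @param train_fraction fraction of samples used for training.
#' @param seed RNG seed for the split and weight initialisation.
#' @return Object of class `regressor_config`.
#' @export
regressor_config <- function(hidden_units = 10, iterations = 5000,
                             learning_rate = 0.005, train_fraction = 2 / 3,
                             seed = 1L) {
  stopifnot(hidden_units >= 1, iterations >= 1, learning_rate > 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "regressor_config")
}

r2_rmse <- function(obs, pred) {
  rmse <- sqrt(mean((obs - pred)^2))
  ss <- sum((obs - mean(obs))^2)
  r2 <- if (ss == 0) NA_real_ else 1 - sum((obs - pred)^2) / ss
  c(r2 = r2, rmse = rmse)
}

#' Train a feed-forward trait regressor
#'
#' Fits a single-hidden-layer network (tanh hidden units, linear output)
#' by full-batch gradient descent on the mean squared error, after
#' standardising features and target. The data are first split into
#' training and test sets at the configured ratio (seeded, reproducible);
#' fit quality (R-squared and RMSE) is reported on both splits. A constant
#' target is flagged as degenerate (R-squared undefined).
#'
#' @param features numeric matrix (samples x features).
#' @param targets numeric vector of trait values.
#' @param cfg a [regressor_config()].
#' @return Object of class `trait_regressor` with a `report` element
#'   (train/test R2 and RMSE, split indices) supporting [predict()].
#' @export
train_trait_regressor <- function(features, targets, cfg = regressor_config()) {
  features <- as.matrix(features)
  targets <- as.numeric(targets)
  if (nrow(features) != length(targets))
    stop("`features` and `targets` must have the same number of samples")
  if (nrow(features) < 3L) stop("at least 3 samples are required")
  if (any(!is.finite(features)) || any(!is.finite(targets)))
    stop("features and targets must be finite")
  stopifnot(inherits(cfg, "regressor_config"))

  n <- nrow(features); d <- ncol(features); h <- cfg$hidden_units
  set.seed(cfg$seed)
  n_train <- max(2L, round(cfg$train_fraction * n))
  train_idx <- sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)

  x_center <- colMeans(features[train_idx, , drop = FALSE])
  x_scale <- apply(features[train_idx, , drop = FALSE], 2L, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(targets[train_idx])
  y_scale <- stats::sd(targets[train_idx])
  degenerate <- is.na(y_scale) || y_scale == 0
  if (degenerate) y_scale <- 1

  X <- scale(features[train_idx, , drop = FALSE], x_center, x_scale)
  y <- (targets[train_idx] - y_center) / y_scale

  W1 <- matrix(stats::runif(d * h, -0.7, 0.7) / sqrt(d), d, h)
  b1 <- numeric(h)
  w2 <- stats::runif(h, -0.7, 0.7) / sqrt(h)
  b2 <- 0
  if (degenerate) {
    # constant target: nothing to fit; predict the constant exactly
    w2 <- numeric(h); b2 <- 0
  }
  m <- length(y)
  for (it in if (degenerate) integer(0) else seq_len(cfg$iterations)) {
    A <- tanh(sweep(X %*% W1, 2L, b1, "+"))
    yhat <- drop(A %*% w2) + b2
    e <- (yhat - y) / m
    gw2 <- drop(crossprod(A, e)); gb2 <- sum(e)
    dA <- (e %o% w2) * (1 - A^2)
    gW1 <- crossprod(X, dA); gb1 <- colSums(dA)
    lr <- cfg$learning_rate
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    w2 <- w2 - lr * gw2; b2 <- b2 - lr * gb2
  }

  reg <- structure(
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         cfg = cfg, degenerate = degenerate),
    class = "trait_regressor")

  fit_tr <- r2_rmse(targets[train_idx], predict(reg, features[train_idx, , drop = FALSE]))
  fit_te <- if (length(test_idx))
    r2_rmse(targets[test_idx], predict(reg, features[test_idx, , drop = FALSE]))
  else c(r2 = NA_real_, rmse = NA_real_)
  reg$report <- list(
    train = list(r2 = unname(fit_tr["r2"]), rmse = unname(fit_tr["rmse"]),
                 n = length(train_idx)),
    test = list(r2 = unname(fit_te["r2"]), rmse = unname(fit_te["rmse"]),
                n = length(test_idx)),
    train_idx = train_idx, test_idx = test_idx,
    degenerate_target = degenerate)
  reg
}

#' @param object a `trait_regressor`.
#' @param newdata numeric matrix of features.
#' @param ... unused.
#' @rdname train_trait_regressor
#' @export
predict.trait_regressor <- function(object, newdata, ...) {
  X <- scale(as.matrix(newdata), object$x_center, object$x_scale)
  A <- tanh(sweep(X %*% object$W1, 2L, object$b1, "+"))
  drop(A %*% object$w2 + object$b2) * object$y_scale + object$y_center
}

#' @export
print.trait_regressor <- function(x, ...) {
  cat(sprintf("<trait_regressor> %d features -> %d tanh units -> linear output\n",
              nrow(x$W1), length(x$b1)))
  r <- x$report
  cat(sprintf("  train: R2 = %.3f, RMSE = %.4g (n = %d)\n",
              r$train$r2, r$train$rmse, r$train$n))
  cat(sprintf("  test:  R2 = %.3f, RMSE = %.4g (n = %d)\n",
              r$test$r2, r$test$rmse, r$test$n))
  if (r$degenerate_target)
    cat("  note: constant target; R2 undefined\n")
  invisible(x)
}

#' Predict a trait raster from feature rasters
#'
#' Applies a fitted [train_trait_regressor()] model pixelwise to a stack
#' of co-registered feature rasters, producing a per-pixel trait map. The
#' intersection of the feature masks is propagated.
#'
#' @param regressor a `trait_regressor`.
#' @param feature_rasters list of [trait_raster()]s (one per feature,
#'   identical geometry).
#' @param trait trait tag for the output raster.
#' @return A [trait_raster()] of predictions.
#' @export
predict_trait_raster <- function(regressor, feature_rasters, trait = "LAI") {
  stopifnot(inherits(regressor, "trait_regressor"), length(feature_rasters) >= 1)
  dims <- dim(feature_rasters[[1]]$values)
  mask <- Reduce(`&`, lapply(feature_rasters, function(r) {
    if (!all(dim(r$values) == dims)) stop("feature rasters must share geometry")
    r$mask
  }))
  X <- do.call(cbind, lapply(feature_rasters, function(r) r$values[mask]))
  vals <- matrix(NA_real_, dims[1], dims[2])
  vals[mask] <- predict(regressor, X)
  r1 <- feature_rasters[[1]]
  trait_raster(vals, mask, gsd_m = r1$gsd_m, trait = trait,
               plot_id = r1$plot_id, stage = r1$stage)
}
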