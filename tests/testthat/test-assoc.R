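# correlation, MLR fitting, frozen reference equations, clustering, ANOVA

make_records <- function(values, index = "pielou", trait = "LAI",
                         stage = "FS") {
  data.frame(plot_id = as.character(seq_along(values)), stage = stage,
             trait = trait, index = index, value = values)
}

test_that("correlations recover exact linear relations", {
  x <- c(1, 2, 3, 4, 5)
  out <- data.frame(plot_id = as.character(1:5), yield_mg_ha = 2 * x,
                    biomass_mg_ha = -x + 10)
  cc <- correlate_uniformity(make_records(x), out)
  expect_equal(cc$r[cc$outcome == "yield_mg_ha"], 1)
  expect_equal(cc$r[cc$outcome == "biomass_mg_ha"], -1)
  expect_equal(cc$n, c(5L, 5L))
})

test_that("zero variance and missing pairs yield NA markers and reduced n", {
  out <- data.frame(plot_id = as.character(1:6),
                    yield_mg_ha = c(rnorm(5), NA),
                    biomass_mg_ha = rep(4, 6))
  cc <- correlate_uniformity(make_records(c(1, 2, 3, 4, 5, 6)), out)
  expect_equal(cc$n[cc$outcome == "yield_mg_ha"], 5L)  # pairwise deletion
  expect_true(is.na(cc$r[cc$outcome == "biomass_mg_ha"]))
})

test_that("the planted uniformity effect is recovered with the right sign", {
  st <- sim_uniformity_study(n_plots = 100, seed = 23)
  cc <- correlate_uniformity(st$battery, st$outcomes)
  r <- cc$r[cc$index == "pielou" & cc$outcome == "yield_mg_ha"]
  expect_lt(r, 0)
})

test_that("fit_mlr equals the normal-equation oracle and recovers beta", {
  set.seed(9)
  n <- 40
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  beta <- c(2, -1, 0.5)
  d$yield_mg_ha <- 3 + as.matrix(d) %*% beta
  fit <- fit_mlr(yield_mg_ha ~ a + b + c, d, split = 0.7, seed = 1)
  expect_equal(unname(coef(fit)), c(3, beta), tolerance = 1e-8)

  # oracle: closed-form least squares on the same training rows
  tr <- fit$report$train_idx
  X <- cbind(1, as.matrix(d[tr, c("a", "b", "c")]))
  bhat <- solve(crossprod(X), crossprod(X, d$yield_mg_ha[tr]))
  expect_equal(unname(coef(fit)), as.vector(bhat), tolerance = 1e-8)
  expect_equal(fit$report$validation$rmse, 0, tolerance = 1e-7)
  expect_equal(fit$report$train$r2, 1, tolerance = 1e-10)
})

test_that("fit_mlr splits are seeded and degenerate designs error", {
  set.seed(10)
  d <- data.frame(a = rnorm(30), yield_mg_ha = rnorm(30))
  f1 <- fit_mlr(yield_mg_ha ~ a, d, seed = 7)
  f2 <- fit_mlr(yield_mg_ha ~ a, d, seed = 7)
  expect_identical(f1$report$train_idx, f2$report$train_idx)
  expect_identical(coef(f1), coef(f2))
  # response orthogonal to the predictor: near-zero R2
  expect_lt(abs(f1$report$train$r2), 0.3)

  d$b <- 2 * d$a
  expect_error(fit_mlr(yield_mg_ha ~ a + b, d), "collinear.*b")
  expect_error(fit_mlr(yield_mg_ha ~ a, d[1:2, ]), "too few")
})

test_that("uniformity_mlr behaves like a classic fitted model object", {
  set.seed(12)
  d <- data.frame(a = rnorm(30))
  d$yield_mg_ha <- 1 + 2 * d$a + rnorm(30, sd = 0.1)
  fit <- fit_mlr(yield_mg_ha ~ a, d, split = 1, seed = 1)
  expect_output(print(fit), "uniformity_mlr")
  expect_s3_class(summary(fit), "summary.lm")
  expect_length(residuals(fit), 30)
  expect_equal(unname(predict(fit, data.frame(a = 0))),
               unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(evaluate_model(fit, c(a = 1)), unname(sum(coef(fit))),
               tolerance = 1e-12)
})

test_that("frozen reference equations evaluate exactly as printed", {
  zero12 <- function(m) stats::setNames(rep(0, 12), m$predictor_names)
  ym <- reference_model("yield_mean")
  bm <- reference_model("biomass_mean")
  yi <- reference_model("yield_index")
  bi <- reference_model("biomass_index")
  expect_equal(evaluate_model(ym, zero12(ym)), -4.934)
  expect_equal(evaluate_model(bm, zero12(bm)), -8.566)
  expect_equal(evaluate_model(yi, zero12(yi)), 6.621)
  expect_equal(evaluate_model(bi, zero12(bi)), 13.609)

  p <- zero12(yi); p["LJ_FS"] <- 1
  expect_equal(evaluate_model(yi, p) - 6.621, -2.559, tolerance = 1e-12)
  q <- zero12(bi); q["SJ_JS"] <- 1
  expect_equal(evaluate_model(bi, q) - 13.609, 13.550, tolerance = 1e-12)

  # general linear combination against a direct dot-product oracle
  set.seed(13)
  v <- stats::setNames(rnorm(12), yi$predictor_names)
  expect_equal(evaluate_model(yi, v),
               yi$intercept + sum(yi$coefficients * v), tolerance = 1e-12)
  expect_error(evaluate_model(yi, v[-1]), "missing predictor.*FE_JS")
})

test_that("cultivar clustering recovers planted groups, labelled by yield", {
  set.seed(14)
  g <- data.frame(
    cultivar = paste0("cv", 1:30),
    yield = c(rnorm(10, 9, 0.2), rnorm(10, 6.5, 0.2), rnorm(10, 5, 0.2)),
    biomass = c(rnorm(10, 18, 0.4), rnorm(10, 15, 0.4), rnorm(10, 11, 0.4)))
  cl <- cluster_cultivars(g, k = 3)
  truth <- rep(c("C1", "C2", "C3"), each = 10)
  expect_equal(as.character(cl$labels), truth)
  expect_true(all(diff(cl$means$yield) < 0))  # C1 > C2 > C3 by mean yield

  one <- cluster_cultivars(g, k = 1)
  expect_equal(nlevels(one$labels), 1L)
  dup <- rbind(g[1, ], g[1, ]); dup$cultivar <- c("a", "b")
  dd <- cluster_cultivars(rbind(dup, g[11:30, ]), k = 3)
  expect_equal(dd$labels[["a"]], dd$labels[["b"]])
  expect_error(cluster_cultivars(g, k = 31), "cannot form")
})

test_that("two-group ANOVA reduces to the squared t test", {
  set.seed(15)
  v <- rnorm(24); g <- rep(c("a", "b"), each = 12)
  a <- anova_effects(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA detects planted effects and validates factors", {
  set.seed(16)
  v <- c(rnorm(20), rnorm(20, mean = 5))
  a <- anova_effects(v, rep(c("lo", "hi"), each = 20))
  expect_lt(a$p_value, 1e-6)

  # two-way main effects, cultivar x year, one replicate per cell
  cult <- rep(paste0("c", 1:10), times = 2)
  year <- rep(c("y1", "y2"), each = 10)
  eff <- rep(seq(0, 0.9, by = 0.1), times = 2) + (year == "y2") * 2
  tw <- anova_effects(eff + rnorm(20, sd = 0.05), cult, year)
  expect_equal(nrow(tw), 2L)
  expect_lt(tw$p_value[tw$term == "groups2"], 1e-6)
  expect_error(anova_effects(v, rep("a", 40)), "two levels")
})

test_that("bin-width sweep flags degenerate widths and keeps nesting order", {
  st <- sim_uniformity_study(n_plots = 30, seed = 33)
  sw <- sweep_bin_width(st$rasters, st$outcomes, widths = c(0.25, 0.5, 1, 1000))
  expect_true(all(is.na(sw$r[sw$axis_value == 1000])))  # one class everywhere

  # per-plot Shannon entropy is non-increasing on the nested grid
  for (r in st$rasters[1:5]) {
    h <- vapply(c(0.25, 0.5, 1), function(w)
      shannon_entropy(bin_values(raster_values(r), w)), numeric(1))
    expect_true(all(diff(h) <= 1e-12))
  }
  expect_error(sweep_bin_width(st$rasters, st$outcomes, widths = c(2, 1)),
               "increasing")
})

test_that("resolution sweep degrades the GSD axis as configured", {
  st <- sim_uniformity_study(n_plots = 12, seed = 44)
  sr <- sweep_resolution(st$rasters, st$outcomes, factors = c(1, 2),
                         bin_width = 0.5)
  expect_setequal(unique(sr$axis_value), c(0.03, 0.06))
  expect_setequal(unique(sr$index), c("shannon", "pielou", "alatalo"))
})
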