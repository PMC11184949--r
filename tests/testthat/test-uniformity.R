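# discretisation and the entropy/variance index battery

test_that("bin_values assigns half-open bins and drops empty classes", {
  d <- bin_values(c(0.1, 0.4, 0.6, 0.6), bin_width = 0.5)
  expect_equal(d$S, 2L)
  expect_equal(d$p, c(0.5, 0.5))
  expect_equal(sum(d$counts), 4L)

  same <- bin_values(rep(2.3, 7), bin_width = 0.5)
  expect_equal(same$S, 1L)
  expect_equal(same$p, 1)

  expect_error(bin_values(1:3, bin_width = 0), "positive")
  expect_error(bin_values(c(1, NA), bin_width = 1), "finite")
  expect_error(bin_values(numeric(0), bin_width = 1), "at least one")
})

test_that("uniform draws fill equal bins up to multinomial sampling error", {
  set.seed(42)
  d <- bin_values(runif(10000, 0, 5), bin_width = 0.5)
  expect_equal(d$S, 10L)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(d$p - 0.1) <= 3 * se))
})

test_that("entropy and evenness match hand-computed values", {
  d <- bin_values(rep(c(0.5, 1.5, 2.5), c(7, 2, 1)), bin_width = 1)
  expect_equal(d$p, c(0.7, 0.2, 0.1))
  H <- -(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1))
  expect_equal(shannon_entropy(d), H, tolerance = 1e-12)
  expect_equal(shannon_entropy(d), 0.801819, tolerance = 1e-6)
  expect_equal(pielou_index(d), H / log(3), tolerance = 1e-12)
  expect_equal(pielou_index(d), 0.72985, tolerance = 1e-4)
  expect_equal(alatalo_index(d), (1 / 0.54 - 1) / (exp(H) - 1),
               tolerance = 1e-12)
  expect_equal(alatalo_index(d), 0.69279, tolerance = 1e-4)
  expect_equal(sheldon_index(d), exp(H) / 3, tolerance = 1e-12)
  expect_equal(heip_index(d), (exp(H) - 1) / 2, tolerance = 1e-12)

  even2 <- bin_values(c(0.2, 1.2), bin_width = 1)
  expect_equal(shannon_entropy(even2), log(2))
  expect_equal(pielou_index(even2), 1)
  even3 <- bin_values(c(0.5, 1.5, 2.5), bin_width = 1)
  expect_equal(alatalo_index(even3), 1)

  single <- bin_values(rep(1, 5), bin_width = 1)
  expect_equal(shannon_entropy(single), 0)
  expect_equal(pielou_index(single), 0)   # S = 1 convention
  expect_equal(alatalo_index(single), 0)  # S = 1 convention
  expect_error(heip_index(single), "two classes")
})

test_that("every index matches straight-from-formula recomputation", {
  set.seed(7)
  for (i in 1:100) {
    d <- random_dist(sample(2:12, 1))
    p <- d$p
    H <- -sum(p * log(p))
    expect_equal(shannon_entropy(d), H, tolerance = 1e-10)
    expect_equal(pielou_index(d), H / log(length(p)), tolerance = 1e-10)
    expect_equal(alatalo_index(d), (1 / sum(p^2) - 1) / (exp(H) - 1),
                 tolerance = 1e-10)
    expect_equal(sheldon_index(d), exp(H) / length(p), tolerance = 1e-10)
    expect_equal(heip_index(d), (exp(H) - 1) / (length(p) - 1),
                 tolerance = 1e-10)
  }
})

test_that("entropy invariants hold on random distributions", {
  set.seed(11)
  for (i in 1:50) {
    d <- random_dist(sample(2:10, 1))
    H <- shannon_entropy(d)
    expect_gte(H, 0)
    expect_lte(H, log(d$S) + 1e-12)
    expect_true(pielou_index(d) >= 0 && pielou_index(d) <= 1 + 1e-12)
    expect_true(alatalo_index(d) >= 0 && alatalo_index(d) <= 1 + 1e-12)
    even <- all(abs(d$p - 1 / d$S) < 1e-12)
    expect_equal(abs(H - log(d$S)) < 1e-12, even)
  }
})

test_that("indices are invariant to common rescaling and to pixel order", {
  set.seed(13)
  v <- rlnorm(500)
  a <- bin_values(v, bin_width = 0.3, origin = 0.1)
  b <- bin_values(7 * v, bin_width = 7 * 0.3, origin = 7 * 0.1)
  expect_equal(shannon_entropy(a), shannon_entropy(b), tolerance = 1e-12)
  expect_equal(pielou_index(a), pielou_index(b), tolerance = 1e-12)
  expect_equal(alatalo_index(a), alatalo_index(b), tolerance = 1e-12)

  s <- bin_values(sample(v), bin_width = 0.3, origin = 0.1)
  expect_equal(shannon_entropy(s), shannon_entropy(a))
})

test_that("merging bins (coarsening) never increases Shannon entropy", {
  set.seed(17)
  for (i in 1:20) {
    v <- rnorm(400, mean = 5, sd = runif(1, 0.2, 2))
    h <- vapply(c(0.25, 0.5, 1), function(w)
      shannon_entropy(bin_values(v, w)), numeric(1))
    expect_true(all(diff(h) <= 1e-12))
  }
})

test_that("dispersion statistics follow the sample-variance convention", {
  ds <- dispersion_stats(c(2, 4, 6), extras = TRUE)
  expect_equal(ds$mean, 4)
  expect_equal(ds$variance, 4)
  expect_equal(ds$cv, 0.5)
  expect_equal(ds$clustering, 0)       # variance == mean, Poisson-like
  expect_equal(ds$mean_crowding, 4)    # m* = mean when var == mean

  cds <- dispersion_stats(rep(3, 5))
  expect_equal(cds$variance, 0)
  expect_equal(cds$cv, 0)

  zds <- dispersion_stats(c(-1, 0, 1), extras = TRUE)
  expect_equal(zds$mean, 0)
  expect_true(is.na(zds$cv))           # undefined marker, not an error
  expect_true(is.na(zds$mean_crowding))
})

test_that("the binary FVC distribution behaves like a two-class system", {
  v <- rep(c(0, 1), each = 50)
  d <- fvc_distribution(v)
  expect_equal(shannon_entropy(d), log(2))
  expect_equal(pielou_index(d), 1)

  full <- fvc_distribution(rep(1, 40))
  expect_equal(full$S, 1L)
  expect_equal(shannon_entropy(full), 0)
  expect_equal(pielou_index(full), 0)

  v6 <- rep(c(1, 0), c(60, 40))
  r <- make_raster(matrix(v6, 10, 10), trait = "FVC")
  bat <- uniformity_battery(r)
  expect_equal(bat$value[bat$index == "mean"], 0.6)
  expect_equal(bat$value[bat$index == "variance"], var(v6))
  expect_error(fvc_distribution(c(0, 0.5)), "binary")
})

test_that("the battery emits 6 statistics per trait, 24 over four traits", {
  const <- make_raster(matrix(2, 8, 8))
  bat <- uniformity_battery(const)
  expect_equal(nrow(bat), 6L)
  expect_equal(bat$value[bat$index == "mean"], 2)
  expect_equal(bat$value[bat$index == "variance"], 0)
  expect_equal(bat$value[bat$index == "shannon"], 0)
  expect_equal(bat$value[bat$index == "pielou"], 0)
  expect_equal(bat$value[bat$index == "alatalo"], 0)

  set.seed(5)
  four <- rbind(
    uniformity_battery(make_raster(matrix(rbinom(64, 1, 0.6), 8, 8),
                                   trait = "FVC")),
    uniformity_battery(make_raster(matrix(rnorm(64, 3, 0.7), 8, 8),
                                   trait = "LAI")),
    uniformity_battery(make_raster(matrix(rnorm(64, 45, 4), 8, 8),
                                   trait = "SPAD")),
    uniformity_battery(make_raster(matrix(rnorm(64, 80, 6), 8, 8),
                                   trait = "PH")))
  expect_equal(nrow(four), 24L)
  expect_equal(sum(four$index == "mean"), 4L)       # 4 trait means
  expect_equal(sum(four$index != "mean"), 20L)      # 20 uniformity indices
  expect_setequal(
    four$abbrev[four$trait == "PH"],
    c("PM", "PV", "PCV", "PHH", "PJ", "PE"))

  empty <- make_raster(matrix(1, 4, 4), mask = matrix(FALSE, 4, 4))
  expect_error(uniformity_battery(empty), "no valid pixels")
})

test_that("a heterogeneous plot scores higher Pielou than a uniform one", {
  # trait mean at a bin centre (3.25 for width 0.5): the generic alignment.
  # A mean sitting exactly on a bin edge splits a uniform plot into two
  # even classes and inflates Pielou — the binning translation dependence
  # discussed in the vignette.
  het <- list(SPAD = list(field_sd = 3, corr_length_m = 0.2),
              PH = list(field_sd = 5, corr_length_m = 0.2))
  means <- list(LAI = 3.25, SPAD = 45, PH = 80)
  cfg_hi <- field_sim_config(seed = 21, row_structure = FALSE,
    trait_means = means,
    heterogeneity = c(list(LAI = list(field_sd = 1.0, corr_length_m = 0.2)), het))
  cfg_lo <- field_sim_config(seed = 21, row_structure = FALSE,
    trait_means = means,
    heterogeneity = c(list(LAI = list(field_sd = 0.1, corr_length_m = 0.2)), het))
  p_hi <- pielou_index(bin_values(raster_values(
    simulate_trait_raster(cfg_hi, "LAI", 1)), 0.5))
  p_lo <- pielou_index(bin_values(raster_values(
    simulate_trait_raster(cfg_lo, "LAI", 1)), 0.5))
  expect_gt(p_hi, p_lo)
})

test_that("crop masking restricts continuous traits to vegetation pixels", {
  vals <- matrix(c(rep(1, 8), rep(5, 8)), 4, 4)
  veg <- matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 4, 4)
  r <- make_raster(vals)
  masked <- uniformity_battery(r, crop_mask = veg)
  expect_equal(masked$value[masked$index == "mean"], 1)
  unmasked <- uniformity_battery(r, crop_mask = veg, use_crop_mask = FALSE)
  expect_equal(unmasked$value[unmasked$index == "mean"], 3)
})
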