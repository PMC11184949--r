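# small deterministic fixtures shared across test files

make_raster <- function(values, mask = NULL, trait = "LAI", gsd = 0.03,
                        plot = "1", stage = "FS") {
  trait_raster(values, mask, gsd_m = gsd, trait = trait, plot_id = plot,
               stage = stage)
}

# config whose row stripes tile the plot exactly (50 rows of 0.025 m,
# 10-pixel row period) so the vegetated fraction is exactly one half
half_cover_cfg <- function(seed = 1) {
  field_sim_config(gsd_m = 0.025, plot_width_m = 1.5, plot_height_m = 1.25,
                   row_spacing_m = 0.25, seed = seed)
}

# random class distribution with S classes drawn from a Dirichlet-like draw
random_dist <- function(S, n = 1000) {
  w <- rgamma(S, shape = 1)
  counts <- as.vector(stats::rmultinom(1, n, w / sum(w)))
  counts[counts == 0] <- 1
  vals <- rep(seq_len(length(counts)) - 0.5, counts)
  bin_values(vals, bin_width = 1)
}
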