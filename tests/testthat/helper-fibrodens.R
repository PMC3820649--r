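# Shared fixtures for the fibrodens suite. Phantoms at landmark-grade voxel
# counts are expensive, so they are generated once per session and cached.

.phantom_cache <- new.env(parent = emptyenv())

# a phantom at one of the default trajectory weeks, cached by (week, grid)
cached_phantom <- function(week, grid = c(128L, 128L, 96L), seed = 42L) {
  key <- paste(week, paste(grid, collapse = "x"), seed, sep = "|")
  if (is.null(.phantom_cache[[key]])) {
    cfg <- phantom_config(grid_shape = grid, stage = default_stage(week),
                          rng_seed = seed)
    .phantom_cache[[key]] <- generate_phantom(cfg)
  }
  .phantom_cache[[key]]
}

# small config for fast structural tests
tiny_config <- function(week = 0L, f = NULL, seed = 7L, grid = c(40L, 40L, 36L)) {
  stage <- if (is.null(f)) default_stage(week) else stage_params(week, f, 3L)
  phantom_config(grid_shape = grid, stage = stage, rng_seed = seed)
}

# a tiny two-arm cohort (drug + matched vehicle) on a small grid
tiny_cohort_config <- function(n = 4L, seed = 11L, f_vehicle = 0.9,
                               f_drug = 0.2, assays = list(),
                               mortality = c(drug = 0, vehicle = 0)) {
  groups <- data.frame(group = c("drug", "vehicle"),
                       treatment = c("drug", "vehicle"),
                       matched_vehicle = c("vehicle", NA),
                       n = n, stringsAsFactors = FALSE)
  stage_table <- data.frame(group = c("drug", "vehicle"), week = 20L,
                            consolidation_fraction = c(f_drug, f_vehicle))
  cohort_config(groups = groups, timepoints = 20L, stage_table = stage_table,
                histology_noise_sd = 0.3, mortality_prob = mortality,
                assays = assays,
                phantom = phantom_config(grid_shape = c(40L, 40L, 36L)),
                n_patch_seeds = 3L, rng_seed = seed)
}

# analytic upper-tail probability of the two-component HU mixture
mixture_tail <- function(T, f, mix = mixture_params()) {
  f * pnorm(T, mix$mu_consolidated, mix$sigma_consolidated, lower.tail = FALSE) +
    (1 - f) * pnorm(T, mix$mu_aerated, mix$sigma_aerated, lower.tail = FALSE)
}

# brute-force density-curve oracle: per-threshold counting loop
curve_oracle <- function(values, grid) {
  vapply(grid, function(T) 100 * sum(values >= T) / length(values), numeric(1))
}

# exact two-sided permutation p for the pooled-t statistic of x vs y
permutation_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  t_of <- function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  t_obs <- abs(t_of(seq_len(nx)))
  combos <- utils::combn(length(pooled), nx)
  ts <- abs(apply(combos, 2, t_of))
  mean(ts >= t_obs - 1e-12)
}
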