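# small cohort specs reused across tests

tiny_spec <- function(..., seed = 42) {
  # blob coordinates scaled into the small (+/- 33 mm) test grid
  defaults <- list(
    n_per_group = c(ASC_delay = 10, ASC_nodelay = 10, NT = 8),
    grid_shape = c(12, 12, 12), voxel_size = c(6, 6, 6),
    effect_blobs = list(list(center_mm = c(-10, 5, 0), radius_mm = 12,
                             amplitude = 0.08, sign = -1,
                             groups = "ASC_delay", tissue = "GM")),
    latent_spatial_pattern = list(
      list(center_mm = c(8, 6, 2), radius_mm = 14, amplitude = 0.1,
           tissue = "GM"),
      list(center_mm = c(-6, -4, 4), radius_mm = 12, amplitude = 0.06,
           tissue = "WM")),
    seed = seed)
  args <- list(...)
  do.call(cohort_spec, c(args, defaults[setdiff(names(defaults), names(args))]))
}

# no group effects, no latent structure: pure noise around the template
null_spec <- function(..., seed = 42) {
  tiny_spec(global_gm_offset = 0, effect_blobs = list(),
            latent_loadings = c(VIQ = 0, FAS = 0, NWR = 0),
            latent_spatial_pattern = list(), ..., seed = seed)
}

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, spec) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(spec)
  .cohort_cache[[key]]
}

# a stat_map with prescribed t values on a fully-masked cubic grid
make_stat <- function(tvals, dims = c(8, 8, 8), df = 1e6, voxel = 1) {
  grid <- volume_grid(array(0, dims), rep(voxel, 3))
  structure(list(t = tvals, df = df, mask_index = seq_len(prod(dims)),
                 grid = grid, contrast = 1),
            class = "stat_map")
}

# latent-model matrices without the volumetric plumbing, for PLS unit tests
latent_data <- function(n, v, loading = 0.6, n_signal = ceiling(v / 8),
                        snr = 2, n_measures = 3) {
  f <- rnorm(n)
  pattern <- c(rep(1, n_signal), rep(0, v - n_signal))
  brain <- outer(f, pattern) * snr + matrix(rnorm(n * v), n, v)
  behavior <- sapply(seq_len(n_measures), function(i)
    loading * f + sqrt(1 - loading^2) * rnorm(n))
  colnames(behavior) <- paste0("m", seq_len(n_measures))
  list(brain = brain, behavior = behavior, pattern = pattern, f = f)
}
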