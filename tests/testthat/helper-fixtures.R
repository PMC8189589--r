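# shared reduced-scale fixtures; all sizes chosen so the whole suite runs
# in minutes on one CPU

tiny_cohort <- function(seed = 1L, rho = 0.8, ...) {
  generate_paired_cohort(n_paired = 10L, n_unpaired = 5L,
                         n_roi_vox = 60L, n_brain_vox = 120L,
                         planted_rho = rho, seed = seed, ...)
}

# a small smooth loading + expression pair for PLS tests
tiny_expression <- function(seed = 1L, n_samples = 100L, n_genes = 150L,
                            n_signal = 15L, effect_beta = 1,
                            noise_sd = 0.3) {
  coords <- make_lattice(80L, 2)
  set.seed(seed)
  loading <- generate_smooth_field(coords, 8)
  loading <- loading / sqrt(sum(loading^2))
  ex <- generate_expression(loading, coords, n_samples = n_samples,
                            n_genes = n_genes, n_signal = n_signal,
                            effect_beta = effect_beta, noise_sd = noise_sd,
                            seed = seed + 1L)
  list(coords = coords, loading = loading, ex = ex)
}

# influence response at matched sample voxels for a tiny_expression fixture
expression_response <- function(fx) {
  infl <- fx$loading / sd(fx$loading)
  infl[fx$ex$expression$source_voxel]
}
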