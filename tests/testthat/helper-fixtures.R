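# Shared synthetic fixtures, built once per test run. Sizes are kept at
# desk scale so the whole suite stays fast.

small_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_triads = 60, n_nac_triads = 24,
             nac_groups = c(a = 5, b = 4, c = 3, d = 3,
                            e = 3, f = 2, g = 2, h = 2),
             other_tf_families = c(MYB = 8, WRKY = 8),
             n_samples = 30, ...)
}

# One default small dataset reused across files.
fx <- local({
  cfg <- small_config()
  sim <- simulate_dataset(cfg)
  poly_info <- sim$truth$genes[sim$truth$genes$species == "polyploid", ]
  list(cfg = cfg, sim = sim, poly_info = poly_info,
       truth_tf = poly_info$gene[!is.na(poly_info$family)])
})
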