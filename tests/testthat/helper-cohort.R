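# A small shared cohort reused across test files (lazy, cached).
shared_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) {
      coh <<- simulate_cohort(sim_config(
        n_samples = 600, n_mt_probes = 20, n_auto_probes = 20,
        n_baf_sites = 200, plate_size = 96, seed = 101
      ))
    }
    coh
  }
})

# Lightweight config for loops: few probes / sites / variants.
light_config <- function(n_samples, seed, ...) {
  sim_config(n_samples = n_samples, n_mt_probes = 5, n_auto_probes = 4,
             n_baf_sites = 4, n_variants = 10, seed = seed, ...)
}
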