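# Small shared fixtures built once per test run.

fixture_library <- function(n = 6, seed = 2) {
  gen_library(n, clones_per_genotype = 2, seed = seed, include_wt = TRUE)
}

# A small structured cohort reused by several files.
fixture_sim <- function(n_genotypes = 6, n_cells = 40, seed = 7, ...) {
  lib <- gen_library(n_genotypes, seed = 11, include_wt = TRUE)
  cfg <- sim_config(n_genotypes = n_genotypes,
                    n_cells_per_genotype = n_cells,
                    n_genes = 300, seed = seed, ...)
  sim <- gen_counts(lib, cfg)
  list(lib = lib, cfg = cfg, sim = sim)
}
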