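# printed kinetic constants for the two nitrogen sources, and the
# 13-point assay grid, reused across the suite
amm_params <- function() kinetic_params(1.81, 0.02, 213.7, 81.3, T = 0.5)
nit_params <- function() kinetic_params(2.02, 0.31, 16.0, 2.29, T = 2)

assay_grid <- function() c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                           0.75, 1, 2, 5, 10)

# noise-free replicate-level data from a single-phase MM law
mono_data <- function(V, Km, grid = assay_grid(), replicates = 4) {
  S <- rep(grid, each = replicates)
  tibble::tibble(S_mM = S, v_umol_per_gDW_h = V * S / (Km + S))
}

# random valid two-stage parameter sets for property-style tests
random_params <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kinetic_params(
        V1 = runif(1, 0.5, 5),
        Km1 = runif(1, 0.01, 0.5),
        V2 = runif(1, 0, 50),
        Km2 = runif(1, 0.6, 100),
        T = runif(1, 0.3, 5)
      )
    })
  })
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
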