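## shared fixtures; heavy objects are computed lazily and cached for the
## whole test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

cached_cycle <- function(preset = "mcn", ...) {
  cached(paste0("cycle_", preset),
         integrate_to_limit_cycle(mcn_parameters(), preset, ...))
}

random_states <- function(n, seed = 42, mass_range = c(0.3, 2)) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    cdk_state(mpf = runif(1, 0, 0.5), mpf_p = runif(1, 0, 1),
              mpf_rum1 = runif(1, 0, 0.5), rum1 = runif(1, 0, 0.5),
              rum1_p = runif(1, 0, 0.05), wee1 = runif(1),
              cdc25 = runif(1), ie = runif(1), apc_slp1 = runif(1),
              mass = runif(1, mass_range[1], mass_range[2]))
  }))
}
options(testthat.progress.max_fails = Inf)

dwee_diagram <- function() cached("diag_dwee", {
  p <- mcn_parameters()
  d <- trace_branches(c(0.45, 1.1), 0.005, p,
                      genotype_preset("mcn-dwee1dmik1"), n_starts = 4)
  classify_snic(d, envelope = limit_cycle_envelope(
    c(0.45, 1.3), apply_genotype(p, "mcn-dwee1dmik1"), mass_step = 0.01))
})
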