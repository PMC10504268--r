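# shared fixtures for the suite: small, fast parameterizations

# coarse, short wild-type simulation reused by several tests
quick_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_min(min_params(), min_grid(4, dx = 0.1),
                             t_end = 600, seed = 0)
    cache
  }
})

# noiseless generator configuration (the deterministic oracle regime)
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(n_lineages = 1, n_generations = 12, alpha_cv = 0, tau_cv = 0,
         division_fraction_sd = 0, lstable_cv = 0, intensity_noise_sd = 0,
         background_mean = 0, induction_start_gen = 4, seed = 1),
    list(...))
  do.call(lineage_config, args)
}

# independent mass-action right-hand side of the well-mixed 5-species system,
# written directly from the reaction scheme (used as the ODE oracle; kept
# deliberately separate from the package implementation)
oracle_ode_rhs <- function(t, y, p) {
  cDD <- y[1]; cDT <- y[2]; cE <- y[3]; md <- y[4]; mde <- y[5]
  att <- (p$sigma_D + p$sigma_dD * (md + mde)) * cDT
  erec <- p$sigma_E * md * cE
  det <- p$sigma_de * mde
  exch <- p$k_exchange * cDD
  list(c(-exch + det,
         exch - att,
         -erec + det,
         att - erec,
         erec - det))
}
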