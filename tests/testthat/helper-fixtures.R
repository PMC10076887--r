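# shared fixtures and independent oracles used across test files

glyc <- compound_library("glycerol")
bio_gen <- compound_library("biomass_generic")

# independent trapezoid (oracle for integrals; deliberately not the
# package-internal helper)
trapz_oracle <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2)
}

# standard small simulations reused by several files, built once
sim_fb025 <- local({
  sch <- build_schedule("FB-mu", mu_set = 0.025, strain = "GAP-0.025")
  p <- simulation_params(Y_XS = 0.54,
                         product = product_kinetics("growth_coupled",
                                                    alpha = 100.45))
  simulate_cultivation(sch, p, dt_out = 0.25)
})

sim_ps <- local({
  sch <- build_schedule("PS", strain = "PDH-PS")
  p <- simulation_params(Y_XS = 0.58,
                         product = product_kinetics("starvation_induced",
                                                    q_p_max = 12.5,
                                                    q_S_rep = 0.02, tau = 12))
  simulate_cultivation(sch, p, dt_out = 0.25)
})
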