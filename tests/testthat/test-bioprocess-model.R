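test_that("growth-coupled production rate is alpha * mu", {
  expect_equal(qp_growth_coupled(0, 185.22), 0)
  expect_equal(qp_growth_coupled(0.025, 185.22), 4.6305)
  # within the internal consistency of printed feeding-phase KPIs (~3%)
  expect_lt(abs(qp_growth_coupled(0.025, 185.22) - 4.59) / 4.59, 0.03)
  expect_lt(abs(qp_growth_coupled(0.15, 61.28) - 9.44) / 9.44, 0.03)
})

test_that("starvation-induced rate is repressed, peaks at induction, decays as exp(-t/tau)", {
  expect_equal(qp_starvation_induced(0.25, 0, 12.5, 0.02, 12), 0)
  expect_equal(qp_starvation_induced(0.005, 0, 12.5, 0.02, 12), 12.5)
  expect_equal(qp_starvation_induced(0.005, 12, 12.5, 0.02, 12),
               12.5 / exp(1))
  expect_error(qp_starvation_induced(0.005, -1, 12.5, 0.02, 12), ">= 0")
})

test_that("closed system (no feed, no substrate) is stationary", {
  sch <- feed_schedule(list(feed_phase("batch", duration = 10)),
                       V0 = 1, X0 = 5, S0 = 0)
  p <- simulation_params(Y_XS = 0.58, m_S = 0)
  tc <- simulate_cultivation(sch, p, dt_out = 0.5)
  expect_equal(max(abs(tc$X - 5)), 0, tolerance = 1e-8)
  expect_equal(max(abs(tc$V - 1)), 0, tolerance = 1e-12)
  expect_equal(max(tc$P), 0)
})

test_that("FB-mu 0.025 reproduces the set-point growth rate within 2%", {
  pt <- phase_table(sim_fb025)
  est <- estimate_rates(sim_fb025, c(pt$t_start[2], pt$t_end[2]))
  expect_lt(abs(est$mu_real - 0.025) / 0.025, 0.02)
  # feed phase terminates at the DCW target
  expect_equal(sim_fb025$X[nrow(sim_fb025)], 80, tolerance = 1e-3)
})

test_that("carbon is conserved along the whole trajectory within 1%", {
  for (tc in list(sim_fb025, sim_ps)) {
    d <- as.data.frame(tc)
    sch <- attr(tc, "schedule")
    pars <- attr(tc, "params")
    c_in <- (sch$S0 * sch$V0 + d$fed[nrow(d)]) / pars$substrate$cmol_mass
    co2_mol <- trapz_oracle(d$t, d$CER * d$V) / 1000
    dX_cmol <- (d$X[nrow(d)] * d$V[nrow(d)] - sch$X0 * sch$V0) /
      pars$biomass$cmol_mass
    resid_cmol <- d$S[nrow(d)] * d$V[nrow(d)] / pars$substrate$cmol_mass
    expect_lt(abs(dX_cmol + co2_mol + resid_cmol - c_in) / c_in, 0.01)
  }
})

test_that("total biomass grows exponentially at mu_set under exponential feed", {
  d <- as.data.frame(sim_fb025)
  feed <- d[d$phase == 2, ]
  fit <- lm(log(feed$X * feed$V) ~ feed$t)
  expect_lt(abs(coef(fit)[2] - 0.025) / 0.025, 0.02)
  # log-linearity: residuals tiny
  expect_lt(max(abs(resid(fit))), 0.01)
})

test_that("starvation-induced PS run forms essentially all product after induction", {
  d <- as.data.frame(sim_ps)
  pre <- max(which(d$phase < 3))
  frac <- (d$P[pre] * d$V[pre]) / (d$P[nrow(d)] * d$V[nrow(d)])
  expect_lt(frac, 0.05)
  # and the induction transient flattens: late production slower than early
  ind <- d[d$phase == 3, ]
  PV <- ind$P * ind$V
  t3 <- ind$t - ind$t[1]
  early <- (PV[which.min(abs(t3 - 6))] - PV[1]) / 6
  late <- (PV[length(PV)] - PV[which.min(abs(t3 - 30))]) /
    (t3[length(t3)] - 30)
  expect_lt(late, 0.3 * early)
})

test_that("3-PS cycles re-induce production", {
  sch <- build_schedule("3-PS", strain = "PDH-3PS")
  p <- simulation_params(Y_XS = 0.58,
                         product = product_kinetics("starvation_induced",
                                                    q_p_max = 12.5,
                                                    q_S_rep = 0.02, tau = 12))
  tc <- simulate_cultivation(sch, p, dt_out = 0.5)
  d <- as.data.frame(tc)
  # product formed in each induction phase is substantial
  gains <- vapply(c(3, 5, 7), function(i) {
    ph <- d[d$phase == i, ]
    ph$P[nrow(ph)] * ph$V[nrow(ph)] - ph$P[1] * ph$V[1]
  }, numeric(1))
  expect_true(all(gains > 1))     # kAU per cycle
  # later cycles, with more biomass, produce more per cycle
  expect_true(all(diff(gains) > 0))
  # growth phases produce nearly nothing
  for (i in c(2, 4, 6)) {
    ph <- d[d$phase == i, ]
    expect_lt(ph$P[nrow(ph)] * ph$V[nrow(ph)] - ph$P[1] * ph$V[1],
              0.05 * sum(gains))
  }
})

test_that("tightening solver tolerances leaves the final state unchanged within 0.1%", {
  sch <- build_schedule("PS", strain = "conv")
  p <- simulation_params(Y_XS = 0.58,
                         product = product_kinetics("starvation_induced",
                                                    q_p_max = 12.5,
                                                    q_S_rep = 0.02, tau = 12))
  a <- simulate_cultivation(sch, p, dt_out = 0.5)
  b <- simulate_cultivation(sch, p, dt_out = 0.25, rtol = 1e-10, atol = 1e-10)
  fa <- a[nrow(a), c("V", "X", "P")]
  fb <- b[nrow(b), c("V", "X", "P")]
  expect_true(all(abs(unlist(fa) - unlist(fb)) / unlist(fb) < 1e-3))
})

test_that("time courses round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(sim_fb025, path)
  back <- read_timecourse(path)
  expect_equal(back$X, sim_fb025$X, tolerance = 1e-6)
  expect_equal(names(back), names(as.data.frame(sim_fb025)))
})
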