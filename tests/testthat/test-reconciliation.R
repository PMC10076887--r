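test_that("balance matrix carries carbon and degree-of-reduction rows", {
  E <- balance_matrix(glyc, bio_gen)
  expect_equal(unname(E["carbon", ]), c(1, 1, 0, 1))
  expect_equal(unname(E["electron", ]), c(14 / 3, 4.2, -4, 0),
               tolerance = 1e-12)
  expect_equal(qr(E)$rank, 2)
})

test_that("an exactly balanced vector passes untouched with h = 0", {
  nb <- noisy_balanced_rates(0)     # just the truth
  res <- reconcile(nb$truth)
  expect_equal(res$h, 0, tolerance = 1e-20)
  expect_equal(res$x_hat, nb$truth$rates, tolerance = 1e-12)
  expect_true(res$pass)
  expect_equal(unname(res$recovery), c(100, 100), tolerance = 1e-9)
})

test_that("reconciled rates satisfy the balances and the projection is idempotent", {
  set.seed(11)
  nb <- noisy_balanced_rates(20)
  E <- balance_matrix()
  for (rv in nb$replicates[1:20]) {
    res <- reconcile(rv, E)
    expect_lt(max(abs(E %*% res$x_hat)), 1e-10)
    # feeding x_hat back in changes nothing and gives h = 0
    rv2 <- rv; rv2$rates <- res$x_hat
    res2 <- reconcile(rv2, E)
    expect_equal(res2$x_hat, res$x_hat, tolerance = 1e-10)
    expect_lt(res2$h, 1e-15)
  }
})

test_that("reconciliation reduces error against the balanced truth", {
  set.seed(23)
  nb <- noisy_balanced_rates(500)
  E <- balance_matrix()
  sqerr <- vapply(nb$replicates, function(rv) {
    res <- reconcile(rv, E)
    c(raw = sum((rv$rates - nb$truth$rates)^2),
      rec = sum((res$x_hat - nb$truth$rates)^2))
  }, numeric(2))
  expect_lt(mean(sqerr["rec", ]), mean(sqerr["raw", ]))
  # and is unbiased under symmetric noise
  xh <- vapply(nb$replicates, function(rv) reconcile(rv, E)$x_hat,
               numeric(4))
  bias <- abs(rowMeans(xh) - nb$truth$rates) / abs(nb$truth$rates)
  expect_true(all(bias < 0.01))
})

test_that("the 95% consistency test is calibrated on correctly-noised data", {
  set.seed(57)
  nb <- noisy_balanced_rates(2000)
  E <- balance_matrix()
  pass <- vapply(nb$replicates, function(rv) reconcile(rv, E)$pass,
                 logical(1))
  expect_gt(mean(pass), 0.925)
  expect_lt(mean(pass), 0.975)
})

test_that("chi-squared critical value and boundary behaviour", {
  ct <- consistency_test(0, 2)
  expect_true(ct$pass)
  expect_equal(ct$critical, 5.991, tolerance = 1e-3)
  expect_true(consistency_test(5.991, 2)$pass)
  expect_false(consistency_test(6.0, 2)$pass)
  expect_error(consistency_test(1, 0), "positive integer")
})

test_that("gross errors are detected and degrade recovery", {
  set.seed(88)
  nb <- noisy_balanced_rates(1)
  bad <- inject_gross_error(nb$replicates[[1]], "substrate", 1.5)
  expect_false(reconcile(bad)$pass)
  # halving CO2 pulls carbon recovery below 90%
  low_co2 <- inject_gross_error(nb$truth, "co2", 0.5)
  expect_lt(recovery(low_co2)["carbon"], 90)
})

test_that("recovery stays above 90% under routine assay noise", {
  set.seed(99)
  nb <- noisy_balanced_rates(500)
  recs <- t(vapply(nb$replicates, recovery, numeric(2)))
  expect_gte(mean(recs[, "carbon"] > 90 & recs[, "electron"] > 90), 0.99)
})

test_that("mass-basis constructor applies the C-mol conversion and sign convention", {
  g <- gas_rates_from_yields(0.044, 0.58)
  rv <- rate_vector_from_mass(0.044, 0.58 * 0.044, g$q_O2, g$q_CO2)
  expect_lt(rv$rates["substrate"], 0)
  expect_gt(rv$rates["biomass"], 0)
  expect_lt(rv$rates["o2"], 0)
  expect_equal(unname(rv$rates["substrate"]), -0.044 / 30.698,
               tolerance = 1e-4)
  # constructed from a consistent yield: balanced by construction
  expect_lt(max(abs(balance_matrix() %*% rv$rates)), 1e-12)
})
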