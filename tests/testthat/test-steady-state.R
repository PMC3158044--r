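test_that("Hfq-only network reaches the closed-form steady state", {
  net <- hfq_network(1, 1, alpha_H = 2, alpha_S = 0, alpha_T = 0, beta = 1,
                     k1 = 100, k2 = 100)
  ss <- steady_state(net)
  expect_true(ss$converged)
  expect_equal(ss$species$H, 2, tolerance = 1e-9)
  expect_equal(sum(ss$state) - ss$species$H, 0, tolerance = 1e-9)
})

test_that("no annealing path means exactly zero duplex", {
  net <- hfq_network(1, 1, alpha_H = 1, k1 = 10, k2 = 10, k3 = 10, k4 = 10,
                     k5 = 0)
  ss <- steady_state(net)
  expect_true(ss$converged)
  expect_equal(unname(sum(ss$species$D)), 0)
})

test_that("converged solutions have near-zero mass-action residuals", {
  for (seed in 1:5) {
    net <- random_network(2, 2, seed + 100)
    ss <- steady_state(net)
    expect_true(ss$converged)
    expect_lt(ss$residual, 1e-8 * max(ss$state, 1))
  }
})

test_that("steady-state totals obey the production/degradation balance", {
  for (seed in 1:8) {
    net <- random_network(sample(1:3, 1), sample(1:3, 1), seed + 200)
    cc <- conservation_check(steady_state(net))
    expect_lt(max(cc$rel_error), 1e-6)
  }
})

test_that("the balance generalises to per-species degradation overrides", {
  net <- build_scheme("s1_degradation", base = "independent",
                      srna_beta_fold = 10)
  ss <- steady_state(net)
  cc <- conservation_check(ss)
  expect_lt(max(cc$rel_error), 1e-6)
  # uniform-beta shortcut must NOT hold for the sRNA lineage here
  sp <- ss$species
  srna_total <- sp$S + sp$HS + sum(sp$HST) + sum(sp$D)
  expect_gt(abs(net$beta * srna_total - net$alpha_S) / net$alpha_S, 1e-3)
})

test_that("integrator and algebraic root-finder agree on random pairs", {
  for (seed in 1:5) {
    net <- random_network(1, 1, seed + 300)
    ss <- steady_state(net)
    ora <- steady_state_oracle(net)
    expect_true(ora$converged)
    expect_lt(max(abs(ora$state - ss$state)) / max(ss$state), 1e-6)
  }
})

test_that("the oracle satisfies the Hfq conservation identity at its root", {
  net <- random_network(2, 2, 777)
  ora <- steady_state_oracle(net)
  sp <- ora$species
  total_hfq <- sp$H + sum(sp$HS) + sum(sp$HT) + sum(sp$HST)
  expect_equal(net$beta * total_hfq, net$alpha_H, tolerance = 1e-6)
})

test_that("rescaling concentrations leaves fractional outputs unchanged", {
  net <- random_network(1, 1, 31)
  c_fac <- 100
  scaled <- hfq_network(1, 1,
                        alpha_H = net$alpha_H * c_fac,
                        alpha_S = net$alpha_S * c_fac,
                        alpha_T = net$alpha_T * c_fac, beta = net$beta,
                        k1 = net$k1 / c_fac, kneg1 = net$kneg1,
                        k2 = net$k2 / c_fac, kneg2 = net$kneg2,
                        k3 = net$k3 / c_fac, kneg3 = net$kneg3,
                        k4 = net$k4 / c_fac, kneg4 = net$kneg4,
                        k5 = net$k5)
  ss <- steady_state(net)
  ss_scaled <- steady_state(scaled)
  expect_equal(ss_scaled$state / c_fac, ss$state, tolerance = 1e-6)
  expect_equal(percent_duplex(ss_scaled), percent_duplex(ss),
               tolerance = 1e-6)
})

test_that("lengthening the horizon does not move a converged answer", {
  net <- random_network(1, 1, 55)
  a <- steady_state(net, convergence_config(horizon_multiplier = 100))
  b <- steady_state(net, convergence_config(horizon_multiplier = 400))
  expect_lt(max(abs(a$state - b$state)) / max(a$state),
            1e-7)
})

test_that("Newton refinement matches the integrator", {
  net <- build_scheme("independent_with_dissociation", y5 = 1e4, k5 = 1e3)
  ss <- steady_state(net)
  nw <- steady_state(net, method = "newton", init = 0.9 * ss$state)
  expect_true(nw$converged)
  expect_lt(max(abs(nw$state - ss$state)) / max(ss$state), 1e-8)
})
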