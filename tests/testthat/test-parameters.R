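test_that("unit rate constants give unit y-parameters", {
  net <- hfq_network(2, 2, k1 = 1, kneg1 = 1, k2 = 1, kneg2 = 1, k3 = 1,
                     kneg3 = 1, k4 = 1, kneg4 = 1, k5 = diag(2))
  y <- compute_y_metrics(net)
  expect_equal(unlist(y[paste0("y", 1:9)]), setNames(rep(1, 9),
                                                     paste0("y", 1:9)))
})

test_that("y-parameters evaluate their printed definitions", {
  # affinity-asymmetric association regime
  net <- hfq_network(1, 1, k1 = 10^0.5, k2 = 10^4.5, k3 = 10^4.5,
                     k4 = 10^0.5, k5 = 1)
  y <- compute_y_metrics(net)
  expect_equal(y$y1, 1e4, tolerance = 1e-12)
  expect_equal(y$y2, 10^2.5, tolerance = 1e-12)
  expect_equal(y$y3, 1, tolerance = 1e-12)
  expect_equal(y$y4, 1, tolerance = 1e-12)
  # cooperative dissociation regime
  net2 <- hfq_network(1, 1, k1 = 1, k2 = 1, k3 = 1, k4 = 1,
                      kneg1 = 1e6, kneg2 = 1e6, kneg3 = 1e2, kneg4 = 1e2,
                      k5 = 1)
  y2 <- compute_y_metrics(net2)
  expect_equal(y2$y5, 1e4, tolerance = 1e-12)
  expect_equal(y2$y6, 1e4, tolerance = 1e-12)
})

test_that("zero denominators yield undefined (NA) ratios, not errors", {
  net <- hfq_network(1, 1, k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1)  # kneg = 0
  y <- compute_y_metrics(net)
  expect_true(is.na(y$y6))
  expect_true(is.na(y$y7))
  expect_equal(y$y5, 0)
  # 1x1 network has no non-cognate partner
  expect_true(is.na(y$y8) && is.na(y$y9))
})

test_that("association inversion has the unique closed-form solution", {
  expect_equal(unname(association_from_y(1, 7, 1, 1)), rep(7, 4))
  k <- association_from_y(1e4, 10^2.5, 1, 1)
  expect_equal(unname(k), c(10^0.5, 10^4.5, 10^4.5, 10^0.5),
               tolerance = 1e-12)
  k2 <- association_from_y(1, 1, 1e4, 1e4)
  expect_equal(unname(k2), c(1e-4, 1, 1, 1e4), tolerance = 1e-12)
  expect_error(association_from_y(-1, 1, 1, 1), "positive")
})

test_that("association inversion agrees with a log-linear solve", {
  # independent oracle: the four y-definitions are linear in log k
  A <- rbind(c(-1, 1, 1, -1) / 2,
             c(1, 1, 1, 1) / 4,
             c(-1, 1, -1, 1) / 2,
             c(-1, -1, 1, 1) / 2)
  set.seed(99)
  for (rep in 1:20) {
    y <- 10^runif(4, -3, 3)
    k_oracle <- 10^solve(A, log10(y))
    k <- association_from_y(y[1], y[2], y[3], y[4])
    expect_equal(unname(k), unname(k_oracle), tolerance = 1e-9)
  }
})

test_that("dissociation split satisfies its constraints", {
  expect_equal(unname(dissociation_from_y(5, 1)), rep(5, 4))
  expect_equal(unname(dissociation_from_y(0, 1)), rep(0, 4))
  expect_error(dissociation_from_y(0, 2), "inconsistent")
  kn <- dissociation_from_y(1e4, 1e4)
  expect_equal(unname(kn), c(1e6, 1e6, 1e2, 1e2), tolerance = 1e-12)
  # forward formulas recover (y5, y6)
  expect_equal(prod(kn)^0.25, 1e4, tolerance = 1e-12)
  expect_equal(unname(sqrt(kn[1] * kn[2] / (kn[3] * kn[4]))), 1e4,
               tolerance = 1e-12)
})

test_that("preset regimes round-trip their requested y-values", {
  tol <- 1e-12
  y <- compute_y_metrics(build_scheme("independent_no_dissociation",
                                      y1 = 1e4, y2 = 10^2.5))
  expect_equal(y$y1, 1e4, tolerance = tol)
  expect_equal(y$y2, 10^2.5, tolerance = tol)
  expect_equal(y$y3, 1, tolerance = tol)

  y <- compute_y_metrics(build_scheme("cooperative_association", y1 = 1e-2,
                                      y3 = 1e2, y4 = 1e4, y2 = 10^1.5))
  expect_equal(unlist(y[c("y1", "y2", "y3", "y4")]),
               c(y1 = 1e-2, y2 = 10^1.5, y3 = 1e2, y4 = 1e4),
               tolerance = tol)

  y <- compute_y_metrics(build_scheme("independent_with_dissociation",
                                      y2 = 10^2.5, y5 = 1e4))
  expect_equal(unlist(y[c("y2", "y5", "y6")]),
               c(y2 = 10^2.5, y5 = 1e4, y6 = 1),
               tolerance = tol)

  y <- compute_y_metrics(build_scheme("cooperative_dissociation", y4 = 1e4,
                                      y5 = 1e4, y6 = 1e4))
  expect_equal(unlist(y[c("y4", "y5", "y6")]),
               c(y4 = 1e4, y5 = 1e4, y6 = 1e4), tolerance = tol)

  y <- compute_y_metrics(build_scheme("network_uniform", n = 3, y7 = 0.1,
                                      y8 = 10, y9 = 1))
  expect_equal(y$y7, 0.1, tolerance = tol)
  expect_equal(y$y8, 10, tolerance = tol)
  # dissociation-route selection realises the same ratio
  y <- compute_y_metrics(build_scheme("network_uniform", n = 3, y7 = 0.1,
                                      y7_route = "dissociation"))
  expect_equal(y$y7, 0.1, tolerance = tol)

  y <- compute_y_metrics(build_scheme("unstable_pairs", n = 2))
  expect_equal(y$y9, 1e4, tolerance = tol)
  expect_equal(y$k5_cognate, 1e3)
  expect_equal(y$k5_noncognate, 0)

  y <- compute_y_metrics(build_scheme("indiscriminate", n = 3, k5 = 1e3))
  expect_equal(y$k5_noncognate, 1e3)

  y <- compute_y_metrics(build_scheme("unpartnered_pool",
                                      variant = "exclusion"))
  expect_equal(y$y8, 10, tolerance = tol)
  expect_equal(y$y9, 10, tolerance = tol)
})

test_that("positive cooperative association means faster second binding", {
  net <- build_scheme("cooperative_association", y4 = 1e2)
  expect_true(net$k3[1, 1] > net$k2[1] || net$k4[1, 1] > net$k1[1])
})

test_that("scheme builders reject inconsistent requests", {
  expect_error(build_scheme("nonsense"), "unknown regime")
  expect_error(build_scheme("cooperative_dissociation", y5 = 0, y6 = 10),
               "inconsistent")
  expect_error(build_scheme("network_uniform", y9 = 0, y8 = 10), "y9 > 0")
  expect_silent(build_scheme("network_uniform", n = 2, y9 = 0, y7 = 0.1))
})

test_that("production imbalances keep combined production constant", {
  for (r in c(5, 1, 1 / 5)) {
    net <- build_scheme("imbalanced_pair", ratio = r)
    expect_equal(net$alpha_S + net$alpha_T, 2, tolerance = 1e-12)
    expect_equal(net$alpha_S / net$alpha_T, r, tolerance = 1e-12)
  }
})

test_that("the unpartnered pool produces 100x the cognate mRNA", {
  net <- build_scheme("unpartnered_pool")
  expect_identical(c(net$n_srna, net$m_mrna), c(1L, 2L))
  expect_equal(net$alpha_T[2] / net$alpha_T[1], 100)
  expect_equal(net$k5[1, 2], 0)
  # affinity tilt hits both cognate and pool mRNA constants, geometric
  # mean of the six association constants unchanged
  tilted <- build_scheme("unpartnered_pool", affinity_ratio = 1e-2)
  ratio <- ((tilted$k2[1] * tilted$k3[1, 1] * tilted$k3[1, 2]) /
              (tilted$k1[1] * tilted$k4[1, 1] * tilted$k4[1, 2]))^(1 / 3)
  expect_equal(ratio, 1e-2, tolerance = 1e-12)
  # geometric mean over the six tilted constants (k1, k2, k3, k3*, k4, k4*)
  gm <- function(n) prod(n$k1, n$k2[1], n$k3[1, ], n$k4[1, ])^(1 / 6)
  expect_equal(gm(tilted), gm(build_scheme("unpartnered_pool")),
               tolerance = 1e-12)
})

test_that("stability mixes give each RNA its class dissociation rate", {
  net <- stability_mix(2, 1, y9_stable = 1, y9_unstable = 1e4)
  expect_equal(net$kneg1, c(1, 1, 1e4))
  expect_equal(net$kneg4[3, 1], 1e4)  # sRNA 3 leaving any ternary
  expect_equal(net$kneg3[1, 3], 1e4)  # mRNA 3 leaving any ternary
  expect_equal(net$kneg3[3, 1], 1)    # mRNA 1 leaving sRNA-3 ternary
  expect_equal(diag(net$k5), rep(1e3, 3))
  expect_equal(sum(net$k5 > 0), 3)
})
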