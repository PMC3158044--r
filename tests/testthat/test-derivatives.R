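test_that("derivative at the origin is the production vector", {
  net <- hfq_network(2, 2, alpha_H = 1, alpha_S = c(1, 2), alpha_T = 1,
                     k1 = 5, k2 = 5, k3 = 5, k4 = 5, k5 = 10)
  d <- unpack_state(net, derivatives(net, pack_state(net)))
  expect_equal(d$H, 1)
  expect_equal(d$S, c(1, 2))
  expect_equal(d$T, c(1, 1))
  expect_equal(d$HS, c(0, 0))
  expect_true(all(d$HST == 0) && all(d$D == 0))
})

test_that("Hfq balance point is stationary when no RNAs are produced", {
  net <- hfq_network(1, 2, alpha_H = 3, alpha_S = 0, alpha_T = 0, beta = 1.5,
                     k1 = 10, k2 = 10)
  d <- derivatives(net, pack_state(net, H = net$alpha_H / net$beta))
  expect_equal(max(abs(d)), 0)
})

test_that("binding and annealing terms cancel within each conservation lineage", {
  for (seed in 1:10) {
    net <- random_network(sample(1:3, 1), sample(1:3, 1), seed)
    x <- pack_state(net,
                    H = runif(1, 0, 5),
                    S = runif(net$n_srna, 0, 5), T = runif(net$m_mrna, 0, 5),
                    HS = runif(net$n_srna, 0, 5), HT = runif(net$m_mrna, 0, 5),
                    HST = matrix(runif(net$n_srna * net$m_mrna, 0, 5),
                                 net$n_srna),
                    D = matrix(runif(net$n_srna * net$m_mrna, 0, 5),
                               net$n_srna))
    d <- unpack_state(net, derivatives(net, x))
    s <- unpack_state(net, x)
    b <- net$beta
    hfq <- d$H + sum(d$HS) + sum(d$HT) + sum(d$HST)
    expect_equal(hfq, net$alpha_H -
                   b * (s$H + sum(s$HS) + sum(s$HT) + sum(s$HST)),
                 tolerance = 1e-8)
    for (i in seq_len(net$n_srna)) {
      lin <- d$S[i] + d$HS[i] + sum(d$HST[i, ]) + sum(d$D[i, ])
      expect_equal(lin, net$alpha_S[i] -
                     b * (s$S[i] + s$HS[i] + sum(s$HST[i, ]) + sum(s$D[i, ])),
                   tolerance = 1e-8)
    }
    for (j in seq_len(net$m_mrna)) {
      lin <- d$T[j] + d$HT[j] + sum(d$HST[, j]) + sum(d$D[, j])
      expect_equal(lin, net$alpha_T[j] -
                     b * (s$T[j] + s$HT[j] + sum(s$HST[, j]) + sum(s$D[, j])),
                   tolerance = 1e-8)
    }
  }
})

test_that("derivative is linear in production rates at a fixed state", {
  net <- random_network(2, 2, 42)
  x <- abs(pack_state(net, H = 1, S = 1, T = 1, HS = 0.5, HT = 0.5,
                      HST = 0.2, D = 0.1))
  bump <- function(net, dH, dS, dT) {
    net$alpha_H <- net$alpha_H + dH
    net$alpha_S <- net$alpha_S + dS
    net$alpha_T <- net$alpha_T + dT
    net
  }
  d0 <- derivatives(net, x)
  d1 <- derivatives(bump(net, 2, 3, 4), x)
  expected <- d0 + pack_state(net, H = 2, S = 3, T = 4)
  expect_equal(d1, expected, tolerance = 1e-12)
})

test_that("swapping sRNA and mRNA roles transposes the derivative", {
  net <- random_network(2, 3, 7)
  swapped <- hfq_network(net$m_mrna, net$n_srna,
                         alpha_H = net$alpha_H, alpha_S = net$alpha_T,
                         alpha_T = net$alpha_S, beta = net$beta,
                         k1 = net$k2, kneg1 = net$kneg2,
                         k2 = net$k1, kneg2 = net$kneg1,
                         k3 = t(net$k4), kneg3 = t(net$kneg4),
                         k4 = t(net$k3), kneg4 = t(net$kneg3),
                         k5 = t(net$k5))
  set.seed(11)
  sp <- list(H = runif(1), S = runif(2), T = runif(3),
             HS = runif(2), HT = runif(3),
             HST = matrix(runif(6), 2, 3), D = matrix(runif(6), 2, 3))
  d <- unpack_state(net, derivatives(net, do.call(pack_state, c(list(net), sp))))
  sw_state <- pack_state(swapped, H = sp$H, S = sp$T, T = sp$S,
                         HS = sp$HT, HT = sp$HS,
                         HST = t(sp$HST), D = t(sp$D))
  dsw <- unpack_state(swapped, derivatives(swapped, sw_state))
  expect_equal(dsw$H, d$H, tolerance = 1e-12)
  expect_equal(dsw$S, d$T, tolerance = 1e-12)
  expect_equal(dsw$HS, d$HT, tolerance = 1e-12)
  expect_equal(dsw$HST, t(d$HST), tolerance = 1e-12)
  expect_equal(dsw$D, t(d$D), tolerance = 1e-12)
})

test_that("analytic jacobian matches finite differences", {
  for (seed in c(3, 8)) {
    net <- random_network(2, 2, seed)
    x <- abs(pack_state(net, H = 0.7, S = c(0.3, 1.1), T = c(0.9, 0.2),
                        HS = 0.4, HT = 0.6, HST = 0.15, D = 0.05))
    J <- jacobian(net, x)
    d0 <- derivatives(net, x)
    h <- 1e-7
    for (k in seq_along(x)) {
      e <- x; e[k] <- e[k] + h
      expect_equal(J[, k], unname((derivatives(net, e) - d0) / h),
                   tolerance = 1e-4)
    }
  }
})

test_that("per-species degradation overrides enter every matching term", {
  net <- hfq_network(1, 1, alpha_S = 2, k1 = 3,
                     beta_overrides = list(S = 10))
  x <- pack_state(net, H = 1, S = 1, T = 1, HS = 1, HT = 1, HST = 1, D = 1)
  d <- unpack_state(net, derivatives(net, x))
  # dS = alpha_S + kneg1*HS - k1*S*H - 10*S
  expect_equal(d$S, 2 + 0 - 3 - 10)
  # all other species keep the global beta
  expect_equal(d$D, matrix(-1, 1, 1))
})
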