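test_that("a template without annealing never forms duplex on any grid", {
  net <- hfq_network(1, 1, k1 = 100, k2 = 100, k3 = 100, k4 = 100, k5 = 0)
  sw <- hfq_sweep(net, alpha_H_grid(1e-3, 1e3, 2))
  expect_true(all(sw$converged))
  expect_equal(max(sw$percent_duplex), 0)
})

test_that("a single-point grid reproduces a direct solve", {
  net <- build_scheme("independent_with_dissociation", y5 = 10, k5 = 100)
  sw <- hfq_sweep(net, grid = 1)
  ss <- steady_state(set_alpha_H(net, 1))
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$percent_duplex, percent_duplex(ss), tolerance = 1e-8)
  expect_equal(sw$relative_hfq, relative_hfq(ss), tolerance = 1e-8)
})

test_that("sweep rows agree with the independent root-finding oracle", {
  net <- build_scheme("independent_no_dissociation", y2 = 10^2.5, k5 = 1e3)
  grid <- c(1e-2, 1, 1e2)
  sw <- hfq_sweep(net, grid)
  for (k in seq_along(grid)) {
    ora <- steady_state_oracle(set_alpha_H(net, grid[k]))
    expect_equal(sw$percent_duplex[k], percent_duplex(ora),
                 tolerance = 1e-6)
  }
  # the titration is single-peaked: rises to a maximum, then falls
  full <- sweep_cache("fig2_center_sweep",
                      hfq_sweep(net, alpha_H_grid(1e-5, 1e7, 5)))
  pd <- full$percent_duplex
  peak <- which.max(pd)
  expect_true(all(diff(pd[1:peak]) >= -1e-9))
  expect_true(all(diff(pd[peak:length(pd)]) <= 1e-9))
})

test_that("sweeps demand increasing grids and record solver provenance", {
  net <- build_scheme("independent_no_dissociation")
  expect_error(hfq_sweep(net, c(1, 1)), "strictly increasing")
  sw <- hfq_sweep(net, c(0.1, 1), method = "integrate")
  expect_true(all(sw$solver == "integrate"))
})

test_that("allocation fractions stay a partition across a sweep", {
  net <- build_scheme("network_uniform", n = 2)
  sw <- hfq_sweep(net, alpha_H_grid(1e-3, 1e3, 2))
  sums <- sw$free + sw$srna_bound + sw$mrna_bound + sw$cognate_ternary +
    sw$noncognate_ternary
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(sw$percent_duplex >= 0 & sw$percent_duplex <= 100))
})

synthetic_sweep <- function(x, y) {
  tibble::tibble(pair_i = 1L, pair_j = 1L, relative_hfq = x,
                 percent_duplex = y)
}

test_that("bounds are read off by log-linear interpolation", {
  # tent in log10(relative Hfq) crossing 10% exactly at 1e-1 and 1e3
  x <- 10^seq(-3, 5, by = 0.5)
  apex <- 1e1  # peak at log10 = 1
  y <- pmax(0, 30 - 10 * abs(log10(x) - log10(apex)))
  # tent height: 10% at log10 = -1 and 3
  rb <- bounds_and_robustness(synthetic_sweep(x, y))
  expect_true(rb$defined)
  expect_equal(rb$lower_bound, 1e-1, tolerance = 1e-9)
  expect_equal(rb$upper_bound, 1e3, tolerance = 1e-9)
  expect_equal(rb$robustness, 4, tolerance = 1e-9)
  expect_equal(rb$max_percent_duplex, 30)
})

test_that("curves that never reach threshold report undefined bounds", {
  rb <- bounds_and_robustness(synthetic_sweep(10^seq(-2, 2), rep(5, 5)))
  expect_false(rb$defined)
  expect_true(is.na(rb$lower_bound) && is.na(rb$upper_bound))
  expect_equal(rb$robustness, 0)
})

test_that("a peak exactly at threshold collapses the bounds", {
  x <- 10^seq(-2, 2)
  y <- c(0, 5, 10, 5, 0)
  rb <- bounds_and_robustness(synthetic_sweep(x, y))
  expect_true(rb$defined)
  expect_equal(rb$lower_bound, rb$upper_bound)
  expect_equal(rb$robustness, 0)
})

test_that("threshold crossings at the grid edge warn", {
  x <- 10^seq(-2, 2)
  expect_warning(bounds_and_robustness(synthetic_sweep(x, c(50, 50, 50, 8, 0))),
                 "lower grid edge")
  expect_warning(bounds_and_robustness(synthetic_sweep(x, c(0, 8, 50, 50, 50))),
                 "upper grid edge")
})
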