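# Random network generator used by the property-style tests.  Rate
# magnitudes are kept moderate (1e-1 .. 1e3) so the stiff solves stay fast;
# the preset regimes cover the extreme magnitudes.
random_network <- function(n, m, seed) {
  set.seed(seed)
  lu <- function(len, lo = -1, hi = 3) 10^runif(len, lo, hi)
  k5 <- matrix(0, n, m)
  diag_len <- min(n, m)
  k5[cbind(seq_len(diag_len), seq_len(diag_len))] <- lu(diag_len, 0, 3)
  hfq_network(n, m,
              alpha_H = lu(1, -1, 1), alpha_S = lu(n, -1, 1),
              alpha_T = lu(m, -1, 1), beta = 1,
              k1 = lu(n), kneg1 = lu(n), k2 = lu(m), kneg2 = lu(m),
              k3 = matrix(lu(n * m), n, m), kneg3 = matrix(lu(n * m), n, m),
              k4 = matrix(lu(n * m), n, m), kneg4 = matrix(lu(n * m), n, m),
              k5 = k5)
}

# Fabricate a steady-state object from explicit species blocks, for metric
# unit tests that need exact mass placements.
manual_state <- function(net, ...) {
  x <- pack_state(net, ...)
  structure(list(network = net, state = x,
                 species = unpack_state(net, x),
                 converged = TRUE, method = "manual",
                 horizon = NA_real_, iterations = NA_integer_,
                 residual = NA_real_, message = NULL),
            class = "hfq_steady_state")
}

# Shared cache so expensive sweeps computed in one test file are reused by
# later ones within the same run.
sweep_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, envir = env, inherits = FALSE))
      assign(key, force(expr), envir = env)
    get(key, envir = env)
  }
})
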