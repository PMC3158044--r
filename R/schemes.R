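#' Construct a network for a named kinetic regime
#'
#' Builds a fully populated [hfq_network()] whose elementary rate constants
#' realise a requested combination of composite y-parameters.  The regimes
#' cover every kinetic class explored by the model: independent binding with
#' and without RNA dissociation, cooperative association and dissociation,
#' uniform single-partner networks with optional cognate selection (`y7`)
#' and non-cognate exclusion (`y8`), stability mixes, indiscriminate
#' pairing, production imbalances, an unpartnered-mRNA pool, and a variant
#' with accelerated free-sRNA degradation.
#'
#' Regimes and their main parameters (all overridable; `...` also accepts
#' `alpha_H`, `alpha_S`, `alpha_T`, `beta`):
#'
#' * `independent_no_dissociation`: single pair, `k1 = k4`, `k2 = k3`, no
#'   dissociation; parameters `y1`, `y2`, `k5`.
#' * `cooperative_association`: single pair, association from
#'   (`y1`,`y2`,`y3`,`y4`), no dissociation.
#' * `independent_with_dissociation`: single pair, all four association
#'   constants equal to `y2` and all four dissociation constants equal to
#'   `y5`.
#' * `cooperative_dissociation`: association from (`y1`..`y4`), dissociation
#'   from (`y5`,`y6`) by the symmetric split of [dissociation_from_y()].
#' * `network_uniform`: `n` identical single-partner pairs, independent
#'   binding (`y2`) and uniform dissociation (`y9`); optional `y7`/`y8`
#'   apply cognate selection / non-cognate exclusion (see below).
#' * `cognate_selection`, `noncognate_exclusion`: shorthands for
#'   `network_uniform` with `y7 = 0.1` resp. `y8 = 10`.
#' * `stable_pairs`, `unstable_pairs`: `network_uniform` with `y9 = 1`
#'   resp. `y9 = 1e4`; [stability_mix()] builds heterogeneous networks.
#' * `indiscriminate`: every (sRNA, mRNA) combination anneals (`k5` filled,
#'   not diagonal).
#' * `imbalanced_pair`: single pair with sRNA:mRNA production ratio `ratio`
#'   at constant combined production, branch bias through `y3`.
#' * `two_pair_overproduction`: two single-partner pairs with sRNA 1
#'   production multiplied by `srna1_fold`.
#' * `unpartnered_pool`: one sRNA, its cognate mRNA, and an aggregate
#'   unpartnered mRNA produced at `pool_fold` times the cognate rate;
#'   `variant` selects the control, increased-dissociation or
#'   non-cognate-exclusion kinetics and `affinity_ratio` tilts the
#'   mRNA-vs-sRNA affinity for Hfq.
#' * `s1_degradation`: single pair (`base` one of `"independent"`,
#'   `"cooperative_association"`, `"rapid_dissociation"`) with free-sRNA
#'   degradation scaled by `srna_beta_fold`.
#'
#' Cognate selection and non-cognate exclusion can each be realised through
#' either the association constants or the dissociation constants
#' (`y7_route`, `y8_route`).  Selection defaults to the association route
#' (diagonal `k3`/`k4` scaled by `y7^-2`): when annealing is fast the
#' cognate ternary complex empties through `k5` regardless of its
#' dissociation constants, so only faster cognate association changes the
#' steady state.  Exclusion defaults to the dissociation route
#' (off-diagonal `kneg3`/`kneg4` scaled by `y8^2`), i.e. RNAs in
#' non-cognate ternary complexes destabilise one another.  Either route
#' realises the requested ratio exactly.
#'
#' @param regime Regime name (see above).
#' @param ... Regime parameters; unknown names are rejected.
#' @return An [hfq_network()] whose [compute_y_metrics()] reproduce the
#'   requested y-values on the focal pair.
#' @examples
#' build_scheme("network_uniform", n = 5, y7 = 0.1, y8 = 10)
#' @export
build_scheme <- function(regime, ...) {
  regimes <- list(
    independent_no_dissociation = scheme_independent_no_dissociation,
    cooperative_association = scheme_cooperative_association,
    independent_with_dissociation = scheme_independent_with_dissociation,
    cooperative_dissociation = scheme_cooperative_dissociation,
    cognate_selection = function(...) scheme_network(y7 = 0.1, ...),
    noncognate_exclusion = function(...) scheme_network(y8 = 10, ...),
    network_uniform = scheme_network,
    stable_pairs = function(...) scheme_network(y9 = 1e0, ...),
    unstable_pairs = function(...) scheme_network(y9 = 1e4, ...),
    indiscriminate = scheme_indiscriminate,
    imbalanced_pair = scheme_imbalanced_pair,
    two_pair_overproduction = scheme_two_pair,
    unpartnered_pool = scheme_unpartnered_pool,
    s1_degradation = scheme_s1
  )
  f <- regimes[[regime]]
  if (is.null(f))
    stop(sprintf("unknown regime '%s'; expected one of: %s", regime,
                 paste(names(regimes), collapse = ", ")), call. = FALSE)
  f(...)
}

scheme_independent_no_dissociation <- function(y1 = 1, y2 = 10^2.5,
                                               k5 = 1e3, alpha_H = 1,
                                               alpha_S = 1, alpha_T = 1,
                                               beta = 1) {
  # independent binding pins k1 = k4 and k2 = k3, so y3 = y4 = 1
  k14 <- y2 / sqrt(y1)
  k23 <- y2 * sqrt(y1)
  hfq_network(1, 1, alpha_H = alpha_H, alpha_S = alpha_S, alpha_T = alpha_T,
              beta = beta, k1 = k14, k2 = k23, k3 = k23, k4 = k14, k5 = k5)
}

scheme_cooperative_association <- function(y1 = 1, y2 = 10^2.5, y3 = 1,
                                           y4 = 1, k5 = 1e3, alpha_H = 1,
                                           alpha_S = 1, alpha_T = 1,
                                           beta = 1) {
  k <- association_from_y(y1, y2, y3, y4)
  hfq_network(1, 1, alpha_H = alpha_H, alpha_S = alpha_S, alpha_T = alpha_T,
              beta = beta, k1 = k[["k1"]], k2 = k[["k2"]], k3 = k[["k3"]],
              k4 = k[["k4"]], k5 = k5)
}

scheme_independent_with_dissociation <- function(y2 = 10^2.5, y5 = 1e4,
                                                 k5 = 1e3, alpha_H = 1,
                                                 alpha_S = 1, alpha_T = 1,
                                                 beta = 1) {
  hfq_network(1, 1, alpha_H = alpha_H, alpha_S = alpha_S, alpha_T = alpha_T,
              beta = beta, k1 = y2, k2 = y2, k3 = y2, k4 = y2,
              kneg1 = y5, kneg2 = y5, kneg3 = y5, kneg4 = y5, k5 = k5)
}

scheme_cooperative_dissociation <- function(y1 = 1, y2 = 10^2.5, y3 = 1,
                                            y4 = 1, y5 = 1e4, y6 = 1,
                                            k5 = 1e3, alpha_H = 1,
                                            alpha_S = 1, alpha_T = 1,
                                            beta = 1) {
  k <- association_from_y(y1, y2, y3, y4)
  kn <- dissociation_from_y(y5, y6)
  hfq_network(1, 1, alpha_H = alpha_H, alpha_S = alpha_S, alpha_T = alpha_T,
              beta = beta,
              k1 = k[["k1"]], k2 = k[["k2"]], k3 = k[["k3"]], k4 = k[["k4"]],
              kneg1 = kn[["kneg1"]], kneg2 = kn[["kneg2"]],
              kneg3 = kn[["kneg3"]], kneg4 = kn[["kneg4"]], k5 = k5)
}

scheme_network <- function(n = 5, y2 = 10^2.5, y9 = 1e0, y7 = 1, y8 = 1,
                           k5 = 1e3, k5_noncognate = 0,
                           y7_route = c("association", "dissociation"),
                           y8_route = c("dissociation", "association"),
                           alpha_H = 1, alpha_S = 1, alpha_T = 1, beta = 1) {
  y7_route <- match.arg(y7_route)
  y8_route <- match.arg(y8_route)
  if (y9 <= 0 && ((y7 != 1 && y7_route == "dissociation") ||
                  (y8 != 1 && y8_route == "dissociation")))
    stop("cognate selection / exclusion via the dissociation route needs y9 > 0",
         call. = FALSE)
  k3 <- matrix(y2, n, n); k4 <- matrix(y2, n, n)
  kneg3 <- matrix(y9, n, n); kneg4 <- matrix(y9, n, n)
  d <- diag(n) == 1
  if (y7_route == "dissociation") {
    kneg3[d] <- kneg3[d] * y7^2; kneg4[d] <- kneg4[d] * y7^2
  } else {
    k3[d] <- k3[d] / y7^2; k4[d] <- k4[d] / y7^2
  }
  if (y8_route == "dissociation") {
    kneg3[!d] <- kneg3[!d] * y8^2; kneg4[!d] <- kneg4[!d] * y8^2
  } else {
    k3[!d] <- k3[!d] / y8^2; k4[!d] <- k4[!d] / y8^2
  }
  k5m <- matrix(k5_noncognate, n, n); k5m[d] <- k5
  hfq_network(n, n, alpha_H = alpha_H, alpha_S = alpha_S, alpha_T = alpha_T,
              beta = beta, k1 = y2, kneg1 = y9, k2 = y2, kneg2 = y9,
              k3 = k3, kneg3 = kneg3, k4 = k4, kneg4 = kneg4, k5 = k5m)
}

scheme_indiscriminate <- function(n = 5, y2 = 10^2.5, y9 = 1e0, k5 = 1e3,
                                  alpha_H = 1, alpha_S = 1, alpha_T = 1,
                                  beta = 1) {
  scheme_network(n = n, y2 = y2, y9 = y9, k5 = k5, k5_noncognate = k5,
                 alpha_H = alpha_H, alpha_S = alpha_S, alpha_T = alpha_T,
                 beta = beta)
}

#' Network mixing stable and unstable cognate pairs
#'
#' Builds a single-partner network whose first `n_stable` pairs bind Hfq
#' stably (slow dissociation, `y9_stable`) and whose remaining `n_unstable`
#' pairs bind unstably (fast dissociation, `y9_unstable`).  Each RNA carries
#' its own dissociation rate: `kneg1`/`kneg4` rows follow the sRNA's class
#' and `kneg2`/`kneg3` columns the mRNA's class.
#'
#' @param n_stable,n_unstable Pair counts per class (`n_stable + n_unstable
#'   >= 1`).
#' @param y9_stable,y9_unstable Dissociation rates for the two classes
#'   (1/time).
#' @param y2 Association magnitude; `k5` cognate annealing rate.
#' @param alpha_H,alpha_S,alpha_T,beta Production/degradation rates.
#' @return An [hfq_network()] with `n_stable + n_unstable` pairs; stable
#'   pairs come first.
#' @export
stability_mix <- function(n_stable, n_unstable, y9_stable = 1e0,
                          y9_unstable = 1e4, y2 = 10^2.5, k5 = 1e3,
                          alpha_H = 1, alpha_S = 1, alpha_T = 1, beta = 1) {
  n <- n_stable + n_unstable
  if (n < 1L) stop("need at least one pair", call. = FALSE)
  cls <- c(rep(y9_stable, n_stable), rep(y9_unstable, n_unstable))
  k5m <- diag(rep(k5, n), n, n)
  hfq_network(n, n, alpha_H = alpha_H, alpha_S = alpha_S, alpha_T = alpha_T,
              beta = beta,
              k1 = y2, kneg1 = cls, k2 = y2, kneg2 = cls,
              k3 = y2, kneg3 = matrix(cls, n, n, byrow = TRUE),
              k4 = y2, kneg4 = matrix(cls, n, n, byrow = FALSE),
              k5 = k5m)
}

scheme_imbalanced_pair <- function(ratio = 1, y1 = 1, y2 = 10^2.5, y3 = 1,
                                   y4 = 1, k5 = 1e3, total_production = 2,
                                   alpha_H = 1, beta = 1) {
  # sRNA:mRNA production ratio at fixed combined production
  if (ratio <= 0) stop("`ratio` must be > 0", call. = FALSE)
  k <- association_from_y(y1, y2, y3, y4)
  hfq_network(1, 1, alpha_H = alpha_H,
              alpha_S = total_production * ratio / (1 + ratio),
              alpha_T = total_production / (1 + ratio),
              beta = beta, k1 = k[["k1"]], k2 = k[["k2"]], k3 = k[["k3"]],
              k4 = k[["k4"]], k5 = k5)
}

scheme_two_pair <- function(srna1_fold = 1, y2 = 10^2.5, y9 = 1e0, k5 = 1e3,
                            alpha_H = 1, beta = 1) {
  scheme_network(n = 2, y2 = y2, y9 = y9, k5 = k5,
                 alpha_S = c(srna1_fold, 1), alpha_T = 1,
                 alpha_H = alpha_H, beta = beta)
}

scheme_unpartnered_pool <- function(pool_fold = 100,
                                    variant = c("control", "dissociation",
                                                "exclusion"),
                                    affinity_ratio = 1, y2 = 10^2.5,
                                    k5 = 1e3, alpha_H = 1, beta = 1,
                                    with_pool = TRUE) {
  variant <- match.arg(variant)
  kn <- switch(variant,
    control = c(base = 1e0, starred = 1e0),          # y9 = 1,  y8 = 1
    dissociation = c(base = 1e4, starred = 1e4),     # y9 = 1e4, y8 = 1
    # exclusion: y8 = 10 with total dissociation y9 = 10, achieved by
    # kneg_base = y9 * y8^(-2/3), kneg_starred = y9 * y8^(4/3)
    exclusion = c(base = 10 * 10^(-2 / 3), starred = 10 * 10^(4 / 3))
  )
  # affinity tilt: ((k2*k3*k3s)/(k1*k4*k4s))^(1/3) = affinity_ratio at
  # fixed geometric mean -> sRNA-side constants / sqrt(ratio), mRNA-side
  # constants * sqrt(ratio)
  a <- 1 / sqrt(affinity_ratio)  # k1, k4, k4s
  b <- sqrt(affinity_ratio)      # k2, k3, k3s
  if (!with_pool) {
    return(hfq_network(1, 1, alpha_H = alpha_H, beta = beta,
                       k1 = y2 * a, kneg1 = kn[["base"]],
                       k2 = y2 * b, kneg2 = kn[["base"]],
                       k3 = y2 * b, kneg3 = kn[["base"]],
                       k4 = y2 * a, kneg4 = kn[["base"]], k5 = k5))
  }
  # column 1 = cognate mRNA, column 2 = aggregate unpartnered pool
  hfq_network(1, 2, alpha_H = alpha_H, alpha_S = 1,
              alpha_T = c(1, pool_fold), beta = beta,
              k1 = y2 * a, kneg1 = kn[["base"]],
              k2 = y2 * b, kneg2 = kn[["base"]],
              k3 = matrix(y2 * b, 1, 2),
              kneg3 = matrix(c(kn[["base"]], kn[["starred"]]), 1, 2),
              k4 = matrix(y2 * a, 1, 2),
              kneg4 = matrix(c(kn[["base"]], kn[["starred"]]), 1, 2),
              k5 = matrix(c(k5, 0), 1, 2))
}

scheme_s1 <- function(base = c("independent", "cooperative_association",
                               "rapid_dissociation"),
                      srna_beta_fold = 10, y2 = 10^2.5, k5 = 1e3,
                      alpha_H = 1, beta = 1) {
  base <- match.arg(base)
  net <- switch(base,
    independent = scheme_independent_no_dissociation(y2 = y2, k5 = k5,
                                                     alpha_H = alpha_H,
                                                     beta = beta),
    cooperative_association = scheme_cooperative_association(
      y4 = 1e4, y2 = y2, k5 = k5, alpha_H = alpha_H, beta = beta),
    rapid_dissociation = scheme_independent_with_dissociation(
      y2 = y2, y5 = 1e4, k5 = k5, alpha_H = alpha_H, beta = beta)
  )
  if (srna_beta_fold != 1)
    net$beta_overrides <- list(S = srna_beta_fold * beta)
  validate_hfq_network(net)
}

#' Change the Hfq production rate of a network
#'
#' Convenience used by sweeps: returns a copy of `net` with `alpha_H`
#' replaced.
#'
#' @param net An [hfq_network()].
#' @param alpha_H New Hfq production rate.
#' @return The modified network.
#' @export
set_alpha_H <- function(net, alpha_H) {
  stopifnot(inherits(net, "hfq_network"))
  net$alpha_H <- as.numeric(alpha_H)
  validate_hfq_network(net)
}
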