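#' Composite kinetic parameters for an Hfq reaction scheme
#'
#' The elementary rate constants of a single sRNA-target mRNA pair are
#' summarised by nine composite parameters that each isolate one kinetic
#' property of the scheme:
#'
#' * `y1 = sqrt((k2*k3)/(k1*k4))` — relative affinity of mRNAs vs sRNAs for
#'   Hfq (unitless).
#' * `y2 = (k1*k2*k3*k4)^(1/4)` — overall magnitude of the association rate
#'   constants (1/(concentration*time)).
#' * `y3 = sqrt((k2*k4)/(k1*k3))` — branch bias: `y3 < 1` favours the
#'   sRNA-Hfq branch, `y3 > 1` the mRNA-Hfq branch.
#' * `y4 = sqrt((k3*k4)/(k1*k2))` — cooperative association: `y4 > 1` means
#'   an RNA binds faster once its partner is already on Hfq.
#' * `y5 = (kneg1*kneg2*kneg3*kneg4)^(1/4)` — overall magnitude of RNA
#'   dissociation from Hfq complexes (1/time).
#' * `y6 = sqrt((kneg1*kneg2)/(kneg3*kneg4))` — cooperative dissociation:
#'   `y6 > 1` means RNAs leave singly-bound complexes faster than ternary
#'   complexes.
#' * `y7 = ((k1*k2*kneg3*kneg4)/(kneg1*kneg2*k3*k4))^(1/4)` — affinity for
#'   the cognate ternary complex relative to singly-bound complexes;
#'   `y7 < 1` is cognate selection.
#' * `y8` — the same ratio evaluated with the non-cognate (starred)
#'   constants `k3*`, `k4*`, `kneg3*`, `kneg4*`; `y8 > 1` is non-cognate
#'   exclusion.
#' * `y9 = (kneg1*kneg2*kneg3*kneg3s*kneg4*kneg4s)^(1/6)` — total magnitude
#'   of RNA dissociation including the non-cognate routes (1/time).
#'
#' `compute_y_metrics()` evaluates all nine (plus the cognate and
#' non-cognate `k5`) on a focal cognate pair of a network; the starred
#' constants are read from a designated non-cognate partner column.  Ratios
#' whose denominator is zero are reported as `NA` (undefined), not an error.
#'
#' @param net An [hfq_network()].
#' @param focal_pair Integer pair `c(i, j)` naming the cognate pair whose
#'   constants are read (default `c(1, 1)`).
#' @param noncognate_partner mRNA index supplying the starred constants
#'   (default: the first column different from `focal_pair[2]`, or `NA` for
#'   a 1x1 network, in which case `y8`/`y9` are `NA`).
#' @return A one-row tibble with columns `y1` .. `y9`, `k5_cognate`,
#'   `k5_noncognate`.
#' @examples
#' net <- build_scheme("independent_with_dissociation",
#'                     y2 = 10^2.5, y5 = 1e4, k5 = 1e3)
#' compute_y_metrics(net)
#' @export
compute_y_metrics <- function(net, focal_pair = c(1L, 1L),
                              noncognate_partner = NULL) {
  stopifnot(inherits(net, "hfq_network"))
  i <- as.integer(focal_pair[1]); j <- as.integer(focal_pair[2])
  if (i < 1L || i > net$n_srna || j < 1L || j > net$m_mrna)
    stop("`focal_pair` out of range", call. = FALSE)
  if (is.null(noncognate_partner)) {
    cand <- setdiff(seq_len(net$m_mrna), j)
    noncognate_partner <- if (length(cand)) cand[1] else NA_integer_
  }
  jp <- as.integer(noncognate_partner)

  k1 <- net$k1[i]; k2 <- net$k2[j]
  k3 <- net$k3[i, j]; k4 <- net$k4[i, j]
  kn1 <- net$kneg1[i]; kn2 <- net$kneg2[j]
  kn3 <- net$kneg3[i, j]; kn4 <- net$kneg4[i, j]

  ratio <- function(num, den, p) {
    if (den == 0) return(NA_real_)
    (num / den)^p
  }
  gm <- function(x, p) prod(x)^p

  y1 <- ratio(k2 * k3, k1 * k4, 0.5)
  y2 <- gm(c(k1, k2, k3, k4), 0.25)
  y3 <- ratio(k2 * k4, k1 * k3, 0.5)
  y4 <- ratio(k3 * k4, k1 * k2, 0.5)
  y5 <- gm(c(kn1, kn2, kn3, kn4), 0.25)
  y6 <- ratio(kn1 * kn2, kn3 * kn4, 0.5)
  y7 <- ratio(k1 * k2 * kn3 * kn4, kn1 * kn2 * k3 * k4, 0.25)

  if (is.na(jp)) {
    y8 <- NA_real_; y9 <- NA_real_; k5n <- NA_real_
  } else {
    k3s <- net$k3[i, jp]; k4s <- net$k4[i, jp]
    kn3s <- net$kneg3[i, jp]; kn4s <- net$kneg4[i, jp]
    y8 <- ratio(k1 * k2 * kn3s * kn4s, kn1 * kn2 * k3s * k4s, 0.25)
    y9 <- gm(c(kn1, kn2, kn3, kn3s, kn4, kn4s), 1 / 6)
    k5n <- net$k5[i, jp]
  }

  tibble::tibble(y1 = y1, y2 = y2, y3 = y3, y4 = y4, y5 = y5, y6 = y6,
                 y7 = y7, y8 = y8, y9 = y9,
                 k5_cognate = net$k5[i, j], k5_noncognate = k5n)
}

#' Elementary association constants from (y1, y2, y3, y4)
#'
#' Inverts the four association definitions.  The system is log-linear with
#' a unique solution:
#' `k1 = y2 / sqrt(y1*y3*y4)`, `k2 = y2 * sqrt(y1*y3/y4)`,
#' `k3 = y2 * sqrt(y1*y4/y3)`, `k4 = y2 * sqrt(y3*y4/y1)`.
#'
#' @param y1,y2,y3,y4 Strictly positive composite association parameters.
#' @return A named numeric vector `c(k1, k2, k3, k4)`.
#' @examples
#' association_from_y(1e4, 10^2.5, 1, 1)
#' @export
association_from_y <- function(y1, y2, y3, y4) {
  vals <- c(y1 = y1, y2 = y2, y3 = y3, y4 = y4)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("y1..y4 must be strictly positive and finite", call. = FALSE)
  c(k1 = y2 / sqrt(y1 * y3 * y4),
    k2 = y2 * sqrt(y1 * y3 / y4),
    k3 = y2 * sqrt(y1 * y4 / y3),
    k4 = y2 * sqrt(y3 * y4 / y1))
}

#' Elementary dissociation constants from (y5, y6)
#'
#' Two constraints on four constants leave the split under-determined; the
#' symmetric convention sets `kneg1 = kneg2 = y5*sqrt(y6)` and
#' `kneg3 = kneg4 = y5/sqrt(y6)`, which satisfies both definitions while
#' treating sRNA and mRNA alike.  `y5 = 0` (no dissociation) requires
#' `y6 = 1` and returns all zeros.
#'
#' @param y5 Overall dissociation magnitude (1/time), `>= 0`.
#' @param y6 Cooperative-dissociation strength (unitless), `> 0`.
#' @return A named numeric vector `c(kneg1, kneg2, kneg3, kneg4)`.
#' @examples
#' dissociation_from_y(1e4, 1e4)
#' @export
dissociation_from_y <- function(y5, y6 = 1) {
  if (!is.finite(y5) || y5 < 0) stop("`y5` must be >= 0", call. = FALSE)
  if (!is.finite(y6) || y6 <= 0) stop("`y6` must be > 0", call. = FALSE)
  if (y5 == 0) {
    if (y6 != 1)
      stop("`y5 = 0` (no dissociation) is inconsistent with `y6 != 1`",
           call. = FALSE)
    return(c(kneg1 = 0, kneg2 = 0, kneg3 = 0, kneg4 = 0))
  }
  c(kneg1 = y5 * sqrt(y6), kneg2 = y5 * sqrt(y6),
    kneg3 = y5 / sqrt(y6), kneg4 = y5 / sqrt(y6))
}
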