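cognate_mask <- function(net) net$k5 > 0

#' Percent of a target mRNA converted to a specific duplex
#'
#' The pathway output: `100 * D[i,j] / total mRNA j`, where the total mRNA
#' pool for species `j` counts its free form, its singly-bound complex, all
#' ternary complexes holding it and all duplexes containing it.  At steady
#' state with uniform degradation this denominator equals `alpha_T[j] /
#' beta`, which [conservation_check()] verifies.
#'
#' @param ss An `hfq_steady_state` from [steady_state()].
#' @param pair Integer pair `c(i, j)`; defaults to `c(1, 1)`.
#' @return A single percentage in `[0, 100]`, or `NA` when the total mRNA
#'   pool is zero.
#' @export
percent_duplex <- function(ss, pair = c(1L, 1L)) {
  stopifnot(inherits(ss, "hfq_steady_state"))
  sp <- ss$species
  i <- pair[1]; j <- pair[2]
  total <- sp$T[j] + sp$HT[j] + sum(sp$HST[, j]) + sum(sp$D[, j])
  if (total <= 0) return(NA_real_)
  100 * sp$D[i, j] / total
}

#' Total Hfq relative to a focal pair's total target mRNA
#'
#' `relative Hfq = 1` means the concentration of Hfq in all its forms
#' equals the total concentration of the focal target mRNA (free, bound and
#' in duplexes).  With uniform degradation this equals
#' `alpha_H / alpha_T[focal_j]` at steady state; the state-based value is
#' returned so that `beta_overrides` are honoured.
#'
#' @param ss An `hfq_steady_state`.
#' @param focal_j Index of the focal target mRNA (default 1).
#' @return A unitless ratio, `NA` when the focal mRNA total is zero.
#' @export
relative_hfq <- function(ss, focal_j = 1L) {
  stopifnot(inherits(ss, "hfq_steady_state"))
  sp <- ss$species
  total_hfq <- sp$H + sum(sp$HS) + sum(sp$HT) + sum(sp$HST)
  total_mrna <- sp$T[focal_j] + sp$HT[focal_j] + sum(sp$HST[, focal_j]) +
    sum(sp$D[, focal_j])
  if (total_mrna <= 0) return(NA_real_)
  total_hfq / total_mrna
}

#' Allocation of Hfq among its molecular forms
#'
#' Splits total Hfq into the fractions held as free hexamer, sRNA
#' singly-bound complex, mRNA singly-bound complex, cognate ternary complex
#' and non-cognate ternary complex (cognate meaning `k5 > 0` for the bound
#' pair).  The fractions sum to one.
#'
#' @param ss An `hfq_steady_state`.
#' @return A one-row tibble with columns `free`, `srna_bound`,
#'   `mrna_bound`, `cognate_ternary`, `noncognate_ternary`; all `NA` when
#'   total Hfq is zero.
#' @export
hfq_allocation <- function(ss) {
  stopifnot(inherits(ss, "hfq_steady_state"))
  sp <- ss$species
  cog <- cognate_mask(ss$network)
  parts <- c(free = sp$H,
             srna_bound = sum(sp$HS),
             mrna_bound = sum(sp$HT),
             cognate_ternary = sum(sp$HST[cog]),
             noncognate_ternary = sum(sp$HST[!cog]))
  total <- sum(parts)
  if (total <= 0) parts[] <- NA_real_ else parts <- parts / total
  tibble::as_tibble(as.list(parts))
}

#' Percent of Hfq sequestered in non-productive complexes
#'
#' Sequestered Hfq is bound Hfq that cannot currently release a duplex:
#' singly-bound complexes plus non-cognate ternary complexes, as a
#' percentage of total Hfq.  (This is a convention: the complement of the
#' free and cognate-ternary fractions of [hfq_allocation()].)
#'
#' @param ss An `hfq_steady_state`.
#' @return A percentage in `[0, 100]`, `NA` when total Hfq is zero.
#' @export
percent_hfq_sequestered <- function(ss) {
  al <- hfq_allocation(ss)
  if (anyNA(al)) return(NA_real_)
  100 * (al$srna_bound + al$mrna_bound + al$noncognate_ternary)
}
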