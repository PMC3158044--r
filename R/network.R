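#' Define an Hfq reaction network
#'
#' An `hfq_network` is the complete kinetic specification of a deterministic
#' mass-action model in which `n` sRNA species and `m` target-mRNA species
#' compete for a shared pool of Hfq hexamers.  Each Hfq hexamer can carry at
#' most one sRNA and one mRNA; a ternary complex (Hfq bound by one sRNA and
#' one mRNA) can anneal its cargo into a duplex and release it together with
#' free Hfq in a single lumped step.
#'
#' The molecular species are: free Hfq (`H`), free sRNAs (`S_i`), free mRNAs
#' (`T_j`), singly-bound complexes (`HS_i`, `HT_j`), ternary complexes
#' (`HST_ij`) and duplexes (`D_ij`).  Concentrations and time are unitless
#' model units; rate-constant magnitudes in the preset regimes span roughly
#' 1e-5 to 1e8.
#'
#' Reactions, with their rate constants:
#' * `S_i + H <-> HS_i` at `k1[i]` / `kneg1[i]`
#' * `T_j + H <-> HT_j` at `k2[j]` / `kneg2[j]`
#' * `T_j + HS_i <-> HST_ij` at `k3[i,j]` / `kneg3[i,j]`
#' * `S_i + HT_j <-> HST_ij` at `k4[i,j]` / `kneg4[i,j]`
#' * `HST_ij -> D_ij + H` at `k5[i,j]` (annealing and release; duplexes
#'   never rebind Hfq)
#'
#' Every species is produced at a constant rate (`alpha_*`, zero for
#' complexes) and removed by first-order degradation/dilution at the global
#' rate `beta`, optionally overridden per species role via `beta_overrides`.
#'
#' @param n_srna,m_mrna Positive integer counts of sRNA and mRNA species.
#' @param alpha_H Hfq production rate (concentration/time).
#' @param alpha_S,alpha_T Production rates of the sRNAs (length `n_srna`)
#'   and mRNAs (length `m_mrna`); scalars are recycled.
#' @param beta Global degradation/dilution rate constant (1/time).
#' @param k1,kneg1 Association (1/(concentration*time)) and dissociation
#'   (1/time) of sRNAs with free Hfq; length `n_srna`, scalars recycled.
#' @param k2,kneg2 Same for mRNAs with free Hfq; length `m_mrna`.
#' @param k3,kneg3 `n x m` matrices: mRNA `j` binding to / leaving the
#'   `HS_i` complex (off-diagonal entries describe non-cognate ternary
#'   complex formation).  Scalars are expanded to a constant matrix.
#' @param k4,kneg4 `n x m` matrices: sRNA `i` binding to / leaving the
#'   `HT_j` complex.
#' @param k5 `n x m` matrix of duplex annealing-and-release rates (1/time);
#'   positive entries mark cognate pairs, zeros non-cognate ones.
#' @param beta_overrides Optional named list overriding `beta` for a species
#'   role; names among `"H"`, `"S"`, `"T"`, `"HS"`, `"HT"`, `"HST"`, `"D"`.
#'   Each entry is a scalar or a vector/matrix of the role's natural shape
#'   (e.g. `list(S = 10)` degrades all free sRNAs ten-fold faster).
#'
#' @return An object of class `hfq_network`: a validated list carrying the
#'   dimensions, production rates and rate-constant tensors.
#' @seealso [steady_state()], [hfq_sweep()], [build_scheme()],
#'   [state_dimension()], [tidy.hfq_network()]
#' @examples
#' net <- hfq_network(1, 1, alpha_H = 1, k1 = 100, k2 = 100,
#'                    k3 = 100, k4 = 100, k5 = 1000)
#' state_dimension(net)
#' @export
hfq_network <- function(n_srna, m_mrna,
                        alpha_H = 1,
                        alpha_S = 1, alpha_T = 1,
                        beta = 1,
                        k1 = 0, kneg1 = 0,
                        k2 = 0, kneg2 = 0,
                        k3 = 0, kneg3 = 0,
                        k4 = 0, kneg4 = 0,
                        k5 = 0,
                        beta_overrides = NULL) {
  n <- as.integer(n_srna)
  m <- as.integer(m_mrna)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("`n_srna` must be a single positive integer", call. = FALSE)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop("`m_mrna` must be a single positive integer", call. = FALSE)

  net <- structure(list(
    n_srna = n, m_mrna = m,
    alpha_H = as.numeric(alpha_H),
    alpha_S = expand_vec(alpha_S, n, "alpha_S"),
    alpha_T = expand_vec(alpha_T, m, "alpha_T"),
    beta = as.numeric(beta),
    k1 = expand_vec(k1, n, "k1"),
    kneg1 = expand_vec(kneg1, n, "kneg1"),
    k2 = expand_vec(k2, m, "k2"),
    kneg2 = expand_vec(kneg2, m, "kneg2"),
    k3 = expand_mat(k3, n, m, "k3"),
    kneg3 = expand_mat(kneg3, n, m, "kneg3"),
    k4 = expand_mat(k4, n, m, "k4"),
    kneg4 = expand_mat(kneg4, n, m, "kneg4"),
    k5 = expand_mat(k5, n, m, "k5"),
    beta_overrides = beta_overrides
  ), class = "hfq_network")
  validate_hfq_network(net)
}

expand_vec <- function(x, len, name) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, len)
  if (length(x) != len)
    stop(sprintf("`%s` must have length 1 or %d, got %d", name, len, length(x)),
         call. = FALSE)
  x
}

expand_mat <- function(x, n, m, name) {
  if (is.null(dim(x))) {
    x <- as.numeric(x)
    if (length(x) == 1L) return(matrix(x, n, m))
    stop(sprintf("`%s` must be a scalar or an %d x %d matrix", name, n, m),
         call. = FALSE)
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(n, m)))
    stop(sprintf("`%s` must be %d x %d, got %d x %d",
                 name, n, m, nrow(x), ncol(x)), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

validate_hfq_network <- function(net) {
  num_fields <- c("alpha_H", "alpha_S", "alpha_T", "beta",
                  "k1", "kneg1", "k2", "kneg2",
                  "k3", "kneg3", "k4", "kneg4", "k5")
  for (f in num_fields) {
    v <- net[[f]]
    if (anyNA(v) || any(v < 0))
      stop(sprintf("`%s` must be non-negative and finite", f), call. = FALSE)
    if (any(!is.finite(v)))
      stop(sprintf("`%s` must be finite", f), call. = FALSE)
  }
  if (net$beta <= 0)
    stop("`beta` must be strictly positive", call. = FALSE)
  bo <- net$beta_overrides
  if (!is.null(bo)) {
    if (!is.list(bo) || is.null(names(bo)) || any(names(bo) == ""))
      stop("`beta_overrides` must be a named list", call. = FALSE)
    roles <- c("H", "S", "T", "HS", "HT", "HST", "D")
    bad <- setdiff(names(bo), roles)
    if (length(bad))
      stop("unknown `beta_overrides` roles: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (r in names(bo)) {
      if (anyNA(bo[[r]]) || any(bo[[r]] < 0))
        stop(sprintf("beta_overrides$%s must be non-negative", r),
             call. = FALSE)
    }
  }
  net
}

#' @export
print.hfq_network <- function(x, ...) {
  cat(sprintf("<hfq_network> %d sRNA x %d mRNA (%d ODE states)\n",
              x$n_srna, x$m_mrna, state_dimension(x)))
  cat(sprintf("  alpha_H = %g, beta = %g\n", x$alpha_H, x$beta))
  cat(sprintf("  alpha_S in [%g, %g]; alpha_T in [%g, %g]\n",
              min(x$alpha_S), max(x$alpha_S), min(x$alpha_T), max(x$alpha_T)))
  cog <- sum(x$k5 > 0)
  cat(sprintf("  k5 > 0 for %d of %d (sRNA, mRNA) pairs\n",
              cog, x$n_srna * x$m_mrna))
  if (!is.null(x$beta_overrides))
    cat("  beta overrides:", paste(names(x$beta_overrides), collapse = ", "),
        "\n")
  invisible(x)
}

#' Number of ODE states for a network
#'
#' One equation for free Hfq, `n + m` for the free RNAs, `n + m` for the
#' singly-bound complexes, and `n*m` each for ternary complexes and
#' duplexes: `1 + 2n + 2m + 2nm` in total.
#'
#' @param net An [hfq_network()].
#' @return A single integer.
#' @examples
#' state_dimension(hfq_network(5, 5)) # 71
#' @export
state_dimension <- function(net) {
  stopifnot(inherits(net, "hfq_network"))
  n <- net$n_srna; m <- net$m_mrna
  as.integer(1L + 2L * n + 2L * m + 2L * n * m)
}

#' Count the distinct Hfq complex types in a single-partner network
#'
#' In a network of `n` sRNA-target mRNA pairs where each RNA has exactly one
#' cognate partner (cognate iff `i == j`), the possible Hfq complex classes
#' are: `2n` singly-bound complexes, `n` cognate ternary complexes and
#' `n^2 - n` non-cognate ternary complexes.  If sRNAs and mRNAs compete for
#' shared sites on Hfq instead of having separate sites, two same-class RNAs
#' can co-occupy a hexamer and the non-cognate count grows to `2n^2 - n`
#' (adding the `(sRNA)2`-Hfq and `(mRNA)2`-Hfq classes).
#'
#' @param n,m Number of sRNA and mRNA species; pairing requires `n == m`.
#' @param shared_sites If `TRUE`, count the shared-site combinatorics.
#' @return A tibble with columns `singly_bound`, `cognate_ternary`,
#'   `noncognate_ternary`.
#' @examples
#' count_complex_types(5, 5)
#' @export
count_complex_types <- function(n, m = n, shared_sites = FALSE) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (n != m)
    stop("single-partner pairing requires n == m", call. = FALSE)
  tibble::tibble(
    singly_bound = 2L * n,
    cognate_ternary = n,
    noncognate_ternary = if (shared_sites) 2L * n * n - n else n * n - n
  )
}

# ---- state packing -------------------------------------------------------
# Fixed flattening order: H, S (1..n), T (1..m), HS, HT, HST row-major,
# D row-major.  All serialization and solver code relies on this layout.

state_index <- function(n, m) {
  list(
    H = 1L,
    S = 1L + seq_len(n),
    T = 1L + n + seq_len(m),
    HS = 1L + n + m + seq_len(n),
    HT = 1L + 2L * n + m + seq_len(m),
    HST = 1L + 2L * n + 2L * m + seq_len(n * m),
    D = 1L + 2L * n + 2L * m + n * m + seq_len(n * m)
  )
}

#' Assemble a flat state vector from species blocks
#'
#' @param net An [hfq_network()].
#' @param H,S,T,HS,HT,HST,D Species concentrations; scalars are recycled to
#'   the block's natural shape (`HST` and `D` are `n x m`, stored row-major
#'   with the sRNA index `i` varying slowest).
#' @return A named numeric vector of length [state_dimension()].
#' @export
pack_state <- function(net, H = 0, S = 0, T = 0, HS = 0, HT = 0,
                       HST = 0, D = 0) {
  n <- net$n_srna; m <- net$m_mrna
  HSTm <- expand_mat(HST, n, m, "HST")
  Dm <- expand_mat(D, n, m, "D")
  x <- c(as.numeric(H),
         expand_vec(S, n, "S"), expand_vec(T, m, "T"),
         expand_vec(HS, n, "HS"), expand_vec(HT, m, "HT"),
         as.numeric(t(HSTm)), as.numeric(t(Dm)))
  names(x) <- state_names(net)
  x
}

#' Split a flat state vector into named species blocks
#'
#' @param net An [hfq_network()].
#' @param x Numeric vector of length [state_dimension()].
#' @return A list with elements `H` (scalar), `S`, `T`, `HS`, `HT`
#'   (vectors) and `HST`, `D` (`n x m` matrices).
#' @export
unpack_state <- function(net, x) {
  n <- net$n_srna; m <- net$m_mrna
  if (length(x) != state_dimension(net))
    stop(sprintf("state has length %d, expected %d",
                 length(x), state_dimension(net)), call. = FALSE)
  idx <- state_index(n, m)
  list(
    H = unname(x[idx$H]),
    S = unname(x[idx$S]),
    T = unname(x[idx$T]),
    HS = unname(x[idx$HS]),
    HT = unname(x[idx$HT]),
    HST = matrix(x[idx$HST], n, m, byrow = TRUE),
    D = matrix(x[idx$D], n, m, byrow = TRUE)
  )
}

state_names <- function(net) {
  n <- net$n_srna; m <- net$m_mrna
  ij <- expand.grid(j = seq_len(m), i = seq_len(n))[, c("i", "j")]
  c("H",
    paste0("S", seq_len(n)),
    paste0("T", seq_len(m)),
    paste0("HS", seq_len(n)),
    paste0("HT", seq_len(m)),
    paste0("HST", ij$i, "_", ij$j),
    paste0("D", ij$i, "_", ij$j))
}

# Effective degradation rates per flattened state entry, honouring
# beta_overrides.  Returns a vector aligned with the state layout.
beta_vector <- function(net) {
  n <- net$n_srna; m <- net$m_mrna
  bo <- net$beta_overrides
  one <- function(role, len, mat = FALSE) {
    if (!is.null(bo) && !is.null(bo[[role]])) {
      if (mat) as.numeric(t(expand_mat(bo[[role]], n, m, role)))
      else expand_vec(bo[[role]], len, role)
    } else rep(net$beta, len)
  }
  c(one("H", 1L), one("S", n), one("T", m), one("HS", n), one("HT", m),
    one("HST", n * m, mat = TRUE), one("D", n * m, mat = TRUE))
}
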