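#' Tidy a network specification into a long tibble
#'
#' One row per rate parameter: production rates, degradation, and every
#' entry of the rate-constant vectors and matrices, with the sRNA/mRNA
#' indices it applies to.
#'
#' @param x An [hfq_network()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `i`, `j`, `value`.
#' @method tidy hfq_network
#' @export
tidy.hfq_network <- function(x, ...) {
  n <- x$n_srna; m <- x$m_mrna
  vec_rows <- function(name, v, role) {
    tibble::tibble(parameter = name,
                   i = if (role == "s") seq_along(v) else NA_integer_,
                   j = if (role == "t") seq_along(v) else NA_integer_,
                   value = as.numeric(v))
  }
  mat_rows <- function(name, mm) {
    tibble::tibble(parameter = name,
                   i = as.integer(row(mm)), j = as.integer(col(mm)),
                   value = as.numeric(mm))
  }
  dplyr::bind_rows(
    tibble::tibble(parameter = c("alpha_H", "beta"), i = NA_integer_,
                   j = NA_integer_, value = c(x$alpha_H, x$beta)),
    vec_rows("alpha_S", x$alpha_S, "s"), vec_rows("alpha_T", x$alpha_T, "t"),
    vec_rows("k1", x$k1, "s"), vec_rows("kneg1", x$kneg1, "s"),
    vec_rows("k2", x$k2, "t"), vec_rows("kneg2", x$kneg2, "t"),
    mat_rows("k3", x$k3), mat_rows("kneg3", x$kneg3),
    mat_rows("k4", x$k4), mat_rows("kneg4", x$kneg4),
    mat_rows("k5", x$k5))
}

#' One-line summary of a network
#'
#' @param x An [hfq_network()].
#' @param ... Unused.
#' @return A one-row tibble: dimensions, state count, cognate pair count,
#'   production rates.
#' @method glance hfq_network
#' @export
glance.hfq_network <- function(x, ...) {
  tibble::tibble(n_srna = x$n_srna, m_mrna = x$m_mrna,
                 n_states = state_dimension(x),
                 n_cognate = sum(x$k5 > 0),
                 alpha_H = x$alpha_H, beta = x$beta)
}

#' Tidy a steady state into species records
#'
#' @param x An `hfq_steady_state` from [steady_state()].
#' @param ... Unused.
#' @return A tibble with columns `species` (H, S, T, HS, HT, HST, D),
#'   `i`, `j` and `concentration` — the tabular serialization of the
#'   state.
#' @method tidy hfq_steady_state
#' @export
tidy.hfq_steady_state <- function(x, ...) {
  sp <- x$species
  n <- x$network$n_srna; m <- x$network$m_mrna
  dplyr::bind_rows(
    tibble::tibble(species = "H", i = NA_integer_, j = NA_integer_,
                   concentration = sp$H),
    tibble::tibble(species = "S", i = seq_len(n), j = NA_integer_,
                   concentration = sp$S),
    tibble::tibble(species = "T", i = NA_integer_, j = seq_len(m),
                   concentration = sp$T),
    tibble::tibble(species = "HS", i = seq_len(n), j = NA_integer_,
                   concentration = sp$HS),
    tibble::tibble(species = "HT", i = NA_integer_, j = seq_len(m),
                   concentration = sp$HT),
    tibble::tibble(species = "HST", i = as.integer(row(sp$HST)),
                   j = as.integer(col(sp$HST)),
                   concentration = as.numeric(sp$HST)),
    tibble::tibble(species = "D", i = as.integer(row(sp$D)),
                   j = as.integer(col(sp$D)),
                   concentration = as.numeric(sp$D)))
}

#' Convergence metadata of a steady-state solve
#'
#' @param x An `hfq_steady_state`.
#' @param ... Unused.
#' @return A one-row tibble: `converged`, `method`, `horizon`,
#'   `iterations`, `residual`, plus headline outputs (free Hfq, total
#'   duplex).
#' @method glance hfq_steady_state
#' @export
glance.hfq_steady_state <- function(x, ...) {
  tibble::tibble(converged = x$converged, method = x$method,
                 horizon = x$horizon, iterations = x$iterations,
                 residual = x$residual,
                 free_hfq = x$species$H, total_duplex = sum(x$species$D))
}
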