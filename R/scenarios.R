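#' Named simulation scenarios
#'
#' A scenario packages one of the standard simulation designs — a set of
#' kinetic regimes, network sizes and production patterns — as a list of
#' labelled networks plus sweep settings, ready for [run_scenario()].
#' Available ids:
#'
#' * `fig2` — independent binding, no dissociation; 3x3 grid of
#'   `y1 = c(1e-4, 1, 1e4)` by `y2 = c(10^0.5, 10^2.5, 10^4.5)`.
#' * `fig3_assoc` — cooperative association; 3x3 grid of
#'   `y3` by `y4`, both `c(1e-4, 1, 1e4)`.
#' * `fig3_dissoc` — independent binding and dissociation; 3x3 grid of
#'   `y5 = c(1, 1e4, 1e8)` by `k5 = c(1, 1e3, 1e6)`.
#' * `fig4a` — cooperative association with/without independent
#'   dissociation: `y4 = c(1, 1e4)` by `y5 = c(0, 1e4)`.
#' * `fig4b` — cooperative association with/without cooperative
#'   dissociation: `y4 = c(1, 1e4)` by `y6 = c(1, 1e4)` at `y5 = 1e4`.
#' * `fig6` — one pair in isolation vs the same kinetics inside a
#'   five-pair single-partner network (independent binding/unbinding).
#' * `fig7` — network scaling of cognate selection (`y7 = 0.1`) and
#'   non-cognate exclusion (`y8 = 10`), alone and combined, over
#'   `n = c(1, 2, 5, 10, 20)`.
#' * `fig8` — network scaling of dissociation (`y9 = c(1, 1e4)`) against
#'   annealing (`k5 = c(1e3, 1e6)`) over the same `n` values.
#' * `fig9` — stability mixes: grids of stable x unstable pair counts with
#'   focal stable and unstable pairs.
#' * `fig10` — specific vs indiscriminate pairing at slow/fast
#'   dissociation (`y9 = c(1, 1e4)`).
#' * `fig11` — sRNA:mRNA production ratio from 5:1 to 1:5 at constant
#'   combined production, branch bias `y3 = c(1e-8, 1, 1e8)`.
#' * `fig12` — two-pair network with sRNA 1 production scaled 1x to 100x.
#' * `fig13` — unpartnered-pool design: control / increased-dissociation /
#'   non-cognate-exclusion kinetics, affinity ratio `c(1, 1e-2, 1e2)`,
#'   with and without the 100x pool.
#' * `s1` — uniform degradation vs 10x free-sRNA degradation for three
#'   base regimes.
#'
#' Every numeric design choice can be overridden through `...` (for
#' example `scenario("fig7", n = c(1, 5), points_per_decade = 4)`).
#'
#' @param id Scenario id (see above).
#' @param ... Overrides of the scenario's parameters, plus the sweep
#'   controls `grid_from`, `grid_to` and `points_per_decade`.
#' @return An object of class `hfq_scenario`.
#' @seealso [expand_scenario()], [run_scenario()]
#' @export
scenario <- function(id, ...) {
  defaults <- scenario_defaults(id)
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad))
    stop(sprintf("unknown parameters for scenario '%s': %s", id,
                 paste(bad, collapse = ", ")), call. = FALSE)
  params <- utils::modifyList(defaults, dots)
  structure(list(id = id, params = params), class = "hfq_scenario")
}

scenario_ids <- c("fig2", "fig3_assoc", "fig3_dissoc", "fig4a", "fig4b",
                  "fig6", "fig7", "fig8", "fig9", "fig10", "fig11",
                  "fig12", "fig13", "s1")

scenario_defaults <- function(id) {
  if (!id %in% scenario_ids)
    stop(sprintf("unknown scenario id '%s'; expected one of: %s", id,
                 paste(scenario_ids, collapse = ", ")), call. = FALSE)
  sweep_defaults <- list(grid_from = 1e-5, grid_to = 1e7,
                         points_per_decade = 10)
  extra <- switch(id,
    fig2 = list(y1 = c(1e-4, 1, 1e4), y2 = 10^c(0.5, 2.5, 4.5), k5 = 1e3),
    fig3_assoc = list(y3 = c(1e-4, 1, 1e4), y4 = c(1e-4, 1, 1e4),
                      y2 = 10^2.5, k5 = 1e3),
    fig3_dissoc = list(y5 = c(1, 1e4, 1e8), k5 = c(1, 1e3, 1e6),
                       y2 = 10^2.5),
    fig4a = list(y4 = c(1, 1e4), y5 = c(0, 1e4), y2 = 10^2.5, k5 = 1e3),
    fig4b = list(y4 = c(1, 1e4), y6 = c(1, 1e4), y5 = 1e4, y2 = 10^2.5,
                 k5 = 1e3),
    fig6 = list(n = c(1, 5), y2 = 10^0.5, y9 = 1, k5 = 1e0),
    fig7 = list(n = c(1, 2, 5, 10, 20), y7 = 0.1, y8 = 10, y2 = 10^2.5,
                y9 = 1, k5 = 1e3),
    fig8 = list(n = c(1, 2, 5, 10, 20), y9 = c(1, 1e4), k5 = c(1e3, 1e6),
                y2 = 10^2.5),
    fig9 = list(n_stable = 0:8, n_unstable = 0:8, y9_stable = 1,
                y9_unstable = 1e4, y2 = 10^2.5, k5 = 1e3),
    fig10 = list(n = 5, y9 = c(1, 1e4), k5 = 1e3, y2 = 10^2.5),
    fig11 = list(ratio = c(5, 2, 1, 1 / 2, 1 / 5),
                 y3 = c(1e-8, 1, 1e8), y2 = 10^2.5, k5 = 1e3),
    fig12 = list(srna1_fold = 10^seq(0, 2, by = 0.5), y2 = 10^2.5,
                 y9 = 1, k5 = 1e3),
    fig13 = list(variant = c("control", "dissociation", "exclusion"),
                 affinity_ratio = c(1, 1e-2, 1e2), pool_fold = 100,
                 with_pool = c(FALSE, TRUE), y2 = 10^2.5, k5 = 1e3),
    s1 = list(base = c("independent", "cooperative_association",
                       "rapid_dissociation"),
              srna_beta_fold = c(1, 10), y2 = 10^2.5, k5 = 1e3)
  )
  c(extra, sweep_defaults)
}

#' @export
print.hfq_scenario <- function(x, ...) {
  cat(sprintf("<hfq_scenario> %s (%d simulation entries)\n",
              x$id, nrow(expand_scenario(x))))
  invisible(x)
}

panel_label <- function(row, col) {
  paste0(c("T", "M", "B")[row], c("L", "C", "R")[col])
}

fmt <- function(x) {
  if (is.character(x)) return(x)
  ifelse(x == 0, "0", sprintf("1e%.3g", log10(x)))
}

#' Expand a scenario into labelled networks
#'
#' Deterministically expands a [scenario()] into its simulation entries:
#' one row per network to sweep, with a human-readable label (3x3 designs
#' also carry a `panel` position, rows by the first varied parameter and
#' columns by the second).
#'
#' @param sc An `hfq_scenario`.
#' @return A tibble with columns `label`, `panel`, `network` (list of
#'   [hfq_network()] objects), `pairs` (list of focal pairs) and `grid`
#'   (list of alpha_H grids).
#' @export
expand_scenario <- function(sc) {
  stopifnot(inherits(sc, "hfq_scenario"))
  p <- sc$params
  grid <- alpha_H_grid(p$grid_from, p$grid_to, p$points_per_decade)
  entry <- function(label, network, pairs = list(c(1L, 1L)), panel = NA) {
    tibble::tibble(label = label, panel = panel, network = list(network),
                   pairs = list(pairs), grid = list(grid))
  }

  rows <- switch(sc$id,
    fig2 = {
      out <- list()
      for (r in seq_along(p$y1)) for (cc in seq_along(p$y2))
        out[[length(out) + 1L]] <- entry(
          sprintf("y1=%s|y2=%s", fmt(p$y1[r]), fmt(p$y2[cc])),
          build_scheme("independent_no_dissociation", y1 = p$y1[r],
                       y2 = p$y2[cc], k5 = p$k5),
          panel = panel_label(r, cc))
      out
    },
    fig3_assoc = {
      out <- list()
      for (r in seq_along(p$y4)) for (cc in seq_along(p$y3))
        out[[length(out) + 1L]] <- entry(
          sprintf("y3=%s|y4=%s", fmt(p$y3[cc]), fmt(p$y4[r])),
          build_scheme("cooperative_association", y3 = p$y3[cc],
                       y4 = p$y4[r], y2 = p$y2, k5 = p$k5),
          panel = panel_label(r, cc))
      out
    },
    fig3_dissoc = {
      out <- list()
      for (r in seq_along(p$y5)) for (cc in seq_along(p$k5))
        out[[length(out) + 1L]] <- entry(
          sprintf("y5=%s|k5=%s", fmt(p$y5[r]), fmt(p$k5[cc])),
          build_scheme("independent_with_dissociation", y5 = p$y5[r],
                       y2 = p$y2, k5 = p$k5[cc]),
          panel = panel_label(r, cc))
      out
    },
    fig4a = {
      out <- list()
      for (y5 in p$y5) for (y4 in p$y4)
        out[[length(out) + 1L]] <- entry(
          sprintf("y4=%s|y5=%s", fmt(y4), fmt(y5)),
          build_scheme("cooperative_dissociation", y4 = y4, y5 = y5,
                       y6 = 1, y2 = p$y2, k5 = p$k5))
      out
    },
    fig4b = {
      out <- list()
      for (y6 in p$y6) for (y4 in p$y4)
        out[[length(out) + 1L]] <- entry(
          sprintf("y4=%s|y6=%s", fmt(y4), fmt(y6)),
          build_scheme("cooperative_dissociation", y4 = y4, y5 = p$y5,
                       y6 = y6, y2 = p$y2, k5 = p$k5))
      out
    },
    fig6 = lapply(p$n, function(n) entry(
      sprintf("n=%d", n),
      build_scheme("network_uniform", n = n, y2 = p$y2, y9 = p$y9,
                   k5 = p$k5))),
    fig7 = {
      topo <- list(independent = c(1, 1), cognate_selection = c(p$y7, 1),
                   noncognate_exclusion = c(1, p$y8),
                   both = c(p$y7, p$y8))
      out <- list()
      for (tn in names(topo)) for (n in p$n) {
        if (n == 1 && tn != "independent") next  # no non-cognate class
        out[[length(out) + 1L]] <- entry(
          sprintf("%s|n=%d", tn, n),
          build_scheme("network_uniform", n = n, y2 = p$y2, y9 = p$y9,
                       y7 = topo[[tn]][1], y8 = topo[[tn]][2], k5 = p$k5))
      }
      out
    },
    fig8 = {
      out <- list()
      for (y9 in p$y9) for (k5 in p$k5) for (n in p$n)
        out[[length(out) + 1L]] <- entry(
          sprintf("k5=%s|y9=%s|n=%d", fmt(k5), fmt(y9), n),
          build_scheme("network_uniform", n = n, y2 = p$y2, y9 = y9,
                       k5 = k5))
      out
    },
    fig9 = {
      out <- list()
      for (ns in p$n_stable) for (nu in p$n_unstable) {
        if (ns + nu == 0) next
        net <- stability_mix(ns, nu, y9_stable = p$y9_stable,
                             y9_unstable = p$y9_unstable, y2 = p$y2,
                             k5 = p$k5)
        pairs <- list()
        if (ns > 0) pairs$stable <- c(1L, 1L)
        if (nu > 0) pairs$unstable <- c(ns + 1L, ns + 1L)
        out[[length(out) + 1L]] <- entry(
          sprintf("stable=%d|unstable=%d", ns, nu), net, pairs = pairs)
      }
      out
    },
    fig10 = {
      out <- list()
      for (pairing in c("specific", "indiscriminate")) for (y9 in p$y9)
        out[[length(out) + 1L]] <- entry(
          sprintf("%s|y9=%s", pairing, fmt(y9)),
          build_scheme(
            if (pairing == "specific") "network_uniform" else "indiscriminate",
            n = p$n, y2 = p$y2, y9 = y9, k5 = p$k5))
      out
    },
    fig11 = {
      out <- list()
      for (y3 in p$y3) for (r in p$ratio)
        out[[length(out) + 1L]] <- entry(
          sprintf("y3=%s|ratio=%s", fmt(y3), format(r)),
          build_scheme("imbalanced_pair", ratio = r, y3 = y3, y2 = p$y2,
                       k5 = p$k5))
      out
    },
    fig12 = lapply(p$srna1_fold, function(f) entry(
      sprintf("srna1_fold=%.3g", f),
      build_scheme("two_pair_overproduction", srna1_fold = f, y2 = p$y2,
                   y9 = p$y9, k5 = p$k5),
      pairs = list(pair1 = c(1L, 1L), pair2 = c(2L, 2L)))),
    fig13 = {
      out <- list()
      for (v in p$variant) for (ar in p$affinity_ratio) for (wp in p$with_pool)
        out[[length(out) + 1L]] <- entry(
          sprintf("%s|affinity=%s|%s", v, fmt(ar),
                  if (wp) "pool" else "no_pool"),
          build_scheme("unpartnered_pool", variant = v,
                       affinity_ratio = ar, pool_fold = p$pool_fold,
                       with_pool = wp, y2 = p$y2, k5 = p$k5))
      out
    },
    s1 = {
      out <- list()
      for (b in p$base) for (f in p$srna_beta_fold)
        out[[length(out) + 1L]] <- entry(
          sprintf("%s|srna_beta_fold=%g", b, f),
          build_scheme("s1_degradation", base = b, srna_beta_fold = f,
                       y2 = p$y2, k5 = p$k5))
      out
    }
  )
  dplyr::bind_rows(rows)
}

#' Run every simulation entry of a scenario
#'
#' Orchestrates [hfq_sweep()] and [bounds_and_robustness()] over the
#' expansion of a scenario.  Per-entry convergence failures are recorded in
#' the sweep rows and the run continues.  Results can be cached in an
#' environment keyed by label, making interrupted runs resumable.
#'
#' @param sc An `hfq_scenario` (or a scenario id string).
#' @param cfg A [convergence_config()].
#' @param threshold Percent-duplex threshold for the robustness summaries.
#' @param cache Optional environment; sweeps already present (by label)
#'   are reused and new ones stored.
#' @param quiet Suppress per-label progress messages.
#' @return A list with `sweeps` (one tibble, all sweep rows with a `label`
#'   column) and `summaries` (one `hfq_robustness` row per label x focal
#'   pair, with `pair` naming the focal class where the scenario defines
#'   one).
#' @export
run_scenario <- function(sc, cfg = convergence_config(), threshold = 10,
                         cache = NULL, quiet = TRUE) {
  if (is.character(sc)) sc <- scenario(sc)
  ex <- expand_scenario(sc)
  sweeps <- vector("list", nrow(ex))
  summaries <- vector("list", nrow(ex))
  for (k in seq_len(nrow(ex))) {
    lbl <- ex$label[k]
    if (!quiet) message(sprintf("[%s] %s", sc$id, lbl))
    sw <- if (!is.null(cache) && exists(lbl, envir = cache, inherits = FALSE))
      get(lbl, envir = cache)
    else hfq_sweep(ex$network[[k]], grid = ex$grid[[k]],
                   pairs = ex$pairs[[k]], cfg = cfg)
    if (!is.null(cache)) assign(lbl, sw, envir = cache)
    sweeps[[k]] <- dplyr::mutate(sw, label = lbl, .before = 1)
    prs <- ex$pairs[[k]]
    pr_names <- names(prs) %||% rep(NA_character_, length(prs))
    summaries[[k]] <- dplyr::bind_rows(lapply(seq_along(prs), function(q) {
      bb <- suppressWarnings(
        bounds_and_robustness(sw, prs[[q]], threshold = threshold))
      dplyr::mutate(bb, label = lbl, pair = pr_names[q], .before = 1)
    }))
  }
  list(sweeps = dplyr::bind_rows(sweeps),
       summaries = dplyr::bind_rows(summaries))
}
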