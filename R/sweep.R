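#' Default Hfq-production grid
#'
#' Log-spaced grid over the standard titration range 1e-5 to 1e7
#' concentration/time.
#'
#' @param from,to Grid end points (alpha_H values).
#' @param points_per_decade Grid density (default 10, resolving bounds to
#'   under 0.1 decade).
#' @return A strictly increasing numeric vector.
#' @export
alpha_H_grid <- function(from = 1e-5, to = 1e7, points_per_decade = 10) {
  decades <- log10(to) - log10(from)
  10^seq(log10(from), log10(to), length.out = round(decades *
                                                     points_per_decade) + 1)
}

#' Sweep Hfq production and collect steady-state metrics
#'
#' Solves the network to steady state at every value of an increasing
#' `alpha_H` grid and records, per grid point and focal pair: the relative
#' Hfq concentration, percent duplex, the Hfq allocation fractions and
#' percent Hfq sequestered.  By default each point after the first is
#' solved by Newton continuation warm-started from the previous steady
#' state, with automatic fallback to stiff integration whenever the Newton
#' result fails validation (residual, non-negativity); `method =
#' "integrate"` forces the reference integrator everywhere.  Per-point
#' convergence failures are recorded in the `converged` column, never
#' fatal.
#'
#' @param net Template [hfq_network()]; its `alpha_H` is replaced by each
#'   grid value.
#' @param grid Increasing vector of Hfq production rates
#'   (default [alpha_H_grid()]).
#' @param pairs List of focal `c(i, j)` pairs (default the (1,1) pair).
#' @param cfg A [convergence_config()].
#' @param method `"continuation"` (default) or `"integrate"`.
#' @return A tibble of class `hfq_sweep`: one row per grid point x focal
#'   pair with columns `alpha_H`, `pair_i`, `pair_j`, `relative_hfq`,
#'   `percent_duplex`, `free`, `srna_bound`, `mrna_bound`,
#'   `cognate_ternary`, `noncognate_ternary`, `percent_sequestered`,
#'   `converged`, `solver`.
#' @examples
#' net <- build_scheme("independent_with_dissociation", y5 = 1e4, k5 = 1e3)
#' sw <- hfq_sweep(net, alpha_H_grid(1e-2, 1e2, points_per_decade = 2))
#' @export
hfq_sweep <- function(net, grid = alpha_H_grid(), pairs = list(c(1L, 1L)),
                      cfg = convergence_config(),
                      method = c("continuation", "integrate")) {
  stopifnot(inherits(net, "hfq_network"))
  method <- match.arg(method)
  if (any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing", call. = FALSE)
  if (!is.list(pairs)) pairs <- list(pairs)

  prev <- NULL
  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    nk <- set_alpha_H(net, grid[k])
    ss <- NULL
    if (method == "continuation" && !is.null(prev)) {
      ss <- steady_state_newton(nk, cfg, init = prev)
      if (!ss$converged) ss <- NULL
    }
    if (is.null(ss)) ss <- steady_state_integrate(nk, cfg)
    if (ss$converged) prev <- ss$state

    al <- hfq_allocation(ss)
    per_pair <- lapply(pairs, function(p) {
      tibble::tibble(
        alpha_H = grid[k], pair_i = p[1], pair_j = p[2],
        relative_hfq = relative_hfq(ss, p[2]),
        percent_duplex = percent_duplex(ss, p),
        free = al$free, srna_bound = al$srna_bound,
        mrna_bound = al$mrna_bound,
        cognate_ternary = al$cognate_ternary,
        noncognate_ternary = al$noncognate_ternary,
        percent_sequestered = percent_hfq_sequestered(ss),
        converged = ss$converged, solver = ss$method)
    })
    rows[[k]] <- dplyr::bind_rows(per_pair)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hfq_sweep", class(out))
  attr(out, "network") <- net
  out
}

#' Lower/upper Hfq bounds and robustness from a sweep
#'
#' The lower and upper bounds are the minimum and maximum relative-Hfq
#' values at which at least `threshold` percent of the focal target mRNA is
#' converted to duplex, located by interpolating the duplex curve linearly
#' in `log10(relative Hfq)` between the grid points bracketing each
#' threshold crossing.  Hfq robustness is `log10(upper / lower)`, the
#' log-fold width of the operating range.  When the curve never reaches the
#' threshold the bounds are undefined and robustness is reported as 0 with
#' `defined = FALSE` (never silently).  A warning is issued when the curve
#' is still above threshold at a grid edge, since the true bound then lies
#' outside the sweep.
#'
#' @param sweep An `hfq_sweep` tibble (or any data frame with columns
#'   `relative_hfq` and `percent_duplex`).
#' @param pair Focal pair, matched against `pair_i`/`pair_j` when present.
#' @param threshold Duplex-formation threshold in percent (default 10).
#' @return A one-row tibble of class `hfq_robustness`: `pair_i`, `pair_j`,
#'   `threshold`, `lower_bound`, `upper_bound`, `robustness`,
#'   `max_percent_duplex`, `defined`.
#' @export
bounds_and_robustness <- function(sweep, pair = c(1L, 1L), threshold = 10) {
  df <- as.data.frame(sweep)
  if (all(c("pair_i", "pair_j") %in% names(df)))
    df <- df[df$pair_i == pair[1] & df$pair_j == pair[2], ]
  df <- df[is.finite(df$relative_hfq) & is.finite(df$percent_duplex), ]
  df <- df[order(df$relative_hfq), ]
  if (nrow(df) == 0L)
    stop("sweep contains no finite points for the requested pair",
         call. = FALSE)

  x <- log10(df$relative_hfq)
  y <- df$percent_duplex
  max_pd <- max(y)

  undefined <- tibble::tibble(
    pair_i = pair[1], pair_j = pair[2], threshold = threshold,
    lower_bound = NA_real_, upper_bound = NA_real_, robustness = 0,
    max_percent_duplex = max_pd, defined = FALSE)

  above <- y >= threshold
  if (!any(above)) {
    out <- undefined
  } else {
    first <- which(above)[1]
    last <- rev(which(above))[1]
    interp <- function(i0, i1) {
      # log-linear interpolation of the crossing between grid points
      if (y[i1] == y[i0]) return(x[i1])
      x[i0] + (threshold - y[i0]) * (x[i1] - x[i0]) / (y[i1] - y[i0])
    }
    lower <- if (first == 1L) {
      warning("duplex curve already at/above threshold at the lower grid edge")
      x[1]
    } else interp(first - 1L, first)
    upper <- if (last == length(y)) {
      warning("duplex curve still at/above threshold at the upper grid edge")
      x[length(y)]
    } else interp(last + 1L, last)
    out <- tibble::tibble(
      pair_i = pair[1], pair_j = pair[2], threshold = threshold,
      lower_bound = 10^lower, upper_bound = 10^upper,
      robustness = upper - lower, max_percent_duplex = max_pd,
      defined = TRUE)
  }
  class(out) <- c("hfq_robustness", class(out))
  out
}
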