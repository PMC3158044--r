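#' Convergence settings for steady-state integration
#'
#' The integrator runs the network from the all-zero state (a cell before
#' induction) over a horizon of `horizon_multiplier` RNA lifetimes (one
#' lifetime is `1/beta`) and declares convergence when the solution at
#' `rel_check_fraction` of the horizon and at the full horizon agree per
#' species to within `tolerance` (absolute) or `rel_tolerance` (relative,
#' which guards regimes whose concentrations are many orders of magnitude
#' above one).  If the check fails, the horizon is doubled up to
#' `max_doublings` times before a failure is reported.
#'
#' @param horizon_multiplier Simulation length in RNA lifetimes
#'   (default 100).
#' @param rel_check_fraction Fraction of the horizon at which the
#'   comparison solution is taken (default 0.9).
#' @param tolerance Absolute per-species convergence tolerance
#'   (default 1e-10).
#' @param rel_tolerance Relative per-species convergence tolerance
#'   (default 1e-8).
#' @param max_doublings Maximum number of horizon doublings (default 6).
#' @param rtol,atol Integrator error tolerances passed to
#'   [deSolve::lsoda()]; the solver must cope with rate constants spanning
#'   ten or more orders of magnitude, hence the stiff default method.
#' @param maxsteps Maximum internal integrator steps per call.
#' @return A list of class `hfq_convergence_config`.
#' @export
convergence_config <- function(horizon_multiplier = 100,
                               rel_check_fraction = 0.9,
                               tolerance = 1e-10,
                               rel_tolerance = 1e-8,
                               max_doublings = 6L,
                               rtol = 1e-8, atol = 1e-12,
                               maxsteps = 50000L) {
  stopifnot(tolerance > 0, rel_tolerance >= 0,
            rel_check_fraction > 0, rel_check_fraction < 1,
            horizon_multiplier > 0)
  structure(list(horizon_multiplier = horizon_multiplier,
                 rel_check_fraction = rel_check_fraction,
                 tolerance = tolerance, rel_tolerance = rel_tolerance,
                 max_doublings = as.integer(max_doublings),
                 rtol = rtol, atol = atol, maxsteps = as.integer(maxsteps)),
            class = "hfq_convergence_config")
}

new_steady_state <- function(net, state, converged, method, horizon = NA_real_,
                             iterations = NA_integer_, message = NULL) {
  state <- pmax(state, 0)
  names(state) <- state_names(net)
  res <- derivatives(net, state)
  structure(list(network = net, state = state,
                 species = unpack_state(net, state),
                 converged = converged, method = method,
                 horizon = horizon, iterations = iterations,
                 residual = max(abs(res)), message = message),
            class = "hfq_steady_state")
}

#' @export
print.hfq_steady_state <- function(x, ...) {
  cat(sprintf("<hfq_steady_state> %s, method = %s, residual = %.3g\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$method, x$residual))
  if (!is.null(x$message)) cat("  ", x$message, "\n")
  cat(sprintf("  free Hfq %.4g; total duplex %.4g\n",
              x$species$H, sum(x$species$D)))
  invisible(x)
}

#' Solve a network to steady state
#'
#' `method = "integrate"` (the reference method) integrates the stiff ODE
#' system from the all-zero state with [deSolve::lsoda()] using the analytic
#' [jacobian()], applying the convergence criterion of
#' [convergence_config()].  `method = "newton"` runs a damped Newton
#' iteration from `init` (or from an integration at loose tolerance when
#' `init` is missing); it is much faster inside parameter sweeps where the
#' previous grid point provides a warm start, and every Newton solution is
#' validated against the mass-action residual and non-negativity.
#'
#' Non-convergence is reported explicitly through the `converged` flag and
#' `message` field of the result, never silently.
#'
#' @param net An [hfq_network()].
#' @param cfg A [convergence_config()].
#' @param method `"integrate"` or `"newton"`.
#' @param init Optional initial state for the Newton method.
#' @return An object of class `hfq_steady_state` with fields `state`
#'   (named vector), `species` (unpacked blocks), `converged`, `method`,
#'   `horizon`, `residual` and `message`.
#' @examples
#' net <- hfq_network(1, 1, alpha_H = 2, alpha_S = 0, alpha_T = 0, beta = 1)
#' steady_state(net)$species$H # alpha_H / beta = 2
#' @export
steady_state <- function(net, cfg = convergence_config(),
                         method = c("integrate", "newton"), init = NULL) {
  stopifnot(inherits(net, "hfq_network"))
  method <- match.arg(method)
  if (method == "integrate") steady_state_integrate(net, cfg)
  else steady_state_newton(net, cfg, init)
}

steady_state_integrate <- function(net, cfg = convergence_config()) {
  N <- state_dimension(net)
  y0 <- rep(0, N)
  func <- function(t, y, p) list(derivatives(net, y))
  jacf <- function(t, y, p) jacobian(net, y)
  horizon <- cfg$horizon_multiplier / net$beta
  xb <- y0

  for (attempt in 0:cfg$max_doublings) {
    times <- c(0, cfg$rel_check_fraction * horizon, horizon)
    sol <- try(deSolve::lsoda(y0, times, func, parms = NULL,
                              jacfunc = jacf, jactype = "fullusr",
                              rtol = cfg$rtol, atol = cfg$atol,
                              maxsteps = cfg$maxsteps), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < 3L) {
      horizon <- horizon * 2
      next
    }
    xa <- sol[2, -1]; xb <- sol[3, -1]
    ok <- abs(xb - xa) <= pmax(cfg$tolerance, cfg$rel_tolerance * abs(xb))
    if (all(ok)) {
      if (min(xb) < -sqrt(cfg$tolerance))
        return(new_steady_state(net, xb, FALSE, "integrate", horizon,
                                message = sprintf(
                                  "negative concentration %.3g beyond tolerance",
                                  min(xb))))
      return(new_steady_state(net, xb, TRUE, "integrate", horizon))
    }
    horizon <- horizon * 2
  }
  new_steady_state(net, xb, FALSE, "integrate", horizon,
                   message = sprintf(
                     "per-species convergence check failed after %d horizon doublings",
                     cfg$max_doublings))
}

steady_state_newton <- function(net, cfg = convergence_config(),
                                init = NULL, max_iter = 60L) {
  if (is.null(init)) {
    rough <- steady_state_integrate(net, cfg)
    init <- rough$state
  }
  x <- pmax(as.numeric(init), 0)
  scale <- max(1, net$alpha_H / net$beta,
               max(net$alpha_S) / net$beta, max(net$alpha_T) / net$beta)
  tol_f <- 1e-11 * scale
  f <- derivatives(net, x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) <= tol_f)
      return(new_steady_state(net, x, TRUE, "newton", iterations = it))
    J <- jacobian(net, x)
    dx <- try(solve(J, -f), silent = TRUE)
    if (inherits(dx, "try-error")) break
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * dx, 0)
      fn <- derivatives(net, xn)
      if (max(abs(fn)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (max(abs(fn)) >= max(abs(f))) break  # stalled; judge residual below
    x <- xn; f <- fn
  }
  if (max(abs(f)) <= 1e-8 * max(1, max(x)))
    return(new_steady_state(net, x, TRUE, "newton", iterations = max_iter))
  new_steady_state(net, x, FALSE, "newton",
                   message = sprintf("Newton stalled at residual %.3g",
                                     max(abs(f))))
}

#' Independent algebraic steady-state oracle
#'
#' Finds a root of the mass-action derivative with a damped
#' Levenberg-Marquardt root-finder ([minpack.lm::nls.lm()]), started from
#' the integrator's answer and from cold starts (the all-zero state and the
#' production/degradation balance point).  Intended as an independent
#' cross-check of [steady_state()] on small systems (`n*m` up to ~9); it
#' shares only the derivative definition with the integrator, not the
#' solution path.
#'
#' @param net An [hfq_network()].
#' @param cfg A [convergence_config()] for the integrator start.
#' @param starts Optional list of additional start vectors.
#' @return An `hfq_steady_state` (method `"oracle"`); `converged = FALSE`
#'   with a message if no start converges.
#' @export
steady_state_oracle <- function(net, cfg = convergence_config(),
                                starts = NULL) {
  if (net$n_srna * net$m_mrna > 9)
    warning("the algebraic oracle is intended for small systems (n*m <= 9)")
  N <- state_dimension(net)
  bal <- pack_state(net,
                    H = net$alpha_H / net$beta,
                    S = net$alpha_S / net$beta,
                    T = net$alpha_T / net$beta)
  cand <- list(steady_state_integrate(net, cfg)$state, bal, rep(0, N))
  if (!is.null(starts)) cand <- c(cand, starts)

  scale <- max(1, net$alpha_H, max(net$alpha_S), max(net$alpha_T)) / net$beta
  best <- NULL
  for (x0 in cand) {
    # per-start failures are expected (cold starts can stall); the winner
    # is judged on its residual below
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = pmax(as.numeric(x0), 0),
      fn = function(p) derivatives(net, p),
      jac = function(p) jacobian(net, p),
      lower = rep(0, N),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000,
                                           ftol = 1e-15, ptol = 1e-15))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    x <- fit$par
    res <- max(abs(derivatives(net, x)))
    if (is.null(best) || res < best$res) best <- list(x = x, res = res)
  }
  if (is.null(best))
    return(new_steady_state(net, rep(0, N), FALSE, "oracle",
                            message = "root-finder failed from every start"))
  converged <- best$res <= 1e-8 * max(1, scale)
  new_steady_state(net, best$x, converged, "oracle",
                   message = if (!converged)
                     sprintf("best residual %.3g did not meet tolerance",
                             best$res))
}

#' Steady-state conservation check
#'
#' At steady state with uniform degradation, total Hfq obeys
#' `beta * (H + sum(HS) + sum(HT) + sum(HST)) = alpha_H`, and each sRNA and
#' mRNA lineage obeys the analogous identity including its ternary and
#' duplex rows/columns.  With `beta_overrides` the identity generalises to
#' the sum of `beta_species * concentration` over the lineage.
#'
#' @param ss An `hfq_steady_state`.
#' @return A tibble with one row per lineage (`hfq`, `srna` i, `mrna` j):
#'   production rate, total degradation flux, and their relative error.
#' @export
conservation_check <- function(ss) {
  stopifnot(inherits(ss, "hfq_steady_state"))
  net <- ss$network
  n <- net$n_srna; m <- net$m_mrna
  bv <- beta_vector(net)
  flux <- bv * ss$state
  fl <- unpack_state(net, flux)
  rows <- list(
    tibble::tibble(lineage = "hfq", index = NA_integer_,
                   production = net$alpha_H,
                   degradation_flux = fl$H + sum(fl$HS) + sum(fl$HT) +
                     sum(fl$HST)),
    tibble::tibble(lineage = "srna", index = seq_len(n),
                   production = net$alpha_S,
                   degradation_flux = fl$S + fl$HS + rowSums(fl$HST) +
                     rowSums(fl$D)),
    tibble::tibble(lineage = "mrna", index = seq_len(m),
                   production = net$alpha_T,
                   degradation_flux = fl$T + fl$HT + colSums(fl$HST) +
                     colSums(fl$D))
  )
  out <- dplyr::bind_rows(rows)
  out$rel_error <- abs(out$degradation_flux - out$production) /
    pmax(out$production, .Machine$double.xmin)
  out
}
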