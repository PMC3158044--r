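#' Serialize a network to a declarative configuration list
#'
#' The configuration is a flat keyed structure suitable for YAML: scalars,
#' vectors, and matrices as lists of rows.  Matrices whose diagonal and
#' off-diagonal entries are each constant are compacted to the
#' `(diagonal, offdiagonal)` shorthand used by single-partner networks.
#'
#' @param net An [hfq_network()].
#' @return A named list.
#' @export
network_to_config <- function(net) {
  stopifnot(inherits(net, "hfq_network"))
  mat_out <- function(x) {
    n <- nrow(x); m <- ncol(x)
    d <- diag(x)[seq_len(min(n, m))]
    off <- x[row(x) != col(x)]
    if (length(unique(d)) == 1L &&
        (length(off) == 0L || length(unique(off)) == 1L)) {
      list(diagonal = unname(d[1]),
           offdiagonal = if (length(off)) unname(off[1]) else unname(d[1]))
    } else {
      lapply(seq_len(n), function(i) unname(x[i, ]))
    }
  }
  cfg <- list(
    n_srna = net$n_srna, m_mrna = net$m_mrna,
    alpha_H = net$alpha_H, alpha_S = net$alpha_S, alpha_T = net$alpha_T,
    beta = net$beta,
    k1 = net$k1, kneg1 = net$kneg1, k2 = net$k2, kneg2 = net$kneg2,
    k3 = mat_out(net$k3), kneg3 = mat_out(net$kneg3),
    k4 = mat_out(net$k4), kneg4 = mat_out(net$kneg4),
    k5 = mat_out(net$k5))
  if (!is.null(net$beta_overrides))
    cfg$beta_overrides <- net$beta_overrides
  cfg
}

config_mat_in <- function(x, n, m, key) {
  if (is.list(x) && !is.null(names(x)) &&
      all(c("diagonal", "offdiagonal") %in% names(x))) {
    out <- matrix(x$offdiagonal, n, m)
    diag_len <- min(n, m)
    out[cbind(seq_len(diag_len), seq_len(diag_len))] <- x$diagonal
    return(out)
  }
  if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
  if (is.null(dim(x)) && length(x) == 1L) return(matrix(x, n, m))
  x <- as.matrix(x)
  if (!all(dim(x) == c(n, m)))
    stop(sprintf("config key `%s`: expected a %d x %d matrix or a (diagonal, offdiagonal) shorthand",
                 key, n, m), call. = FALSE)
  x
}

#' Build a network from a configuration list
#'
#' Accepts either a full kinetic specification (the output of
#' [network_to_config()]) or a regime reference of the form
#' `list(regime = "<name>", <regime parameters>)` which is expanded through
#' [build_scheme()] at load time.  Unknown keys are rejected by name.
#'
#' @param cfg A named list (e.g. parsed from YAML).
#' @return An [hfq_network()].
#' @export
network_from_config <- function(cfg) {
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("network config must be a named list", call. = FALSE)
  if (!is.null(cfg$regime)) {
    args <- cfg[setdiff(names(cfg), "regime")]
    return(do.call(build_scheme, c(list(regime = cfg$regime), args)))
  }
  known <- c("n_srna", "m_mrna", "alpha_H", "alpha_S", "alpha_T", "beta",
             "k1", "kneg1", "k2", "kneg2", "k3", "kneg3", "k4", "kneg4",
             "k5", "beta_overrides")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown network config keys: ",
         paste0("network.", bad, collapse = ", "), call. = FALSE)
  need <- c("n_srna", "m_mrna")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("network config is missing required keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- as.integer(cfg$n_srna); m <- as.integer(cfg$m_mrna)
  args <- cfg
  for (key in c("k3", "kneg3", "k4", "kneg4", "k5"))
    if (!is.null(cfg[[key]])) args[[key]] <- config_mat_in(cfg[[key]], n, m, key)
  for (key in setdiff(known, c("n_srna", "m_mrna", "beta_overrides",
                               "k3", "kneg3", "k4", "kneg4", "k5")))
    if (!is.null(args[[key]])) args[[key]] <- unlist(args[[key]])
  do.call(hfq_network, args)
}

#' Read and write network configurations as YAML
#'
#' @param path File path.
#' @param net An [hfq_network()].
#' @return `read_network_config()` returns an [hfq_network()];
#'   `write_network_config()` returns `path` invisibly.
#' @export
read_network_config <- function(path) {
  network_from_config(yaml::read_yaml(path))
}

#' @rdname read_network_config
#' @export
write_network_config <- function(net, path) {
  yaml::write_yaml(network_to_config(net), path, precision = 15)
  invisible(path)
}

#' Load a full run configuration
#'
#' A run configuration is a YAML document with keys:
#' `network` (a kinetic specification or regime reference, required),
#' `grid` (`from`, `to`, `points_per_decade`), `convergence` (any
#' [convergence_config()] field), `pairs` (list of `[i, j]` focal pairs)
#' and `threshold` (percent duplex).  Unknown keys are rejected with their
#' location.
#'
#' @param path YAML file path.
#' @return A list of class `hfq_run_config` with elements `network`,
#'   `grid`, `cfg`, `pairs`, `threshold`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("network", "grid", "convergence", "pairs", "threshold")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown run config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$network))
    stop("run config requires a `network` entry", call. = FALSE)
  net <- network_from_config(raw$network)

  g <- raw$grid %||% list()
  badg <- setdiff(names(g), c("from", "to", "points_per_decade"))
  if (length(badg))
    stop("unknown run config keys: ", paste0("grid.", badg, collapse = ", "),
         call. = FALSE)
  grid <- alpha_H_grid(g$from %||% 1e-5, g$to %||% 1e7,
                       g$points_per_decade %||% 10)

  cv <- raw$convergence %||% list()
  badc <- setdiff(names(cv), names(formals(convergence_config)))
  if (length(badc))
    stop("unknown run config keys: ",
         paste0("convergence.", badc, collapse = ", "), call. = FALSE)
  cfg <- do.call(convergence_config, cv)

  pairs <- raw$pairs %||% list(c(1L, 1L))
  pairs <- lapply(pairs, function(p) {
    p <- as.integer(unlist(p))
    if (length(p) != 2L || anyNA(p))
      stop("run config key `pairs`: each entry must be an [i, j] pair",
           call. = FALSE)
    p
  })
  structure(list(network = net, grid = grid, cfg = cfg, pairs = pairs,
                 threshold = raw$threshold %||% 10),
            class = "hfq_run_config")
}

#' Write sweep and robustness results to disk
#'
#' Writes tidy CSV files (one observation per row, stable documented
#' columns) plus a versioned JSON bundle.  `results` may be a single
#' `hfq_sweep`, a single `hfq_robustness`, or the list returned by
#' [run_scenario()].
#'
#' @param results Result object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"hfqnet"`).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir, prefix = "hfqnet") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  emit_csv <- function(df, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".csv"))
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    paths <<- c(paths, p)
    df
  }
  bundle <- list(schema = "hfqnet/results/v1")
  if (inherits(results, "hfq_sweep")) {
    bundle$sweep <- emit_csv(results, "sweep")
  } else if (inherits(results, "hfq_robustness")) {
    bundle$summary <- emit_csv(results, "robustness")
  } else if (is.list(results) &&
             all(c("sweeps", "summaries") %in% names(results))) {
    bundle$sweep <- emit_csv(results$sweeps, "sweep")
    bundle$summary <- emit_csv(results$summaries, "robustness")
  } else {
    stop("unsupported results object", call. = FALSE)
  }
  pj <- file.path(dir, paste0(prefix, "_results.json"))
  jsonlite::write_json(bundle, pj, dataframe = "columns", digits = NA,
                       na = "null")
  paths <- c(paths, pj)
  invisible(paths)
}

#' Read a sweep back from its CSV serialization
#'
#' @param path CSV path written by [write_results()].
#' @return An `hfq_sweep` tibble (without the template network attribute).
#' @export
read_sweep_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  class(df) <- c("hfq_sweep", class(df))
  df
}
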