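# Graph input/output, fixtures, pipeline configuration and the top-level
# inference driver.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the inference pipeline. Defaults follow
#' the method's standard protocol: 50 surrogates per dimension, a clustering
#' window of half-width 0.1, hidden-degree tolerance 1, a dimension cap of 12,
#' odd K values up to 25, and a 20-network `beta ~ U(1, 15)` calibration
#' sample at `D = 1`.
#'
#' @param seed master integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param n_surrogates_per_dim surrogates generated per candidate dimension.
#' @param delta_ct half-width of the edge-clustering window sampled around the
#'   observed value.
#' @param tolerance_epsilon convergence tolerance of hidden-degree inference
#'   (degree units).
#' @param d_cap hard cap on the dimensions scanned.
#' @param k_grid candidate neighbor counts for [optimize_k()].
#' @param refine_mu whether experiment drivers refine `mu` on the realized
#'   expected degree.
#' @param n_reals_dmax realizations per dimension inside
#'   [estimate_max_dimension()].
#' @param calib_n,calib_beta_range size and beta range of the `D = 1`
#'   calibration sample.
#' @param max_iter sweep cap of hidden-degree inference.
#' @return A list of class `"netdim_config"`.
#' @export
netdim_config <- function(seed = NULL, n_surrogates_per_dim = 50L,
                          delta_ct = 0.1, tolerance_epsilon = 1,
                          d_cap = 12L, k_grid = seq(1L, 25L, by = 2L),
                          refine_mu = TRUE, n_reals_dmax = 10L,
                          calib_n = 20L, calib_beta_range = c(1, 15),
                          max_iter = 200L) {
  cfg <- list(
    seed = if (is.null(seed)) NULL else check_count(seed, "seed", min = 0L),
    n_surrogates_per_dim = check_count(n_surrogates_per_dim,
                                       "n_surrogates_per_dim"),
    delta_ct = check_positive(delta_ct, "delta_ct"),
    tolerance_epsilon = check_positive(tolerance_epsilon, "tolerance_epsilon"),
    d_cap = check_count(d_cap, "d_cap"),
    k_grid = sort(unique(as.integer(k_grid))),
    refine_mu = isTRUE(refine_mu),
    n_reals_dmax = check_count(n_reals_dmax, "n_reals_dmax"),
    calib_n = check_count(calib_n, "calib_n", min = 5L),
    calib_beta_range = as.numeric(calib_beta_range),
    max_iter = check_count(max_iter, "max_iter")
  )
  structure(cfg, class = "netdim_config")
}

#' Read a graph from a whitespace-separated edge list
#'
#' Each non-comment line names two endpoints (arbitrary string labels);
#' lines starting with `#` are ignored. Self-loops and duplicate edges are
#' dropped with a message; labels are mapped to consecutive integers and kept
#' as vertex names.
#'
#' @param path file path.
#' @return A simple undirected `igraph` graph with the original labels in
#'   `V(g)$name`; attributes `n_selfloops` / `n_duplicates` record dropped
#'   lines.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty edge list: ", path, call. = FALSE)
  tokens <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(tokens) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("malformed edge list line %d in %s: %s",
                 lineno[bad[1]], path, lines[bad[1]]), call. = FALSE)
  }
  ends <- matrix(unlist(tokens), ncol = 2, byrow = TRUE)
  labels <- sort(unique(as.vector(ends)))
  a <- match(ends[, 1], labels)
  b <- match(ends[, 2], labels)
  self <- a == b
  n_self <- sum(self)
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  dup <- duplicated(cbind(a2, b2))
  n_dup <- sum(dup)
  if (n_self + n_dup > 0) {
    message(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  }
  if (sum(!dup) == 0) stop("no edges left after cleaning: ", path, call. = FALSE)
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::add_edges(g, rbind(a2[!dup], b2[!dup]))
  igraph::V(g)$name <- labels
  g$n_selfloops <- n_self
  g$n_duplicates <- n_dup
  g
}

#' Write a graph as a two-column edge list
#'
#' @param graph an `igraph` graph; vertex names (or 1-based indices) become
#'   the labels.
#' @param path output file path.
#' @param kappa_path optional path for a CSV sidecar of per-node hidden
#'   degrees and position coordinates (written when the graph carries them).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, kappa_path = NULL) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  if (!is.null(kappa_path)) {
    df <- data.frame(node = igraph::V(graph)$name)
    if (!is.null(igraph::V(graph)$kappa)) df$kappa <- igraph::V(graph)$kappa
    pos <- graph$positions
    if (!is.null(pos)) {
      colnames(pos) <- paste0("x", seq_len(ncol(pos)))
      df <- cbind(df, pos)
    }
    utils::write.csv(df, kappa_path, row.names = FALSE)
  }
  invisible(path)
}

#' Deterministic toy graphs for cycle-census checks
#'
#' @param name one of `"cycle4"`, `"cycle5"`, `"complete4"`, `"wheel5"`
#'   (a hub joined to a 4-cycle rim), `"petersen"`, `"er"` (Erdős–Rényi
#'   `G(n, p)`).
#' @param n,p order and edge probability for `"er"`.
#' @param seed integer seed for `"er"`.
#' @return An `igraph` graph.
#' @export
make_fixture <- function(name = c("cycle4", "cycle5", "complete4", "wheel5",
                                  "petersen", "er"),
                         n = 30L, p = 0.2, seed = NULL) {
  name <- match.arg(name)
  switch(
    name,
    cycle4 = igraph::make_ring(4),
    cycle5 = igraph::make_ring(5),
    complete4 = igraph::make_full_graph(4),
    wheel5 = igraph::add_edges(igraph::make_ring(4) + igraph::vertices(1),
                               c(5, 1, 5, 2, 5, 3, 5, 4)),
    petersen = igraph::make_graph("Petersen"),
    er = with_seed(seed, igraph::sample_gnp(n, p))
  )
}

#' Run the full dimensionality-inference pipeline
#'
#' Orchestrates the method end to end: read and clean the graph, measure its
#' chordless-cycle phase point, bound and calibrate the candidate dimensions,
#' build the surrogate ensemble, select `K`, classify, and attach the
#' leave-one-out classifier accuracy. A triangle-free input (clustering the
#' model cannot reach in any dimension) exits early with `D_star = 1` and an
#' anomalous flag.
#'
#' @param x an `igraph` graph or a path to an edge-list file.
#' @param config a [netdim_config()].
#' @param output optional path; when given, the result (including every seed
#'   and parameter used) is written there as JSON.
#' @return An object of class `"netdim_result"`: `D_star`, `f`, `K`,
#'   `accuracy`, `D_max`, `anomalous`, the observed `phase`, an `ensemble`
#'   summary data frame, and the `config` used.
#' @export
run_pipeline <- function(x, config = netdim_config(), output = NULL) {
  g <- if (igraph::is_igraph(x)) x else read_edge_list(x)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  }
  iso <- which(igraph::degree(g) == 0)
  if (length(iso) > 0) {
    warning(sprintf("dropping %d isolated node(s)", length(iso)), call. = FALSE)
    g <- igraph::delete_vertices(g, iso)
  }
  if (igraph::vcount(g) < 3) stop("graph too small", call. = FALSE)
  pp <- phase_point(g)

  if (pp$C_t <= 0) {
    res <- structure(
      list(D_star = 1L, f = c(`1` = 1), K = NA_integer_,
           accuracy = NA_real_, D_max = NA_integer_, anomalous = TRUE,
           phase = pp, ensemble = NULL, config = config),
      class = "netdim_result")
  } else {
    ens <- build_surrogate_ensemble(g, config = config, seed = config$seed)
    K <- optimize_k(ens, k_grid = config$k_grid)
    est <- classify_dimension(pp, ens, K)
    est$accuracy <- attr(K, "accuracy_by_k")[[as.character(K)]]
    res <- structure(
      list(D_star = est$D_star, f = est$f, K = as.integer(K),
           accuracy = est$accuracy, D_max = attr(ens, "D_max"),
           anomalous = isTRUE(attr(ens, "anomalous")),
           phase = pp, ensemble = as.data.frame(ens), config = config),
      class = "netdim_result")
  }
  if (!is.null(output)) {
    report <- list(
      schema = "netdim-report/1",
      D_star = res$D_star, f = as.list(res$f), K = res$K,
      accuracy = res$accuracy, D_max = res$D_max, anomalous = res$anomalous,
      phase = res$phase[c("C_t", "C_s", "C_p", "C")],
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
      config = unclass(config),
      ensemble_size = if (is.null(res$ensemble)) 0L else nrow(res$ensemble)
    )
    jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  res
}

#' @export
print.netdim_result <- function(x, ...) {
  cat(sprintf("netdim: D* = %d%s\n", x$D_star,
              if (x$anomalous) " (anomalous cycle statistics)" else ""))
  cat(sprintf("  phase point: C_t = %.4f, C_s = %.4f, C_p = %.4f\n",
              x$phase$C_t, x$phase$C_s, x$phase$C_p))
  if (!is.na(x$accuracy)) {
    cat(sprintf("  K = %d, classifier accuracy = %.3f, D_max = %d, ensemble = %d surrogates\n",
                x$K, x$accuracy, x$D_max, nrow(x$ensemble)))
  }
  cat("  f(D):", paste(sprintf("%s: %.3f", names(x$f), x$f), collapse = ", "),
      "\n")
  invisible(x)
}
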