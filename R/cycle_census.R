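# Chordless-cycle census and phase-space coordinates.
#
# A chordless cycle induces no edge beyond its own: every chord disqualifies
# it. The classifier features are the per-edge densities of chordless
# triangles (C_t), squares (C_s) and pentagons (C_p): each edge's count is
# divided by the maximum compatible with the end degrees, discounting the
# neighbors already used by shorter cycles, then averaged over edges whose
# endpoints both have degree > 1 and whose denominator is positive.

edge_matrix0 <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  el - 1L
}

#' Per-edge chordless-cycle census of a graph
#'
#' Counts, for every edge, the triangles, chordless squares and chordless
#' pentagons passing through it, together with the end degrees, the number
#' `pentagon_pairs` of distinct end-neighbor pairs joined by a chordless
#' 2-path (the pentagon anchor pairs entering [phase_point()]'s density), and
#' the numbers `s_i`, `s_j` of distinct end-neighbors matched in chordless
#' squares.
#'
#' @param graph a simple undirected `igraph` graph.
#' @param max_len longest cycle to census: 3 (triangles only), 4, or 5
#'   (default). Truncating is much faster when only edge clustering is needed.
#' @return A data frame with one row per edge: `from`, `to` (vertex indices,
#'   1-based), `deg_i`, `deg_j`, `triangles`, `squares`, `pentagons`,
#'   `pentagon_pairs`, `s_i`, `s_j`. Counts are symmetric in the edge
#'   orientation.
#' @export
edge_cycle_census <- function(graph, max_len = 5L) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) {
    stop("`graph` must be undirected", call. = FALSE)
  }
  if (!igraph::is_simple(graph)) {
    stop("`graph` must be simple (no loops or multi-edges); see read_edge_list()",
         call. = FALSE)
  }
  max_len <- check_count(max_len, "max_len", min = 3L)
  el <- edge_matrix0(graph)
  res <- edge_cycle_counts_cpp(igraph::vcount(graph), el, max_len)
  data.frame(from = el[, 1] + 1L, to = el[, 2] + 1L, res)
}

census_one_edge <- function(graph, edge, col) {
  stopifnot(length(edge) == 2L)
  ids <- if (is.character(edge)) {
    match(edge, igraph::V(graph)$name)
  } else {
    as.integer(edge)
  }
  eid <- igraph::get_edge_ids(graph, ids, error = FALSE)
  if (is.na(eid) || eid == 0) {
    stop("edge not present in `graph`", call. = FALSE)
  }
  cc <- edge_cycle_census(graph, max_len = if (col == "triangles") 3L else 5L)
  cc[[col]][eid]
}

#' Triangles through one edge
#'
#' `|N(i)` \eqn{\cap} `N(j)|` for an edge `(i, j)`.
#'
#' @param graph a simple undirected `igraph` graph.
#' @param edge a length-2 vector of vertex ids or names.
#' @return A non-negative integer count.
#' @export
edge_triangle_count <- function(graph, edge) {
  census_one_edge(graph, edge, "triangles")
}

#' Chordless squares through one edge
#' @inheritParams edge_triangle_count
#' @return A non-negative integer count.
#' @export
edge_chordless_square_count <- function(graph, edge) {
  census_one_edge(graph, edge, "squares")
}

#' Chordless pentagons through one edge
#' @inheritParams edge_triangle_count
#' @return A non-negative integer count.
#' @export
edge_chordless_pentagon_count <- function(graph, edge) {
  census_one_edge(graph, edge, "pentagons")
}

#' Cycle-density phase-space coordinates of a graph
#'
#' Computes the mean per-edge densities of chordless triangles, squares and
#' pentagons, plus the average local node clustering. Per edge `(i, j)` with
#' degrees `k_i`, `k_j`, `T` triangles and `S` chordless squares, the
#' densities divide by the maximum number compatible with the end degrees,
#' discounting neighbors consumed by shorter cycles:
#' \itemize{
#'   \item triangles: `T / (min(k_i, k_j) - 1)`;
#'   \item squares: `S / m_s` with `m_s = (k_i - 1 - T) * (k_j - 1 - T)` —
#'     each chordless square pairs one non-common, non-endpoint neighbor from
#'     each side, and common neighbors (triangles) are discounted;
#'   \item pentagons: `P_pairs / (m_s - S)`, where `P_pairs` counts the
#'     distinct end-neighbor pairs `(a, b)` joined by at least one chordless
#'     2-path (each such pair anchors the pentagons through the edge) and the
#'     maximum discounts both triangles (via `m_s`) and the pairs already
#'     adjacent, i.e. consumed by squares (`- S`). Counting pairs rather than
#'     raw pentagons keeps the density in `[0, 1]`: several pentagons can
#'     share one end pair through different middle vertices, so no pair-based
#'     maximum bounds the raw count.
#' }
#' An edge enters an average only when both end degrees exceed 1 and the
#' corresponding denominator is positive. Node clustering `C` averages the
#' local clustering coefficient over nodes of degree at least 2.
#'
#' @param graph a simple undirected `igraph` graph.
#' @param max_len longest cycle to include (see [edge_cycle_census()]);
#'   truncated censuses report 0 for the omitted densities.
#' @return An object of class `"phase_point"`: a list with `C_t`, `C_s`,
#'   `C_p`, `C`, `n_edges_eligible` (named count per cycle length) and
#'   `no_eligible_edges` flag.
#' @export
phase_point <- function(graph, max_len = 5L) {
  cc <- edge_cycle_census(graph, max_len = max_len)
  ki <- cc$deg_i
  kj <- cc$deg_j
  deg_ok <- ki > 1 & kj > 1

  m_t <- pmin(ki, kj) - 1
  el_t <- deg_ok & m_t > 0
  C_t <- if (any(el_t)) mean(cc$triangles[el_t] / m_t[el_t]) else 0

  m_s <- (ki - 1 - cc$triangles) * (kj - 1 - cc$triangles)
  el_s <- deg_ok & m_s > 0
  C_s <- if (max_len >= 4 && any(el_s)) mean(cc$squares[el_s] / m_s[el_s]) else 0

  m_p <- m_s - cc$squares
  el_p <- deg_ok & m_p > 0
  C_p <- if (max_len >= 5 && any(el_p)) {
    mean(cc$pentagon_pairs[el_p] / m_p[el_p])
  } else 0

  lc <- igraph::transitivity(graph, type = "local", isolates = "NaN")
  deg <- igraph::degree(graph)
  C <- if (any(deg >= 2)) mean(lc[deg >= 2], na.rm = TRUE) else 0

  n_el <- c(triangles = sum(el_t), squares = sum(el_s), pentagons = sum(el_p))
  no_eligible <- !any(el_t)
  if (no_eligible) {
    warning("no eligible edges (all end degrees <= 1); densities reported as 0",
            call. = FALSE)
  }
  structure(
    list(C_t = C_t, C_s = C_s, C_p = C_p, C = C,
         n_edges_eligible = n_el, no_eligible_edges = no_eligible),
    class = "phase_point"
  )
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("phase point: C_t = %.4f, C_s = %.4f, C_p = %.4f (C = %.4f)\n",
              x$C_t, x$C_s, x$C_p, x$C))
  cat(sprintf("eligible edges: %d / %d / %d (triangles / squares / pentagons)\n",
              x$n_edges_eligible[1], x$n_edges_eligible[2],
              x$n_edges_eligible[3]))
  invisible(x)
}

# Densities + node clustering computed straight from the census list of
# edge_cycle_counts_cpp (no igraph object). `n` is the vertex count; `el0`
# the 0-based edge matrix the census was computed from.
phase_from_census <- function(cc, n, el0, max_len = 5L) {
  ki <- cc$deg_i
  kj <- cc$deg_j
  deg_ok <- ki > 1 & kj > 1

  m_t <- pmin(ki, kj) - 1
  el_t <- deg_ok & m_t > 0
  C_t <- if (any(el_t)) mean(cc$triangles[el_t] / m_t[el_t]) else 0

  m_s <- (ki - 1 - cc$triangles) * (kj - 1 - cc$triangles)
  el_s <- deg_ok & m_s > 0
  C_s <- if (max_len >= 4 && any(el_s)) mean(cc$squares[el_s] / m_s[el_s]) else 0

  m_p <- m_s - cc$squares
  el_p <- deg_ok & m_p > 0
  C_p <- if (max_len >= 5 && any(el_p)) {
    mean(cc$pentagon_pairs[el_p] / m_p[el_p])
  } else 0

  # local node clustering from the edge census: the triangles through the
  # edges at node i count each of i's triangles twice
  ends <- c(el0[, 1], el0[, 2]) + 1L
  deg <- tabulate(ends, nbins = n)
  tri_node <- (tabulate(rep(el0[, 1] + 1L, cc$triangles), nbins = n) +
                 tabulate(rep(el0[, 2] + 1L, cc$triangles), nbins = n)) / 2
  el2 <- deg >= 2
  C <- if (any(el2)) mean(tri_node[el2] / choose(deg[el2], 2)) else 0

  n_el <- c(triangles = sum(el_t), squares = sum(el_s), pentagons = sum(el_p))
  structure(
    list(C_t = C_t, C_s = C_s, C_p = C_p, C = C,
         n_edges_eligible = n_el, no_eligible_edges = !any(el_t),
         k_mean = mean(deg)),
    class = "phase_point"
  )
}

# Fast surrogate phase point: generate an S^D edge set and census it without
# building a graph object. Same draw sequence as generate_sd_network with
# the same seed (positions are consumed first, then pair uniforms).
sd_phase_point <- function(params, kappas, seed = NULL, max_len = 5L,
                           refine = FALSE) {
  with_seed(seed, {
    positions <- sample_positions(params$N, params$D)
    mu <- if (refine) refine_mu(params, kappas) else params$mu
    el <- generate_edges_cpp(positions, kappas, params$R, mu,
                             if (is.infinite(params$beta)) -1 else params$beta,
                             params$D, is.infinite(params$beta))
    cc <- edge_cycle_counts_cpp(params$N, el, max_len)
    phase_from_census(cc, params$N, el, max_len = max_len)
  })
}

phase_vector <- function(x) {
  if (inherits(x, "phase_point")) {
    c(x$C_t, x$C_s, x$C_p)
  } else if (is.numeric(x) && length(x) >= 3) {
    as.numeric(x[1:3])
  } else {
    stop("expected a phase_point or a numeric (C_t, C_s, C_p) vector",
         call. = FALSE)
  }
}
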