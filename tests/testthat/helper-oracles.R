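# Independent brute-force oracles used to pin down the fast kernels.

adj_matrix <- function(graph) {
  as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
}

# Exhaustive per-edge triangle count: scan all 3-subsets containing the edge.
brute_edge_triangles <- function(graph, i, j) {
  A <- adj_matrix(graph)
  n <- nrow(A)
  sum(vapply(setdiff(seq_len(n), c(i, j)),
             function(c) A[i, c] == 1 && A[j, c] == 1, logical(1)))
}

# TRUE when `vs` (in cyclic order) induces a chordless cycle in A.
is_chordless_cycle <- function(A, vs) {
  L <- length(vs)
  ring <- cbind(vs, vs[c(2:L, 1)])
  if (any(A[ring] != 1)) return(FALSE)
  pairs <- utils::combn(vs, 2)
  n_edges <- sum(A[t(pairs)] == 1)
  n_edges == L  # no edge beyond the L cycle edges
}

# All chordless cycles of length L through edge (i, j), by scanning every
# L-subset containing both endpoints and every distinct cyclic arrangement.
brute_edge_chordless_cycles <- function(graph, i, j, L) {
  A <- adj_matrix(graph)
  n <- nrow(A)
  others <- setdiff(seq_len(n), c(i, j))
  if (length(others) < L - 2) return(0L)
  count <- 0L
  subs <- utils::combn(others, L - 2)
  for (s in seq_len(ncol(subs))) {
    mids <- subs[, s]
    # each cycle through (i, j) is the unique path i -> middles -> j plus the
    # closing edge, so every valid middle arrangement is a distinct cycle
    perms <- all_permutations(mids)
    for (p in seq_len(nrow(perms))) {
      vs <- c(i, perms[p, ], j)
      if (is_chordless_cycle(A, vs)) count <- count + 1L
    }
  }
  count
}

all_permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- list()
  for (k in seq_along(x)) {
    rest <- all_permutations(x[-k])
    out[[k]] <- cbind(x[k], rest)
  }
  do.call(rbind, out)
}

# Independent distance-weighted K-NN vote (direct transcription).
brute_knn_f <- function(x, feat, labels, K) {
  d <- apply(feat, 1, function(r) sqrt(sum((r - x)^2)))
  ord <- order(d)[seq_len(K)]
  dk <- d[ord]
  w <- if (any(dk == 0)) as.numeric(dk == 0) else 1 / dk
  w <- w / sum(w)
  lev <- sort(unique(labels))
  stats::setNames(vapply(lev, function(D) sum(w[labels[ord] == D]),
                         numeric(1)), lev)
}
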