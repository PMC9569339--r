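# Chordless-cycle census: named fixtures with known counts, brute-force
# oracle equivalence on random graphs, and the normalization rules.

test_that("named fixtures have their known per-edge counts and densities", {
  c4 <- make_fixture("cycle4")
  expect_equal(edge_triangle_count(c4, c(1, 2)), 0)
  expect_equal(edge_chordless_square_count(c4, c(1, 2)), 1)
  pp4 <- phase_point(c4)
  expect_equal(c(pp4$C_t, pp4$C_s, pp4$C_p), c(0, 1, 0))

  c5 <- make_fixture("cycle5")
  expect_equal(edge_chordless_pentagon_count(c5, c(1, 2)), 1)
  pp5 <- phase_point(c5)
  expect_equal(c(pp5$C_t, pp5$C_s, pp5$C_p), c(0, 0, 1))

  k4 <- make_fixture("complete4")
  expect_equal(edge_triangle_count(k4, c(1, 2)), 2)
  expect_equal(edge_chordless_square_count(k4, c(1, 2)), 0)
  expect_equal(phase_point(k4)$C_t, 1)
  # K_n: every edge has n - 2 triangles over denominator n - 2
  k7 <- igraph::make_full_graph(7)
  expect_equal(phase_point(k7)$C_t, 1)
  expect_equal(phase_point(k7)$C_s, 0)

  w5 <- make_fixture("wheel5")
  cc <- edge_cycle_census(w5)
  expect_true(all(cc$pentagons == 0))  # the hub chords every 5-cycle

  pet <- make_fixture("petersen")
  expect_equal(igraph::vcount(pet), 10)
  expect_equal(igraph::ecount(pet), 15)
  ppp <- phase_point(pet)
  expect_equal(c(ppp$C_t, ppp$C_s), c(0, 0))  # girth 5
  expect_gt(ppp$C_p, 0)
  # each Petersen edge lies on 4 of the 12 pentagons, all chordless
  expect_equal(edge_chordless_pentagon_count(pet, c(1, 2)), 4)
})

test_that("census equals exhaustive subset enumeration on random graphs", {
  set.seed(20)
  specs <- data.frame(n = sample(8:14, 50, replace = TRUE),
                      p = stats::runif(50, 0.15, 0.45))
  for (r in seq_len(nrow(specs))) {
    g <- make_fixture("er", n = specs$n[r], p = specs$p[r], seed = 7000 + r)
    if (igraph::ecount(g) == 0) next
    cc <- edge_cycle_census(g)
    for (e in seq_len(min(nrow(cc), 8))) {  # a few edges per graph
      i <- cc$from[e]; j <- cc$to[e]
      expect_equal(cc$triangles[e], brute_edge_triangles(g, i, j),
                   info = sprintf("triangles graph %d edge %d-%d", r, i, j))
      expect_equal(cc$squares[e], brute_edge_chordless_cycles(g, i, j, 4),
                   info = sprintf("squares graph %d edge %d-%d", r, i, j))
      expect_equal(cc$pentagons[e], brute_edge_chordless_cycles(g, i, j, 5),
                   info = sprintf("pentagons graph %d edge %d-%d", r, i, j))
    }
  }
  # a couple of larger sparser graphs for triangles and squares
  for (r in 1:3) {
    g <- make_fixture("er", n = 40, p = 0.08, seed = 8100 + r)
    cc <- edge_cycle_census(g)
    for (e in seq_len(min(nrow(cc), 5))) {
      i <- cc$from[e]; j <- cc$to[e]
      expect_equal(cc$triangles[e], brute_edge_triangles(g, i, j))
      expect_equal(cc$squares[e], brute_edge_chordless_cycles(g, i, j, 4))
    }
  }
})

test_that("counts are symmetric in the edge orientation", {
  g <- make_fixture("er", n = 25, p = 0.25, seed = 31)
  cc <- edge_cycle_census(g)
  grev <- igraph::graph_from_edgelist(
    igraph::as_edgelist(g, names = FALSE)[, 2:1], directed = FALSE)
  ccr <- edge_cycle_census(grev)
  expect_equal(cc$triangles, ccr$triangles)
  expect_equal(cc$squares, ccr$squares)
  expect_equal(cc$pentagons, ccr$pentagons)
})

test_that("densities are normalized into [0, 1] and respect eligibility", {
  for (r in 1:10) {
    g <- make_fixture("er", n = 40, p = 0.12, seed = 400 + r)
    pp <- suppressWarnings(phase_point(g))
    expect_true(all(c(pp$C_t, pp$C_s, pp$C_p, pp$C) >= 0))
    expect_true(all(c(pp$C_t, pp$C_s, pp$C_p, pp$C) <= 1))
  }
  # a path has no cycles at all: all densities exactly 0
  path <- igraph::make_ring(6, circular = FALSE)
  pp <- phase_point(path)
  expect_equal(c(pp$C_t, pp$C_s, pp$C_p), c(0, 0, 0))
  # star: every edge touches a degree-1 endpoint, so nothing is eligible
  star <- igraph::make_star(6, mode = "undirected")
  expect_warning(pps <- phase_point(star), "eligible")
  expect_equal(c(pps$C_t, pps$C_s, pps$C_p), c(0, 0, 0))
  expect_true(pps$no_eligible_edges)
})

test_that("errors are raised for missing edges and non-simple graphs", {
  g <- make_fixture("cycle4")
  expect_error(edge_triangle_count(g, c(1, 3)), "edge")
  multi <- igraph::graph_from_edgelist(rbind(c(1, 2), c(1, 2), c(2, 3)),
                                       directed = FALSE)
  expect_error(edge_cycle_census(multi), "simple")
})
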