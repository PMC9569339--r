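# Hidden-degree inference: the expected-degree integral against Monte Carlo,
# and the fixed-point iteration's convergence and round-trip fidelity.

test_that("equal hidden degrees give equal expected degrees, saturating at N - 1", {
  params <- sd_params(N = 50, D = 2, beta = 4, mean_degree = 5)
  tab <- data.frame(k = 5, kappa = 5, multiplicity = 50)
  ed <- expected_degree(c(5, 5), tab, params)
  expect_equal(ed[1], ed[2])
  # kappa product so large the threshold angle exceeds pi: everyone connects
  pinf <- sd_params(N = 50, D = 1, beta = Inf, mean_degree = 5)
  big <- pi * pinf$R / pinf$mu  # kappa^2 with threshold angle exactly pi
  tab_big <- data.frame(k = 1, kappa = sqrt(big) * 1.1, multiplicity = 50)
  expect_equal(expected_degree(sqrt(big) * 1.1, tab_big, pinf), 49,
               tolerance = 1e-9)
})

test_that("expected degree matches a Monte-Carlo ensemble mean", {
  params <- sd_params(N = 200, D = 1, beta = 3, gamma = 2.7, mean_degree = 8)
  kap <- sample_hidden_degrees(200, 2.7, 8, seed = 5)
  tab <- data.frame(k = NA, kappa = kap, multiplicity = rep(1L, 200))
  probe <- c(1, 50, 100)
  ed <- expected_degree(kap[probe], tab, params)
  mc <- vapply(1:200, function(r) {
    igraph::degree(generate_sd_network(params, kappas = kap,
                                       seed = 3000 + r))[probe]
  }, numeric(3))
  se <- apply(mc, 1, stats::sd) / sqrt(ncol(mc))
  expect_true(all(abs(rowMeans(mc) - ed) < 3 * se + 1e-9))
})

test_that("a regular degree sequence converges to a single consistent class", {
  degs <- rep(6L, 150)
  params <- sd_params(N = 150, D = 1, beta = 2.5, mean_degree = 6)
  tab <- infer_hidden_degrees(degs, params, seed = 1)
  expect_equal(nrow(tab), 1L)
  expect_true(attr(tab, "converged"))
  expect_lte(attr(tab, "epsilon_max"), 1)
  expect_equal(expected_degree(tab$kappa, tab, params), 6, tolerance = 1)
})

test_that("inference round-trips on an S^D degree sequence with epsilon_max <= 1", {
  gen <- sd_params(N = 500, D = 2, beta = 5, gamma = 2.7, mean_degree = 10)
  g <- generate_sd_network(gen, seed = 7, refine = TRUE)
  degs <- igraph::degree(g)
  degs <- degs[degs >= 1]
  params <- sd_params(N = length(degs), D = 2, beta = 5,
                      mean_degree = mean(degs))
  tab <- infer_hidden_degrees(degs, params, seed = 3)
  expect_true(attr(tab, "converged"))
  expect_lte(attr(tab, "epsilon_max"), 1)
  expect_true(all(tab$kappa > 0))
  expect_equal(sum(tab$multiplicity), length(degs))
  # every degree class is represented exactly once
  expect_equal(sort(tab$k), sort(unique(degs)))
  # regenerating with the inferred kappas reproduces per-class mean degrees
  kap <- tab$kappa[match(degs, tab$k)]
  sur <- lapply(1:10, function(r) {
    igraph::degree(generate_sd_network(params, kappas = kap, seed = 600 + r))
  })
  mean_by_class <- function(d) {
    vapply(tab$k, function(k) mean(d[degs == k]), numeric(1))
  }
  got <- rowMeans(vapply(sur, mean_by_class, numeric(nrow(tab))))
  # heaviest classes (most nodes) pin the distribution; sparse high-degree
  # classes fluctuate with O(sqrt(k)) noise over 10 draws
  heavy <- tab$multiplicity >= 10
  expect_true(all(abs(got[heavy] - tab$k[heavy]) < 1.5))
  # degree-distribution fidelity: the two-sample KS statistic between input
  # and surrogate degrees stays below the 1% critical value on average
  ks <- vapply(41:50, function(s) {
    d_sur <- igraph::degree(generate_sd_network(params, kappas = kap, seed = s))
    unname(suppressWarnings(stats::ks.test(degs, d_sur))$statistic)
  }, numeric(1))
  crit <- 1.63 * sqrt(2 / length(degs))  # alpha = 0.01 two-sample
  expect_lt(mean(ks), crit)
})

test_that("per-node and class-based iteration agree on a small graph", {
  g <- make_fixture("er", n = 60, p = 0.12, seed = 12)
  degs <- igraph::degree(g)
  degs <- degs[degs >= 1]
  params <- sd_params(N = length(degs), D = 1, beta = 2,
                      mean_degree = mean(degs))
  tab <- infer_hidden_degrees(degs, params, seed = 9)
  # node-level table: one "class" per node
  tab_node <- infer_hidden_degrees_nodewise(degs, params, seed = 9)
  by_class <- vapply(tab$k, function(k) mean(tab_node$kappa[degs == k]),
                     numeric(1))
  expect_true(all(abs(by_class - tab$kappa) <= 1.5))
})

test_that("the update never yields negative kappas and flags non-convergence", {
  degs <- c(rep(2L, 30), rep(40L, 3))  # hard sequence, tiny iteration budget
  params <- sd_params(N = 33, D = 1, beta = 1.5, mean_degree = mean(degs))
  expect_warning(
    tab <- infer_hidden_degrees(degs, params, seed = 2, max_iter = 2L),
    "did not reach")
  expect_false(attr(tab, "converged"))
  expect_true(all(tab$kappa > 0))
  expect_true(is.finite(attr(tab, "epsilon_max")))
})
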