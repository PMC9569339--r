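# The S^D generator: closed forms, sphere sampling, connection law, and the
# generated ensembles' degree calibration.

test_that("sphere radius matches its closed form", {
  expect_equal(compute_radius(1000, 1), 1000 / (2 * pi), tolerance = 1e-12)
  # independent high-precision evaluation via log-gamma, D = 2 and 5
  for (D in c(2L, 5L)) {
    N <- 1000L
    direct <- (N * exp(lgamma((D + 1) / 2)) / (2 * pi^((D + 1) / 2)))^(1 / D)
    expect_equal(compute_radius(N, D), direct, tolerance = 1e-12)
  }
  # density 1: a circle of N = 2*pi*R nodes has R = N / (2 pi) exactly
  expect_equal(compute_radius(63, 1) / 63, 1 / (2 * pi), tolerance = 1e-12)
  expect_error(compute_radius(1, 1), "N")
  expect_error(compute_radius(100, 0), "D")
  expect_error(compute_radius(10.5, 2), "N")
})

test_that("mu matches its closed form and its zero-temperature limit", {
  # beta = 2, D = 1: 2 Gamma(1/2) sin(pi/2) / (2 pi^{3/2} <k>) = 1/(<k> pi)
  expect_equal(compute_mu(2, 1, 10), 1 / (10 * pi), tolerance = 1e-12)
  # beta = Inf, D = 1: Gamma(3/2) / (sqrt(pi) <k>) = 1 / (2 <k>)
  expect_equal(compute_mu(Inf, 1, 10), 0.05, tolerance = 1e-12)
  expect_equal(compute_mu("infinite", 1, 10), 0.05, tolerance = 1e-12)
  # finite-beta value converges to the limit as beta grows, for several D
  for (D in 1:4) {
    lim <- compute_mu(Inf, D, 7)
    expect_equal(compute_mu(1e6, D, 7), lim, tolerance = 1e-4)
    expect_gt(compute_mu(D + 50, D, 7), compute_mu(D + 5, D, 7))
  }
  expect_error(compute_mu(2, 2, 10), "beta")
  expect_error(compute_mu(2, 3, 10), "beta")
})

test_that("positions are unit vectors uniformly distributed on the sphere", {
  pos <- sample_positions(10000, 1, seed = 5)
  expect_equal(dim(pos), c(10000, 2))
  expect_lt(max(abs(sqrt(rowSums(pos^2)) - 1)), 1e-12)
  # D = 1: polar angle uniform on [0, 2 pi)
  ang <- atan2(pos[, 2], pos[, 1]) + pi
  ks <- suppressWarnings(stats::ks.test(ang, "punif", 0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
  # higher D: mean pairwise dot product ~ 0 by symmetry
  pos3 <- sample_positions(1000, 3, seed = 7)
  dots <- tcrossprod(pos3)[upper.tri(diag(1000))]
  expect_lt(abs(mean(dots)), 3 * stats::sd(dots) / sqrt(length(dots)))
  # reproducible
  expect_identical(sample_positions(50, 2, seed = 1),
                   sample_positions(50, 2, seed = 1))
})

test_that("angular distance handles identical, antipodal and orthogonal pairs", {
  v <- c(1, 0, 0)
  expect_equal(angular_distance(v, v), 0)
  expect_equal(angular_distance(v, -v), pi)
  expect_equal(angular_distance(v, c(0, 1, 0)), pi / 2)
  # clamping: numerically drifted unit vectors stay finite
  u <- c(1, 1e-16, 0)
  expect_equal(angular_distance(u, u), 0)
  expect_error(angular_distance(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("connection probability is the Fermi-Dirac gravity law", {
  p <- sd_params(N = 100, D = 2, beta = 4, mean_degree = 5)
  # chi = 1 at dtheta = (mu k k')^(1/D) / R: probability exactly 1/2
  kk <- c(3, 7)
  dth <- (p$mu * kk[1] * kk[2])^(1 / p$D) / p$R
  expect_equal(connection_probability(kk[1], kk[2], dth, p), 0.5)
  expect_equal(connection_probability(kk[1], kk[2], 0, p), 1)
  # zero-temperature step law
  pinf <- sd_params(N = 100, D = 2, beta = Inf, mean_degree = 5)
  dthf <- (pinf$mu * kk[1] * kk[2])^(1 / pinf$D) / pinf$R
  expect_equal(connection_probability(kk[1], kk[2], 0.99 * dthf, pinf), 1)
  expect_equal(connection_probability(kk[1], kk[2], 1.01 * dthf, pinf), 0)
  expect_equal(connection_probability(kk[1], kk[2], dthf, pinf), 0.5)
  # monotone sharpening: raising beta lowers p when chi > 1, raises it below
  p_lo <- sd_params(N = 100, D = 2, beta = 3, mean_degree = 5)
  p_hi <- sd_params(N = 100, D = 2, beta = 9, mean_degree = 5)
  chi_of <- function(pp, dt) pp$R * dt / (pp$mu * kk[1] * kk[2])^(1 / pp$D)
  dt_far <- 1.8 * (p_lo$mu * kk[1] * kk[2])^(1 / 2) / p_lo$R
  # compare at the same chi by matching dtheta to each mu
  chi <- 1.8
  pr <- function(pp) 1 / (1 + chi^pp$beta)
  expect_lt(pr(p_hi), pr(p_lo))
  chi <- 0.6
  expect_gt(pr(p_hi), pr(p_lo))
})

test_that("hidden degrees are Pareto with the target mean and tail", {
  k <- sample_hidden_degrees(1e5, 2.7, 10, seed = 3)
  kappa0 <- 10 * 0.7 / 1.7
  expect_true(all(k >= kappa0))
  # analytic mean <k> within 3 standard errors
  expect_lt(abs(mean(k) - 10), 3 * stats::sd(k) / sqrt(length(k)))
  # tail exponent: CCDF slope ~ -(gamma - 1) on log-log scale
  k2 <- sample_hidden_degrees(1e5, 2.5, 10, seed = 4)
  q <- stats::quantile(k2, c(0.9, 0.999))
  xs <- exp(seq(log(q[1]), log(q[2]), length.out = 30))
  ccdf <- vapply(xs, function(x) mean(k2 > x), numeric(1))
  slope <- stats::coef(stats::lm(log(ccdf) ~ log(xs)))[2]
  expect_equal(unname(slope), -(2.5 - 1), tolerance = 0.08)
  expect_error(sample_hidden_degrees(10, 2, 10), "gamma")
})

test_that("generated networks are simple, reproducible and degree-calibrated", {
  params <- sd_params(N = 600, D = 2, beta = Inf, gamma = 2.5, mean_degree = 10)
  g <- generate_sd_network(params, seed = 11, refine = TRUE)
  expect_equal(igraph::vcount(g), 600)
  expect_true(igraph::is_simple(g))
  expect_false(igraph::any_loop(g))
  g2 <- generate_sd_network(params, seed = 11, refine = TRUE)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  # kappa and positions retained
  expect_length(igraph::V(g)$kappa, 600)
  expect_equal(dim(g$positions), c(600, 3))
  # with mu refinement the expected mean degree hits the target, so realized
  # mean degree lands within binomial noise of 10
  kmeans <- vapply(1:6, function(r) {
    mean(igraph::degree(generate_sd_network(params, seed = 100 + r,
                                            refine = TRUE)))
  }, numeric(1))
  expect_lt(abs(mean(kmeans) - 10), 0.15)
})

test_that("edge draws are independent: realized edge count tracks the sum of pair probabilities", {
  params <- sd_params(N = 80, D = 1, beta = 3, gamma = NA, mean_degree = 6)
  kap <- sample_hidden_degrees(80, 2.7, 6, seed = 2)
  pos <- sample_positions(80, 1, seed = 3)
  dth <- acos(pmin(pmax(tcrossprod(pos), -1), 1))
  ki <- matrix(kap, 80, 80)  # [i, j] = kap_i
  ut <- upper.tri(dth)
  P <- connection_probability(ki[ut], t(ki)[ut], dth[ut], params)
  m_expected <- sum(P)
  counts <- vapply(1:40, function(r) {
    igraph::ecount(generate_sd_network(params, kappas = kap, positions = pos,
                                       seed = 500 + r))
  }, numeric(1))
  sd_binom <- sqrt(sum(P * (1 - P)))
  expect_lt(abs(mean(counts) - m_expected), 3 * sd_binom / sqrt(40))
})
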