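# Inverse-temperature calibration: exact fit recovery, inversion identity,
# cross-dimension scaling, and the clustering window sampler.

make_exact_fit <- function(cmax = 0.8, a = 0.5, b0 = 1) {
  beta <- seq(1.2, 14, length.out = 20)
  fit_ct_curve(data.frame(beta = beta,
                          C_t = cmax * (1 - exp(-a * (beta - b0)))))
}

test_that("noiseless curves are recovered to 4 decimals", {
  for (truth in list(c(0.8, 0.5, 1), c(0.6, 0.3, 0.5), c(0.9, 1.2, 1.1))) {
    fit <- make_exact_fit(truth[1], truth[2], truth[3])
    expect_equal(fit$ct_max_1, truth[1], tolerance = 1e-5)
    expect_equal(fit$a, truth[2], tolerance = 1e-5)
    expect_equal(fit$beta0, truth[3], tolerance = 1e-5)
  }
  # functional form: 0 at beta0, saturating at ct_max_1
  fit <- make_exact_fit()
  expect_equal(netdim:::ct_from_beta(fit$beta0, fit), 0)
  expect_equal(netdim:::ct_from_beta(1e9, fit), fit$ct_max_1)
})

test_that("fit rejects degenerate or invalid samples", {
  expect_error(fit_ct_curve(data.frame(beta = 1:3, C_t = c(0.1, 0.2, 0.3))),
               "at least 5")
  expect_error(fit_ct_curve(data.frame(beta = 1:6, C_t = rep(0.4, 6))),
               "degenerate")
  expect_error(fit_ct_curve(data.frame(beta = 1:6, C_t = c(1, 1.2, rep(0.5, 4)))),
               "0, 1")
})

test_that("inversion is the identity and scales linearly with dimension", {
  fit <- make_exact_fit()
  for (beta in c(2, 5, 10)) {
    ct <- netdim:::ct_from_beta(beta, fit)
    expect_equal(beta_from_ct(ct, fit, 1), beta, tolerance = 1e-9)
  }
  # beta(D) = D * beta(1) at matched clustering target
  expect_equal(beta_from_ct(0.4, fit, 3), 3 * beta_from_ct(0.4, fit, 1),
               tolerance = 1e-12)
  # ct -> 0+ gives beta -> beta0
  expect_equal(beta_from_ct(1e-12, fit, 1), fit$beta0, tolerance = 1e-6)
  expect_error(beta_from_ct(0.85, fit, 1), "range")
})

test_that("the beta sampler respects the window, the floor and determinism", {
  fit <- make_exact_fit()
  b <- sample_beta_range(0.5, 3, fit, n_networks = 50, seed = 8)
  expect_length(b, 50)
  expect_true(all(b >= 3 + 0.25))
  expect_identical(as.numeric(b),
                   as.numeric(sample_beta_range(0.5, 3, fit, 50, seed = 8)))
  # sampled clustering targets are uniform over the clipped window
  b2 <- sample_beta_range(0.75, 1, fit, n_networks = 400, seed = 9)
  xi <- attr(b2, "xi")
  lo <- 0.65
  hi <- fit$ct_max_1 * (1 - 1e-9)  # upper half clipped at ct_max_1
  ks <- suppressWarnings(stats::ks.test(xi, "punif", lo, hi))
  expect_gt(ks$p.value, 0.01)
  # fully unreachable window: skipped dimension
  b3 <- sample_beta_range(0.95, 2, fit, n_networks = 10, seed = 1)
  expect_length(b3, 0)
  expect_true(attr(b3, "skipped"))
})

test_that("beta floor and window interact: low targets still return D + 0.25", {
  fit <- make_exact_fit()
  b <- sample_beta_range(0.011, 4, fit, n_networks = 100, seed = 3)
  expect_true(all(b >= 4.25))
  expect_true(any(b == 4.25))  # the floor actually binds for tiny targets
})

test_that("unreachable clustering is flagged anomalous at D = 1", {
  g <- generate_sd_network(
    sd_params(N = 300, D = 1, beta = 4, gamma = 2.7, mean_degree = 8),
    seed = 5, refine = TRUE)
  expect_warning(
    d <- estimate_max_dimension(g, ct_observed = 0.999, n_reals = 2, cap = 3,
                                seed = 2),
    "anomalous")
  expect_equal(as.integer(d), 1L)
  expect_true(attr(d, "anomalous"))
})

test_that("surrogates generated at sampled betas bracket the observed clustering", {
  # stochastic round trip at D = 1: build a real S^1 network, calibrate on its
  # inferred kappas, then check surrogate C_t lands near the target window
  gen <- sd_params(N = 700, D = 1, beta = 2.5, gamma = 2.7, mean_degree = 10)
  g <- generate_sd_network(gen, seed = 13, refine = TRUE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  ct_obs <- phase_point(g, max_len = 3)$C_t
  degs <- igraph::degree(g)
  cfg <- netdim_config(calib_n = 12, max_iter = 120)
  fit <- netdim:::calibrate_d1_curve(degs, mean(degs), cfg, seed = 21,
                                     ct_range = ct_obs + c(-0.1, 0.1))
  betas <- sample_beta_range(ct_obs, 1, fit, n_networks = 8, seed = 4)
  cts <- vapply(seq_along(betas), function(b) {
    params <- sd_params(N = length(degs), D = 1, beta = betas[b],
                        mean_degree = mean(degs))
    tab <- infer_hidden_degrees(degs, params, seed = 100 + b)
    netdim:::sd_phase_point(params, tab$kappa[match(degs, tab$k)],
                            seed = 200 + b, max_len = 3)$C_t
  }, numeric(1))
  expect_lt(abs(mean(cts) - ct_obs), 0.15)
})
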