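# The S^D geometric soft configuration model.
#
# Each node i carries a hidden degree kappa_i (its expected degree in the
# ensemble) and a position v_i on the D-dimensional similarity sphere of
# radius R, chosen so that the node density on the sphere is one. Pairs
# connect independently with the gravity-law probability
#
#   p_ij = 1 / (1 + chi_ij^beta),  chi_ij = R * dtheta_ij / (mu kappa_i kappa_j)^(1/D)
#
# where dtheta_ij is the angular distance between v_i and v_j, beta > D is the
# inverse temperature coupling topology to geometry, and mu fixes the mean
# degree. beta = Inf is the zero-temperature limit: a step connection law at
# chi = 1, where clustering is maximal.

#' Radius of the similarity D-sphere
#'
#' Radius at which `N` nodes sit with density one on the D-sphere:
#' \eqn{R = [N \Gamma((D+1)/2) / (2 \pi^{(D+1)/2})]^{1/D}}. For `D = 1` this
#' reduces to the circle of circumference `N`, i.e. `R = N / (2 pi)`.
#'
#' @param N number of nodes (integer, at least 2).
#' @param D similarity dimension (integer, at least 1).
#' @return The radius, a positive scalar.
#' @export
#' @examples
#' compute_radius(1000, 1) # 1000 / (2 * pi)
compute_radius <- function(N, D) {
  N <- check_count(N, "N", min = 2L)
  D <- check_count(D, "D", min = 1L)
  exp((log(N) + lgamma((D + 1) / 2) - log(2) - (D + 1) / 2 * log(pi)) / D)
}

#' Density parameter mu of the S^D model
#'
#' Closed-form value fixing the ensemble mean degree in the thermodynamic
#' limit: \eqn{\mu = \beta \Gamma(D/2) \sin(D\pi/\beta) /
#' (2 \pi^{1+D/2} \langle k \rangle)}. At `beta = Inf` the analytic limit
#' \eqn{\Gamma(D/2+1) / (\pi^{D/2} \langle k \rangle)} is returned. On finite
#' graphs the realized mean degree deviates slightly; see [refine_mu()].
#'
#' @param beta inverse temperature, a number greater than `D`, `Inf`, or the
#'   string `"infinite"`.
#' @param D similarity dimension.
#' @param mean_degree target mean degree, positive.
#' @return mu, a positive scalar.
#' @export
#' @examples
#' compute_mu(2, 1, 10)   # 1 / (10 * pi)
#' compute_mu(Inf, 1, 10) # 1 / 20
compute_mu <- function(beta, D, mean_degree) {
  D <- check_count(D, "D", min = 1L)
  mean_degree <- check_positive(mean_degree, "mean_degree")
  if (is_infinite_beta(beta)) {
    return(exp(lgamma(D / 2 + 1) - D / 2 * log(pi)) / mean_degree)
  }
  beta <- check_positive(beta, "beta")
  if (beta <= D) {
    stop("`beta` must exceed `D` (the mu closed form diverges at beta <= D)",
         call. = FALSE)
  }
  beta * gamma(D / 2) * sin(D * pi / beta) /
    (2 * pi^(1 + D / 2) * mean_degree)
}

#' Parameter set of the S^D ensemble
#'
#' Bundles the model parameters and derives `mu` and `R` from their closed
#' forms. The small-world boundary `beta = 2 D` is recorded as metadata
#' (`small_world`), not enforced.
#'
#' @inheritParams compute_mu
#' @param N number of nodes.
#' @param gamma power-law exponent of the hidden-degree distribution
#'   (`gamma > 2`); `NA` is allowed when hidden degrees are supplied
#'   externally (e.g. inferred from an observed degree sequence).
#' @return An object of class `"sd_params"`.
#' @export
#' @examples
#' sd_params(N = 1000, D = 2, beta = 5, gamma = 2.7, mean_degree = 10)
sd_params <- function(N, D, beta, gamma = NA_real_, mean_degree = 10) {
  N <- check_count(N, "N", min = 2L)
  D <- check_count(D, "D", min = 1L)
  if (is_infinite_beta(beta)) {
    beta <- Inf
  } else {
    beta <- check_positive(beta, "beta")
    if (beta <= D) stop("`beta` must exceed `D` or be infinite", call. = FALSE)
  }
  if (!is.na(gamma) && gamma <= 2) {
    stop("`gamma` must exceed 2 (finite mean hidden degree)", call. = FALSE)
  }
  mean_degree <- check_positive(mean_degree, "mean_degree")
  structure(
    list(
      N = N, D = D, beta = beta, gamma = as.numeric(gamma),
      mean_degree = mean_degree,
      mu = compute_mu(beta, D, mean_degree),
      R = compute_radius(N, D),
      small_world = is.infinite(beta) || beta < 2 * D
    ),
    class = "sd_params"
  )
}

#' @export
print.sd_params <- function(x, ...) {
  cat(sprintf(
    "S^%d model: N = %d, beta = %s, gamma = %s, <k> = %g (mu = %.5g, R = %.5g)\n",
    x$D, x$N, format(x$beta), format(x$gamma), x$mean_degree, x$mu, x$R
  ))
  invisible(x)
}

#' Uniform random positions on the D-sphere
#'
#' Draws `N` points uniformly on the unit D-sphere embedded in `D + 1`
#' dimensions, by normalizing isotropic Gaussian vectors (rotation invariance
#' guarantees uniformity).
#'
#' @inheritParams compute_radius
#' @param seed optional integer seed; the draw is reproducible given the seed
#'   and the caller's RNG state is restored afterwards.
#' @return An `N x (D + 1)` matrix of unit row vectors.
#' @export
sample_positions <- function(N, D, seed = NULL) {
  N <- check_count(N, "N", min = 1L)
  D <- check_count(D, "D", min = 1L)
  with_seed(seed, {
    x <- matrix(stats::rnorm(N * (D + 1)), nrow = N)
    x / sqrt(rowSums(x^2))
  })
}

#' Angular distance between unit vectors
#'
#' @param v1,v2 unit vectors of equal length (rows of a position matrix).
#' @return The angle in `[0, pi]`; the dot product is clamped to `[-1, 1]`
#'   before `acos` to absorb floating-point drift.
#' @export
angular_distance <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    stop("`v1` and `v2` must have the same ambient dimension", call. = FALSE)
  }
  acos(pmin(pmax(sum(v1 * v2), -1), 1))
}

#' Gravity-law connection probability
#'
#' Fermi-Dirac connection probability of the S^D model,
#' \eqn{p = 1/(1 + \chi^\beta)} with
#' \eqn{\chi = R \Delta\theta / (\mu \kappa_i \kappa_j)^{1/D}}. At
#' `beta = Inf` it is the step law: 1 for `chi < 1`, 0 for `chi > 1`, and 1/2
#' exactly at the Fermi level `chi = 1`.
#'
#' @param kappa_i,kappa_j hidden degrees (positive; vectorized).
#' @param dtheta angular distance(s) in `[0, pi]`.
#' @param params an [sd_params()] object.
#' @return Probabilities in `[0, 1]`.
#' @export
connection_probability <- function(kappa_i, kappa_j, dtheta, params) {
  stopifnot(inherits(params, "sd_params"))
  if (any(kappa_i <= 0) || any(kappa_j <= 0)) {
    stop("hidden degrees must be positive", call. = FALSE)
  }
  if (any(dtheta < 0 | dtheta > pi + 1e-12)) {
    stop("`dtheta` must lie in [0, pi]", call. = FALSE)
  }
  chi <- params$R * dtheta / (params$mu * kappa_i * kappa_j)^(1 / params$D)
  if (is.infinite(params$beta)) {
    out <- ifelse(chi < 1, 1, ifelse(chi > 1, 0, 0.5))
  } else {
    out <- 1 / (1 + chi^params$beta)
  }
  out
}

#' Power-law hidden degrees with a prescribed mean
#'
#' I.i.d. draws from the Pareto density
#' \eqn{\rho(\kappa) = (\gamma - 1) \kappa_0^{\gamma-1} \kappa^{-\gamma}} on
#' \eqn{[\kappa_0, \infty)}, with
#' \eqn{\kappa_0 = \langle k \rangle (\gamma - 2) / (\gamma - 1)} so that the
#' distribution mean equals the target mean degree.
#'
#' @param N number of draws.
#' @param gamma tail exponent, strictly greater than 2.
#' @param mean_degree target mean, positive.
#' @param seed optional integer seed.
#' @return A numeric vector of `N` hidden degrees, all at least `kappa_0`.
#' @export
sample_hidden_degrees <- function(N, gamma, mean_degree, seed = NULL) {
  N <- check_count(N, "N", min = 1L)
  gamma <- check_positive(gamma, "gamma")
  if (gamma <= 2) {
    stop("`gamma` must exceed 2: the hidden-degree mean diverges otherwise",
         call. = FALSE)
  }
  mean_degree <- check_positive(mean_degree, "mean_degree")
  kappa0 <- mean_degree * (gamma - 2) / (gamma - 1)
  with_seed(seed, kappa0 * stats::runif(N)^(-1 / (gamma - 1)))
}

# Histogram of log pair products log(kappa_i * kappa_j) over unordered pairs,
# used to evaluate the ensemble mean degree cheaply for many mu values.
pair_product_bins <- function(kappas, n_bins = 4096L) {
  pair_log_hist_cpp(log(kappas), as.integer(n_bins))
}

#' Ensemble mean degree for a fixed hidden-degree sequence
#'
#' Evaluates the expected mean degree of the S^D ensemble for given hidden
#' degrees by integrating the connection probability over the uniform
#' position measure (the same integral that drives hidden-degree inference),
#' binning the \eqn{\kappa_i \kappa_j} products for speed.
#'
#' @param params an [sd_params()] object.
#' @param kappas hidden-degree vector of length `params$N`.
#' @param mu density parameter; defaults to `params$mu`.
#' @return The expected mean degree, a positive scalar.
#' @export
expected_mean_degree <- function(params, kappas, mu = params$mu) {
  stopifnot(inherits(params, "sd_params"), length(kappas) == params$N)
  bins <- pair_product_bins(kappas)
  expected_mean_degree_binned(params, bins, mu)
}

expected_mean_degree_binned <- function(params, bins, mu) {
  t <- exp((log(mu) + bins$centers) / params$D) / params$R
  I <- fermi_sin_integral(t, params$D, params$beta)
  # sum over unordered pairs of 2 * p_ij, divided by N
  2 * sd_prefactor(params$D) * sum(bins$weights * I) / params$N
}

#' Refine mu so the ensemble mean degree matches its target
#'
#' The closed-form `mu` is exact only in the thermodynamic limit; on finite
#' graphs the realized mean degree drifts by a few percent. This adjusts `mu`
#' by bisection on the expected mean degree for the supplied hidden-degree
#' sequence until it matches `target` within `tol`.
#'
#' @inheritParams expected_mean_degree
#' @param target desired mean degree; defaults to `params$mean_degree`.
#' @param tol absolute tolerance on the expected mean degree (default 0.02,
#'   well inside the 0.1 band used when calibrating generated ensembles).
#' @param max_iter bisection iteration cap.
#' @return The refined `mu`, a positive scalar.
#' @export
refine_mu <- function(params, kappas, target = params$mean_degree,
                      tol = 0.02, max_iter = 100L) {
  stopifnot(inherits(params, "sd_params"), length(kappas) == params$N)
  bins <- pair_product_bins(kappas)
  f <- function(mu) expected_mean_degree_binned(params, bins, mu) - target
  lo <- params$mu / 2
  hi <- params$mu * 2
  while (f(lo) > 0 && lo > params$mu * 1e-6) lo <- lo / 4
  while (f(hi) < 0 && hi < params$mu * 1e6) hi <- hi * 4
  for (iter in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    val <- f(mid)
    if (abs(val) <= tol) return(mid)
    if (val > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Generate a network from the S^D model
#'
#' Draws node positions uniformly on the D-sphere (unless supplied), then
#' links every unordered pair independently with the gravity-law probability
#' of [connection_probability()]. At `beta = Inf` the step law is used. The
#' result is a simple undirected graph whose vertices keep their hidden
#' degrees (`kappa` vertex attribute) and positions (`positions` graph
#' attribute); vertex names are the consecutive integers `0 .. N-1`.
#'
#' @param params an [sd_params()] object.
#' @param kappas hidden degrees of length `params$N`; by default sampled via
#'   [sample_hidden_degrees()] with the parameters in `params`.
#' @param seed optional integer seed; generation is reproducible bit-for-bit
#'   for a fixed seed.
#' @param refine logical; if `TRUE`, `mu` is refined with [refine_mu()] before
#'   generating, so the realized mean degree is centered on the target (used
#'   by the experiment drivers). Raw surrogate draws keep the supplied `mu`.
#' @param positions optional `N x (D+1)` matrix of unit vectors.
#' @return An `igraph` graph with `N` vertices.
#' @export
generate_sd_network <- function(params, kappas = NULL, seed = NULL,
                                refine = FALSE, positions = NULL) {
  stopifnot(inherits(params, "sd_params"))
  with_seed(seed, {
    if (is.null(kappas)) {
      if (is.na(params$gamma)) {
        stop("supply `kappas` or a `gamma` in `params`", call. = FALSE)
      }
      kappas <- sample_hidden_degrees(params$N, params$gamma, params$mean_degree)
    }
    stopifnot(length(kappas) == params$N, all(kappas > 0))
    if (is.null(positions)) {
      positions <- sample_positions(params$N, params$D)
    }
    stopifnot(nrow(positions) == params$N, ncol(positions) == params$D + 1)
    mu <- if (refine) refine_mu(params, kappas) else params$mu
    el <- generate_edges_cpp(positions, kappas, params$R, mu,
                             if (is.infinite(params$beta)) -1 else params$beta,
                             params$D, is.infinite(params$beta))
    g <- igraph::make_empty_graph(n = params$N, directed = FALSE)
    if (nrow(el) > 0) {
      g <- igraph::add_edges(g, as.vector(t(el)) + 1L)
    }
    igraph::V(g)$name <- as.character(seq_len(params$N) - 1L)
    igraph::V(g)$kappa <- kappas
    g$positions <- positions
    g$params <- params
    g$mu_used <- mu
    g
  })
}
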