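# Quadrature and closed-form kernels for the expected-degree integral
#
#   I(t; D, beta) = \int_0^pi sin^(D-1)(theta) / (1 + (theta/t)^beta) dtheta
#
# where t = (mu * kappa_i * kappa_j)^(1/D) / R. The integrand is smooth except
# for the Fermi transition near theta = t, so the integral is split there; at
# beta = Inf it reduces to the incomplete integral of sin^(D-1) up to t, which
# has a closed form through the regularized incomplete beta function.

.netdim_cache <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem.
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  cached <- get0(key, envir = .netdim_cache)
  if (!is.null(cached)) return(cached)
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  out <- list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
  assign(key, out, envir = .netdim_cache)
  out
}

# \int_0^x sin^(D-1)(theta) dtheta for x in [0, pi], vectorized in x.
# Substituting u = sin^2(theta) gives (1/2) * B(sin^2 x; D/2, 1/2) on
# [0, pi/2]; the [pi/2, pi] part follows by symmetry of sin about pi/2.
sin_power_integral <- function(x, D) {
  x <- pmin(pmax(x, 0), pi)
  full <- beta(D / 2, 1 / 2)
  half <- function(z) 0.5 * full * stats::pbeta(sin(z)^2, D / 2, 1 / 2)
  ifelse(x <= pi / 2, half(x), full - half(pi - x))
}

# I(t; D, beta) vectorized in t (t > 0). `beta = Inf` uses the closed form.
# 32 Gauss-Legendre nodes per segment leave the quadrature error orders of
# magnitude below the degree-unit tolerances downstream (the integrand is
# smooth on each side of the Fermi transition, where the domain is split).
fermi_sin_integral <- function(t, D, beta, n_nodes = 32L) {
  if (is_infinite_beta(beta)) {
    return(sin_power_integral(pmin(t, pi), D))
  }
  gl <- gauss_legendre(n_nodes)
  t <- as.numeric(t)
  s <- pmin(t, pi)                      # split point (Fermi level or pi)
  integrand <- function(theta, tt) {
    ratio <- theta / tt
    sin(theta)^(D - 1) / (1 + ratio^beta)
  }
  piece <- function(lo, hi, tt) {
    # vectorized over pairs: rows = t values, cols = quadrature nodes
    hw <- (hi - lo) / 2
    mid <- (hi + lo) / 2
    theta <- outer(hw, gl$nodes) + mid
    vals <- integrand(theta, tt)
    hw * as.numeric(vals %*% gl$weights)
  }
  out <- piece(rep(0, length(t)), s, t)
  open <- s < pi
  if (any(open)) {
    out[open] <- out[open] + piece(s[open], rep(pi, sum(open)), t[open])
  }
  out
}

# Prefactor of the S^D expected-degree formula,
# Gamma((D+1)/2) / (sqrt(pi) * Gamma(D/2)); its reciprocal is the full
# integral of sin^(D-1) over [0, pi], so a connection probability of one
# everywhere yields expected degree N - 1.
sd_prefactor <- function(D) {
  exp(lgamma((D + 1) / 2) - lgamma(D / 2)) / sqrt(pi)
}
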