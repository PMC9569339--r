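# Inverse-temperature calibration.
#
# Edge clustering C_t depends on beta non-linearly: it vanishes as
# beta -> D+ and saturates as beta -> Inf. To sample surrogates homogeneously
# in C_t around the observed value, a one-dimensional (D = 1) sample of
# networks is fitted with the saturating-exponential law
#
#   C_t(beta) = C_t,max * (1 - exp(-a (beta - beta0))),
#
# which is then inverted, and extended to higher dimensions through the
# empirical scaling C_t^D(beta / D) / C_t,max^D ~ C_t^1(beta) / C_t,max^1,
# i.e. beta(D) = D * beta(1) at matched relative clustering.

#' Fit the saturating edge-clustering curve
#'
#' Least-squares fit of `C_t(beta) = ct_max_1 * (1 - exp(-a * (beta - beta0)))`
#' to sampled `(beta, C_t)` pairs, typically 20 networks generated at `D = 1`
#' with `beta ~ U(1, 15)`.
#'
#' @param graph_stats a data frame (or matrix) with columns `beta` and `C_t`;
#'   at least 5 points with `C_t` in `[0, 1)`.
#' @param delta_ct half-width of the clustering window later used by
#'   [sample_beta_range()]; stored with the fit (default 0.1).
#' @return An object of class `"ct_curve_fit"`: list with `ct_max_1`, `a`,
#'   `beta0`, `delta_ct` and the fit residual standard deviation `sigma`.
#' @export
fit_ct_curve <- function(graph_stats, delta_ct = 0.1) {
  df <- as.data.frame(graph_stats)
  if (!all(c("beta", "C_t") %in% names(df))) {
    names(df)[1:2] <- c("beta", "C_t")
  }
  df <- df[is.finite(df$beta) & is.finite(df$C_t), , drop = FALSE]
  if (nrow(df) < 5) stop("need at least 5 (beta, C_t) sample points", call. = FALSE)
  if (any(df$C_t < 0 | df$C_t >= 1)) {
    stop("C_t values must lie in [0, 1)", call. = FALSE)
  }
  if (diff(range(df$C_t)) < 1e-10) {
    stop("degenerate sample: all C_t values are equal; cannot fit", call. = FALSE)
  }
  # profiled start values: for fixed cmax the model linearizes as
  # log(1 - C_t / cmax) = -a * beta + a * beta0, so scan cmax for the best
  # linearized RSS, then polish everything with Levenberg-Marquardt.
  lin_fit <- function(cmax) {
    y <- log(pmax(1 - df$C_t / cmax, 1e-12))
    lf <- stats::lm(y ~ df$beta)
    a <- max(-unname(stats::coef(lf)[2]), 1e-6)
    b0 <- unname(stats::coef(lf)[1]) / a
    rss <- sum((df$C_t - cmax * (1 - exp(-a * (df$beta - b0))))^2)
    list(cmax = cmax, a = a, b0 = b0, rss = rss)
  }
  cmax_grid <- max(df$C_t) + (1 - max(df$C_t)) * seq(1e-4, 0.9, length.out = 60)
  starts <- lapply(cmax_grid, lin_fit)
  best <- starts[[which.min(vapply(starts, `[[`, numeric(1), "rss"))]]
  fit <- minpack.lm::nlsLM(
    C_t ~ cmax * (1 - exp(-a * (beta - b0))),
    data = df,
    start = list(cmax = best$cmax, a = best$a, b0 = best$b0),
    lower = c(cmax = 1e-6, a = 1e-6, b0 = -50),
    upper = c(cmax = 1, a = 100, b0 = 50),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  cf <- stats::coef(fit)
  structure(
    list(ct_max_1 = unname(cf["cmax"]), a = unname(cf["a"]),
         beta0 = unname(cf["b0"]), delta_ct = delta_ct,
         sigma = stats::sigma(fit), n = nrow(df)),
    class = "ct_curve_fit"
  )
}

#' @export
print.ct_curve_fit <- function(x, ...) {
  cat(sprintf(
    "C_t(beta) = %.4f * (1 - exp(-%.4f * (beta - %.4f)))  [sigma = %.3g, n = %d]\n",
    x$ct_max_1, x$a, x$beta0, x$sigma, x$n))
  invisible(x)
}

# Forward evaluation of the fitted curve at D = 1.
ct_from_beta <- function(beta, fit) {
  fit$ct_max_1 * (1 - exp(-fit$a * (beta - fit$beta0)))
}

#' Invert the clustering curve: beta for a target C_t
#'
#' Inverts the fitted `D = 1` curve and rescales to dimension `D`:
#' \eqn{\beta = D [\beta_0 - \ln(1 - C_t / C_{t,max}) / a]}. For `D = 1`
#' this is the exact inverse of the fit; for higher dimensions it applies the
#' empirical scaling by which the relative clustering curve is shared across
#' dimensions up to the factor `D` in `beta`.
#'
#' @param ct_target target edge-triangle density, in `(0, ct_max_1)`.
#' @param fit a [fit_ct_curve()] object.
#' @param D dimension to rescale to (default 1).
#' @return The inverse temperature(s), same length as `ct_target`.
#' @export
beta_from_ct <- function(ct_target, fit, D = 1L) {
  stopifnot(inherits(fit, "ct_curve_fit"))
  D <- check_count(D, "D", min = 1L)
  if (any(ct_target <= 0) || any(ct_target >= fit$ct_max_1)) {
    stop(sprintf(
      "`ct_target` must lie in (0, %.4f): clustering outside the reachable range",
      fit$ct_max_1), call. = FALSE)
  }
  D * (fit$beta0 - log(1 - ct_target / fit$ct_max_1) / fit$a)
}

#' Sample the inverse-temperature range bracketing an observed clustering
#'
#' Draws `n_networks` clustering targets \eqn{\xi} uniformly in the window
#' `(ct_observed - delta_ct, ct_observed + delta_ct)` (clipped to the
#' reachable range `(0, ct_max_1)`), maps each through [beta_from_ct()] for
#' dimension `D`, and clips the result from below at `D + 0.25`, the smallest
#' inverse temperature explored per dimension.
#'
#' @param ct_observed observed edge-triangle density, in `(0, 1)`.
#' @param D dimension the betas are meant for.
#' @param fit a [fit_ct_curve()] object.
#' @param n_networks number of betas to draw (default 50, one per surrogate).
#' @param seed optional integer seed.
#' @param delta_ct half-width of the sampling window; defaults to the value
#'   stored in `fit`.
#' @return A numeric vector of betas (attribute `xi` carries the sampled
#'   clustering targets). When the whole window lies above `ct_max_1` the
#'   vector is empty with attribute `skipped = TRUE`: that dimension cannot
#'   reproduce the observed clustering.
#' @export
sample_beta_range <- function(ct_observed, D, fit, n_networks = 50L,
                              seed = NULL, delta_ct = fit$delta_ct) {
  stopifnot(inherits(fit, "ct_curve_fit"))
  D <- check_count(D, "D", min = 1L)
  n_networks <- check_count(n_networks, "n_networks", min = 1L)
  if (ct_observed <= 0 || ct_observed >= 1) {
    stop("`ct_observed` must lie in (0, 1)", call. = FALSE)
  }
  lo <- max(ct_observed - delta_ct, fit$ct_max_1 * 1e-9)
  hi <- min(ct_observed + delta_ct, fit$ct_max_1 * (1 - 1e-9))
  if (lo >= hi) {
    out <- numeric(0)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  with_seed(seed, {
    xi <- stats::runif(n_networks, lo, hi)
    beta <- pmax(beta_from_ct(xi, fit, D), D + 0.25)
    attr(beta, "xi") <- xi
    attr(beta, "skipped") <- FALSE
    beta
  })
}

#' Largest dimension compatible with an observed edge clustering
#'
#' Edge clustering is maximal at `beta = Inf` and this maximum decreases
#' monotonically with the dimension, so the observed C_t bounds the dimensions
#' worth exploring. For `D = 1, 2, ...` the function re-infers hidden degrees
#' from the graph's degree sequence at `beta = Inf`, generates `n_reals`
#' surrogates, and records the mean edge-triangle density; it returns the
#' largest `D` whose attainable clustering still reaches `ct_observed`,
#' stopping at the first failure (hard `cap` by default 12).
#'
#' If even `D = 1` cannot reach it, the clustering is anomalous for the model
#' in any dimension and 1 is returned with attribute `anomalous = TRUE`.
#'
#' @param graph a simple undirected `igraph` graph (degree sequence provider).
#' @param ct_observed observed edge-triangle density in `(0, 1)`; defaults to
#'   the graph's own [phase_point()] value.
#' @param n_reals surrogates per dimension (default 10).
#' @param cap largest dimension scanned (default 12).
#' @param tolerance,max_iter hidden-degree inference controls.
#' @param seed optional integer seed.
#' @return The maximum dimension (integer) with attributes `ct_by_D` (named
#'   vector of mean maximal C_t per scanned dimension) and `anomalous`.
#' @export
estimate_max_dimension <- function(graph, ct_observed = NULL, n_reals = 10L,
                                   cap = 12L, tolerance = 1, max_iter = 200L,
                                   seed = NULL) {
  stopifnot(igraph::is_igraph(graph))
  n_reals <- check_count(n_reals, "n_reals", min = 1L)
  cap <- check_count(cap, "cap", min = 1L)
  degs <- igraph::degree(graph)
  if (any(degs < 1)) stop("drop isolated nodes first", call. = FALSE)
  if (is.null(ct_observed)) {
    ct_observed <- phase_point(graph, max_len = 3L)$C_t
  }
  if (ct_observed <= 0 || ct_observed >= 1) {
    stop("`ct_observed` must lie in (0, 1)", call. = FALSE)
  }
  ct_by_D <- numeric(0)
  d_ok <- 0L
  for (D in seq_len(cap)) {
    params <- sd_params(N = length(degs), D = D, beta = Inf,
                        mean_degree = mean(degs))
    tab <- infer_hidden_degrees(degs, params, tolerance = tolerance,
                                seed = derive_seed(seed, 1000L + D),
                                max_iter = max_iter)
    kap <- kappas_from_table(degs, tab)
    cts <- vapply(seq_len(n_reals), function(r) {
      sd_phase_point(params, kap, seed = derive_seed(seed, 1000L * D + r),
                     max_len = 3L)$C_t
    }, numeric(1))
    ct_by_D[as.character(D)] <- mean(cts)
    if (mean(cts) >= ct_observed) {
      d_ok <- D
    } else {
      break
    }
  }
  anomalous <- d_ok == 0L
  out <- max(d_ok, 1L)
  attr(out, "ct_by_D") <- ct_by_D
  attr(out, "anomalous") <- anomalous
  if (anomalous) {
    warning("observed clustering unreachable even at D = 1 (anomalous cycle statistics); returning D = 1",
            call. = FALSE)
  }
  out
}
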