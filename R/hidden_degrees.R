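# Hidden-degree inference.
#
# Surrogates must reproduce the observed degree sequence, so for every
# observed degree class k we look for the hidden degree kappa whose ensemble
# expected degree kbar(kappa) equals k. kbar is the position-averaged sum of
# connection probabilities,
#
#   kbar(kappa_i) = Gamma((D+1)/2) / (sqrt(pi) Gamma(D/2)) *
#                   sum_{j != i} \int_0^pi sin^(D-1)(t) dt /
#                                (1 + (R t / (mu kappa_i kappa_j)^(1/D))^beta),
#
# and the fixed point is reached by the stochastic iteration
# kappa <- |kappa + (k - kbar(kappa)) u|, u ~ U(0, 1), per degree class.

# Expected degrees of the class kappas against the class table itself,
# excluding each class's own node from its sum. Returns one value per class.
# Compiled kernel; same quadrature as fermi_sin_integral().
expected_degrees_classes <- function(kappa, mult, params) {
  gl <- gauss_legendre(32L)
  expected_degrees_cpp(as.numeric(kappa), as.integer(mult), params$D,
                       if (is.infinite(params$beta)) -1 else params$beta,
                       params$mu, params$R, sd_prefactor(params$D),
                       gl$nodes, gl$weights)
}

#' Model expected degree of a node given a degree-class table
#'
#' Evaluates the S^D ensemble expected degree \eqn{\bar k(\kappa)} of a node
#' with hidden degree `kappa` against the population described by a
#' [infer_hidden_degrees()] table (classes weighted by multiplicity). When
#' `kappa` matches a class kappa exactly, that class contributes
#' `multiplicity - 1` (the node does not pair with itself); any other value is
#' treated as an external probe node.
#'
#' @param kappa hidden degree(s) to evaluate, positive.
#' @param table a `degree_class_table` (or a data frame with columns `kappa`
#'   and `multiplicity`).
#' @param params an [sd_params()] object (finite or infinite `beta`).
#' @return Expected degree(s), same length as `kappa`.
#' @export
expected_degree <- function(kappa, table, params) {
  stopifnot(inherits(params, "sd_params"))
  tab <- as.data.frame(table)
  if (!all(c("kappa", "multiplicity") %in% names(tab)) || nrow(tab) == 0) {
    stop("`table` must have columns `kappa` and `multiplicity`", call. = FALSE)
  }
  if (any(kappa <= 0)) stop("`kappa` must be positive", call. = FALSE)
  n <- length(kappa)
  t <- exp((log(params$mu) + outer(log(kappa), log(tab$kappa), "+")) /
             params$D) / params$R
  I <- matrix(fermi_sin_integral(as.numeric(t), params$D, params$beta),
              n, nrow(tab))
  w <- matrix(tab$multiplicity, n, nrow(tab), byrow = TRUE)
  self <- outer(kappa, tab$kappa, "==")
  w[self] <- w[self] - 1
  sd_prefactor(params$D) * rowSums(I * w)
}

#' Infer hidden degrees from an observed degree sequence
#'
#' Iteratively adjusts one hidden degree per observed degree class until the
#' maximal deviation between expected and observed degrees,
#' \eqn{\epsilon_{max} = \max_k |\bar k(\kappa_k) - k|}, falls below
#' `tolerance` (default 1). Starting from \eqn{\kappa = k}, each
#' non-converged sweep updates every class with
#' \eqn{\kappa \leftarrow |\kappa + (k - \bar k(\kappa)) u|},
#' `u ~ U(0, 1)`; the random damping keeps the iteration out of cycles, and
#' the best iterate is retained since a step can transiently worsen
#' \eqn{\epsilon_{max}}. If the additive correction has not converged after
#' 20 sweeps (at larger `D` the \eqn{\kappa^{1/D}} compression makes
#' \eqn{\bar k} nearly flat in \eqn{\kappa}, stalling it), subsequent sweeps
#' use the log-domain step \eqn{\kappa \leftarrow \kappa (k/\bar k)^u}
#' towards the same fixed point.
#'
#' @param degree_sequence observed degrees, all at least 1 (drop isolated
#'   nodes upstream). Length must equal `params$N`.
#' @param params an [sd_params()] object; its `mean_degree` should be the
#'   observed mean degree (as [run_pipeline()] arranges).
#' @param tolerance convergence threshold on `epsilon_max` (degree units).
#' @param seed optional integer seed (the update is stochastic).
#' @param max_iter sweep cap; on non-convergence the best iterate is returned
#'   with `converged = FALSE` (a warning, not an error).
#' @param kappa_init optional warm start: per-class starting kappas (one per
#'   degree class, ascending). The ensemble builder chains inferences over
#'   neighboring betas this way; the fixed point targeted (and the tolerance)
#'   are unchanged, only the starting point moves.
#' @return An object of class `"degree_class_table"`: a data frame with one
#'   row per degree class (`k`, `kappa`, `multiplicity`) and attributes
#'   `epsilon_max`, `converged`, `iterations`, `params`.
#' @export
infer_hidden_degrees <- function(degree_sequence, params, tolerance = 1,
                                 seed = NULL, max_iter = 200L,
                                 kappa_init = NULL) {
  stopifnot(inherits(params, "sd_params"))
  degree_sequence <- as.numeric(degree_sequence)
  if (length(degree_sequence) != params$N) {
    stop("`params$N` must equal the number of nodes in the degree sequence",
         call. = FALSE)
  }
  if (any(degree_sequence < 1)) {
    stop("all degrees must be >= 1; drop isolated nodes first", call. = FALSE)
  }
  k <- sort(unique(degree_sequence))
  mult <- as.integer(tabulate(match(degree_sequence, k), nbins = length(k)))

  if (!is.null(kappa_init) &&
      (length(kappa_init) != length(k) || any(kappa_init <= 0))) {
    stop("`kappa_init` must hold one positive kappa per degree class",
         call. = FALSE)
  }
  with_seed(seed, {
    kappa <- if (is.null(kappa_init)) k else as.numeric(kappa_init)
    best <- list(kappa = kappa, eps = Inf, iter = 0L)
    converged <- FALSE
    # The additive update stalls when expected degrees are nearly flat in
    # kappa (the kappa^(1/D) compression at larger D can require hub kappas
    # orders of magnitude above their degrees), so after `stall` sweeps
    # without convergence the correction switches to the log domain, which
    # targets the same fixed point with multiplicative steps.
    stall <- min(20L, max_iter)
    for (iter in seq_len(max_iter)) {
      kbar <- expected_degrees_classes(kappa, mult, params)
      eps <- max(abs(kbar - k))
      if (eps < best$eps) best <- list(kappa = kappa, eps = eps, iter = iter)
      if (eps <= tolerance) {
        converged <- TRUE
        break
      }
      u <- stats::runif(length(k))
      if (iter <= stall) {
        kappa <- abs(kappa + (k - kbar) * u)
      } else {
        kappa <- kappa * (k / kbar)^u
      }
      kappa[kappa < 1e-10] <- 1e-10
    }
    if (!converged) {
      warning(sprintf(
        "hidden-degree inference did not reach tolerance %g in %d sweeps (best epsilon_max = %.3g)",
        tolerance, max_iter, best$eps), call. = FALSE)
    }
    structure(
      data.frame(k = k, kappa = best$kappa, multiplicity = mult),
      epsilon_max = best$eps,
      converged = converged,
      iterations = best$iter,
      params = params,
      class = c("degree_class_table", "data.frame")
    )
  })
}

# Map a degree sequence onto per-node kappas through a class table.
kappas_from_table <- function(degree_sequence, table) {
  table$kappa[match(degree_sequence, table$k)]
}

#' @export
print.degree_class_table <- function(x, ...) {
  cat(sprintf(
    "degree-class table: %d classes, epsilon_max = %.3g (%s after %d sweeps)\n",
    nrow(x), attr(x, "epsilon_max"),
    if (attr(x, "converged")) "converged" else "NOT converged",
    attr(x, "iterations")))
  NextMethod()
}
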