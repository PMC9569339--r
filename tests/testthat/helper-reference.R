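# Reference per-node hidden-degree iteration (no degree-class grouping).
# Shares the package's integral kernel: the check targets the class-grouping
# optimization, not the quadrature.
infer_hidden_degrees_nodewise <- function(degs, params, tolerance = 1,
                                          seed = NULL, max_iter = 200L) {
  n <- length(degs)
  expected_all <- function(kappa) {
    t <- exp((log(params$mu) + outer(log(kappa), log(kappa), "+")) /
               params$D) / params$R
    I <- matrix(netdim:::fermi_sin_integral(as.numeric(t), params$D,
                                            params$beta), n, n)
    diag(I) <- 0
    netdim:::sd_prefactor(params$D) * rowSums(I)
  }
  netdim:::with_seed(seed, {
    kappa <- as.numeric(degs)
    best <- list(kappa = kappa, eps = Inf)
    for (iter in seq_len(max_iter)) {
      kbar <- expected_all(kappa)
      eps <- max(abs(kbar - degs))
      if (eps < best$eps) best <- list(kappa = kappa, eps = eps)
      if (eps <= tolerance) break
      kappa <- abs(kappa + (degs - kbar) * stats::runif(n))
      kappa[kappa < 1e-10] <- 1e-10
    }
    data.frame(k = degs, kappa = best$kappa)
  })
}
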