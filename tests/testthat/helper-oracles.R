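# Independent oracles used across the suite.

# Raw PRF sampling-weight integrand (no algebraic simplification).
prf_integrand <- function(x, S, i, n) {
  choose(n, i) * x^(i - 1) * (1 - x)^(n - i - 1) *
    (exp(S) - exp(S * x)) / (exp(S) - 1)
}

# Adaptive-quadrature oracle for H(S, i, n), split at the boundary layer.
oracle_H <- function(S, i, n, rel.tol = 1e-12) {
  if (abs(S) < 1e-12) return(1 / i)
  cut <- if (abs(S) > 50) min(1, 300 / abs(S)) else 1
  v <- integrate(prf_integrand, 0, cut, S = S, i = i, n = n,
                 rel.tol = rel.tol, subdivisions = 800L)$value
  if (cut < 1)
    v <- v + tryCatch(
      integrate(prf_integrand, cut, 1, S = S, i = i, n = n,
                rel.tol = rel.tol, subdivisions = 800L)$value,
      error = function(e) 0)
  v
}

# Adaptive (Gauss-Kronrod) oracle for the gamma-mixed selected spectrum on
# the quantile scale -- an independent integration scheme from the package's
# fixed composite Gauss-Legendre rule.
oracle_unit_selected <- function(b, S_d, i, n) {
  h <- function(u) vapply(u, function(uu) {
    dfeload::sampling_weight(-qgamma(uu, b, scale = -S_d / b), i, n,
                             nodes_per_cell = 24)
  }, numeric(1))
  brk <- c(0, 1e-14, 1e-11, 1e-8, 1e-6, 1e-4, 1e-2, 0.1, 0.5, 0.9, 0.99, 1)
  tot <- 0
  for (j in seq_len(length(brk) - 1L))
    tot <- tot + integrate(h, brk[j], brk[j + 1], rel.tol = 1e-9,
                           subdivisions = 500L)$value
  tot
}

# quick simulated sfs_pair around exact expectations (no noise)
exact_pair <- function(params, n, L_sel, L_neut, n_nodes = 384) {
  e <- dfeload::expected_sfs(params, n, L_sel, L_neut, n_nodes = n_nodes)
  dfeload::sfs_pair(
    dfeload::new_sfs(e$expected[e$class == "neutral_4fold"], n, L_neut,
                     "neutral_4fold"),
    dfeload::new_sfs(e$expected[e$class == "selected_0fold"], n, L_sel,
                     "selected_0fold"))
}
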