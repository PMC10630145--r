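# Poisson-random-field DFE model: gamma deleterious + exponential beneficial
# density, selection-dependent SFS sampling weights, expected spectra with
# ancestral-misidentification and distortion corrections, likelihood,
# discretization and alpha_DFE.

#' DFE model parameters
#'
#' Bundles all parameters of the site-frequency-spectrum model: the gamma
#' deleterious component (shape `b`, mean scaled effect `S_d` <= 0, units of
#' Ne*s), the exponential beneficial component (mixture weight `p_b`, mean
#' `S_b` > 0), the ancestral-misidentification rate `eps_anc`, the per-class
#' distortion (nuisance) vector `r` with `r[1] == 1`, and the per-site scaled
#' mutation rate `theta`.
#'
#' @param b Gamma shape of the deleterious DFE (> 0).
#' @param S_d Mean scaled selection coefficient of deleterious mutations
#'   (<= 0, units Ne*s).
#' @param p_b Probability that a new mutation is beneficial (in `[0, 1)`).
#' @param S_b Mean scaled effect of beneficial mutations (> 0).
#' @param eps_anc Ancestral misidentification rate (in `[0, 0.5)`).
#' @param r Distortion vector `r[i]`, one entry per frequency class
#'   `i = 1..n-1`, with `r[1]` fixed at 1; `NULL` means no distortion.
#' @param theta Per-site scaled mutation rate (> 0).
#' @return An object of class `dfe_params`.
#' @export
dfe_params <- function(b, S_d, p_b = 0, S_b = 1, eps_anc = 0, r = NULL,
                       theta = 0.008) {
  stopifnot(is.numeric(b), length(b) == 1, b > 0)
  if (S_d > 0) stop_dfeload("`S_d` must be <= 0 (mean deleterious effect)")
  if (S_d == 0 && p_b < 1) stop_dfeload("`S_d` = 0 gives a degenerate gamma")
  stopifnot(p_b >= 0, p_b < 1, S_b > 0, eps_anc >= 0, eps_anc < 0.5, theta > 0)
  if (!is.null(r)) {
    stopifnot(all(r > 0))
    if (abs(r[1] - 1) > 1e-12)
      stop_dfeload("`r[1]` is the reference class and must equal 1")
  }
  structure(list(b = b, S_d = S_d, p_b = p_b, S_b = S_b, eps_anc = eps_anc,
                 r = r, theta = theta),
            class = "dfe_params")
}

#' @export
print.dfe_params <- function(x, ...) {
  cat("<dfe_params>  b =", signif(x$b, 4), " S_d =", signif(x$S_d, 4),
      " p_b =", signif(x$p_b, 4), " S_b =", signif(x$S_b, 4),
      " eps_anc =", signif(x$eps_anc, 4), " theta =", signif(x$theta, 4), "\n")
  if (!is.null(x$r)) cat("  r:", paste(signif(x$r, 3), collapse = " "), "\n")
  invisible(x)
}

#' Density of the distribution of fitness effects
#'
#' Mixture density over scaled selection coefficients `S` (units Ne*s): with
#' probability `1 - p_b` a mutation is deleterious with `-S` gamma-distributed
#' (shape `b`, mean `|S_d|`); with probability `p_b` it is beneficial with `S`
#' exponential with mean `S_b`.
#'
#' @param params A [dfe_params()] object.
#' @param S Numeric vector of scaled selection coefficients.
#' @return Density values, same length as `S`.
#' @export
dfe_density <- function(params, S) {
  p <- params
  del <- (1 - p$p_b) * stats::dgamma(-S, shape = p$b, scale = -p$S_d / p$b)
  ben <- p$p_b * dexp(S, rate = 1 / p$S_b)
  out <- ifelse(S < 0, del, ifelse(S > 0, ben, 0))
  out[S == 0] <- 0
  out
}

#' Expected relative SFS contribution of a mutation with scaled effect S
#'
#' The Poisson-random-field sampling weight
#' `H(S, i, n) = C(n,i) * Int_0^1 x^i (1-x)^(n-i) (e^S - e^(Sx)) /
#' ((e^S - 1) x (1-x)) dx`, the expected relative number of sites at derived
#' count `i` in a sample of `n` haplotypes, relative to the neutral influx.
#' `H(0, i, n) = 1/i` (neutral limit). Evaluated by composite Gauss-Legendre
#' quadrature on a fixed endpoint-graded grid; the endpoint singularities are
#' removed analytically and the kernel is computed with `expm1` so that the
#' result is stable for `|S|` up to the clipping bound 1e8.
#'
#' @param S Scaled selection coefficients (any sign); values beyond +-1e8 are
#'   clipped.
#' @param i Derived-allele count class(es), `1 <= i <= n-1`.
#' @param n Haplotype sample size.
#' @param nodes_per_cell Gauss-Legendre nodes per grid cell.
#' @return If `S` and `i` both have length > 1, a `length(S) x length(i)`
#'   matrix; otherwise a vector.
#' @export
sampling_weight <- function(S, i, n, nodes_per_cell = 12) {
  stopifnot(all(i >= 1), all(i <= n - 1), n >= 2)
  S <- pmin(pmax(S, -1e8), 1e8)
  pw <- prf_weight_matrix(n, nodes_per_cell)
  G <- prf_kernel(S, pw$x)
  H <- G %*% t(pw$W[i, , drop = FALSE])
  if (length(S) == 1L || length(i) == 1L) drop(H) else H
}

# Unit-theta expected polymorphic-site density for the selected class:
# s_i = Int phi(S) H(S, i, n) dS, by Gauss-Legendre on the quantile transform
# of each mixture component (n_nodes nodes per component).
unit_selected_sfs <- function(b, S_d, p_b, S_b, n, n_nodes = 384,
                              nodes_per_cell = 12) {
  s <- (1 - p_b) * unit_del_sfs(b, S_d, n, n_nodes, nodes_per_cell)
  if (p_b > 0)
    s <- s + p_b * unit_ben_sfs(S_b, n, n_nodes, nodes_per_cell)
  s
}

# gamma (deleterious) component of the selected spectrum, per unit theta*L
unit_del_sfs <- function(b, S_d, n, n_nodes = 384, nodes_per_cell = 12) {
  gl <- u_grid(n_nodes)
  S_del <- -qgamma(gl$x, shape = b, scale = -S_d / b)
  H_del <- sampling_weight(S_del, seq_len(n - 1L), n, nodes_per_cell)
  as.numeric(gl$w %*% H_del)
}

# exponential (beneficial) component
unit_ben_sfs <- function(S_b, n, n_nodes = 384, nodes_per_cell = 12) {
  gl <- u_grid(n_nodes)
  S_ben <- qexp(gl$x, rate = 1 / S_b)
  H_ben <- sampling_weight(S_ben, seq_len(n - 1L), n, nodes_per_cell)
  as.numeric(gl$w %*% H_ben)
}

# eps-mix: m_i <- (1 - eps) m_i + eps m_(n-i)
mix_eps <- function(m, eps) {
  if (eps == 0) return(m)
  (1 - eps) * m + eps * rev(m)
}

#' Expected site frequency spectra under the DFE model
#'
#' Expected Poisson means for the neutral (4-fold) and selected (0-fold)
#' unfolded spectra: neutral influx `theta * L_neut / i`; selected influx
#' `theta * L_sel * Int phi(S) H(S, i, n) dS`; then the ancestral
#' misidentification mix `(1-eps) m_i + eps m_(n-i)` and finally the
#' per-class distortion `r_i` (applied to both classes in that order).
#'
#' @param params A [dfe_params()] object.
#' @param n Haplotype sample size of the spectra.
#' @param L_sel,L_neut Total selected / neutral sites (monomorphic +
#'   polymorphic).
#' @param n_nodes Gauss-Legendre nodes per DFE mixture component for the
#'   integral over `S`.
#' @param nodes_per_cell Nodes per cell of the inner frequency grid.
#' @return A tibble with columns `class` (`"neutral_4fold"`/`"selected_0fold"`),
#'   `i` and `expected`.
#' @export
expected_sfs <- function(params, n, L_sel, L_neut, n_nodes = 384,
                         nodes_per_cell = 12) {
  stopifnot(L_sel > 0, L_neut > 0, n >= 2)
  p <- params
  i <- seq_len(n - 1L)
  m_neut <- p$theta * L_neut / i
  s <- unit_selected_sfs(p$b, p$S_d, p$p_b, p$S_b, n, n_nodes, nodes_per_cell)
  m_sel <- p$theta * L_sel * s
  m_neut <- mix_eps(m_neut, p$eps_anc)
  m_sel <- mix_eps(m_sel, p$eps_anc)
  if (!is.null(p$r)) {
    stopifnot(length(p$r) == n - 1L)
    m_neut <- p$r * m_neut
    m_sel <- p$r * m_sel
  }
  tibble(class = rep(c("neutral_4fold", "selected_0fold"), each = n - 1L),
         i = rep(i, 2L),
         expected = c(m_neut, m_sel))
}

#' Poisson log-likelihood of an SFS pair under the DFE model
#'
#' Sum over both site classes and frequency classes `i = 1..n-1` of the
#' Poisson log-probability of the observed count given the expected count
#' from [expected_sfs()]. Monomorphic totals are not modelled (they enter
#' only through `L`). Fractional (projected) counts are rounded to the
#' nearest integer unless `round_counts = FALSE`, in which case a continuous
#' Poisson density (gamma-function form) is used.
#'
#' @param params A [dfe_params()] object (including `theta` and, optionally,
#'   `r`).
#' @param sfs_pair An [sfs_pair()] object.
#' @param round_counts Round fractional counts to integers (default TRUE).
#' @inheritParams expected_sfs
#' @return Scalar log-likelihood (`-Inf`, with a warning, if any expected
#'   count is zero where the observed count is positive).
#' @export
dfe_loglik <- function(params, sfs_pair, round_counts = TRUE, n_nodes = 384,
                       nodes_per_cell = 12) {
  stopifnot(inherits(sfs_pair, "sfs_pair"))
  n <- sfs_pair$neutral$n
  e <- expected_sfs(params, n, L_sel = sfs_pair$selected$L,
                    L_neut = sfs_pair$neutral$L, n_nodes = n_nodes,
                    nodes_per_cell = nodes_per_cell)
  x <- c(sfs_pair$neutral$xi, sfs_pair$selected$xi)
  if (round_counts) x <- round(x)
  mu <- e$expected
  if (any(mu == 0 & x > 0)) {
    warn("zero expected count with positive observed count: log-likelihood is -Inf")
    return(-Inf)
  }
  ok <- !(x == 0 & mu == 0)
  sum(x[ok] * log(mu[ok]) - mu[ok] - lgamma(x[ok] + 1))
}

#' Discretize the DFE into scaled-effect bins
#'
#' Probability mass of the fitted DFE in each scaled-selection (`Ne*s`)
#' interval, from the gamma and exponential component CDFs weighted by
#' `(1 - p_b, p_b)`.
#'
#' @param params A [dfe_params()] object.
#' @param bin_edges Ordered breakpoints; default
#'   `c(-Inf, -100, -10, -1, 0, 1, Inf)`.
#' @return A tibble with columns `lower`, `upper`, `mass`.
#' @export
discretize_dfe <- function(params, bin_edges = c(-Inf, -100, -10, -1, 0, 1, Inf)) {
  stopifnot(!is.unsorted(bin_edges), length(bin_edges) >= 2)
  p <- params
  # P(S <= s) of the mixture
  cdf <- function(s) {
    del <- (1 - p$p_b) *
      pgamma(-s, shape = p$b, scale = -p$S_d / p$b, lower.tail = FALSE)
    ben <- (1 - p$p_b) + p$p_b * pexp(pmax(s, 0), rate = 1 / p$S_b)
    ifelse(s < 0, del, ben)
  }
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  tibble(lower = lo, upper = hi, mass = cdf(hi) - cdf(lo))
}

#' Rate of adaptive substitution implied by the DFE
#'
#' `alpha_DFE`: the fraction of substitutions driven by beneficial mutations
#' with scaled effect at least `S_min`, computed as the ratio of
#' `Int_(S_min)^Inf phi(S) omega(S) dS` to `Int phi(S) omega(S) dS`, where
#' `omega(S) = S / (1 - e^(-S))` is the relative fixation rate
#' (`omega(0) = 1`). The lower bound excludes effectively neutral beneficial
#' mutations whose inclusion would inflate the estimate.
#'
#' @param params A [dfe_params()] object.
#' @param S_min Lower scaled-effect bound for a substitution to count as
#'   adaptive (default 5).
#' @param n_nodes Quadrature nodes per component.
#' @return Scalar `alpha` in `[0, 1]`.
#' @export
alpha_dfe <- function(params, S_min = 5, n_nodes = 384) {
  p <- params
  if (p$p_b == 0) return(0)
  gl <- u_grid(n_nodes)
  # beneficial component, full and truncated at S_min (quantile transform)
  ben_full <- sum(gl$w * fixation_weight(qexp(gl$x, rate = 1 / p$S_b)))
  u0 <- pexp(S_min, rate = 1 / p$S_b)
  glt <- gl_rule(n_nodes, u0, 1)
  ben_trunc <- sum(glt$w * fixation_weight(qexp(glt$x, rate = 1 / p$S_b)))
  del <- sum(gl$w * fixation_weight(
    -qgamma(gl$x, shape = p$b, scale = -p$S_d / p$b)))
  num <- p$p_b * ben_trunc
  den <- p$p_b * ben_full + (1 - p$p_b) * del
  num / den
}
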