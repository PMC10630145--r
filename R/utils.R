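# Quadrature grids, shared numeric helpers.

# Gauss-Legendre nodes/weights on (a, b), cached.
gl_rule <- function(k, a = 0, b = 1) {
  key <- sprintf("gl_%d_%.17g_%.17g", k, a, b)
  got <- get0(key, envir = .dfeload_cache)
  if (!is.null(got)) return(got)
  r <- pracma::gaussLegendre(k, a, b)
  out <- list(x = r$x, w = r$w)
  assign(key, out, envir = .dfeload_cache)
  out
}

# Composite Gauss-Legendre grid on (0, 1), geometrically graded towards both
# endpoints so that boundary layers of width down to ~1e-8 (strong selection)
# are resolved with a fixed node set.
x_grid <- function(nodes_per_cell = 12) {
  key <- sprintf("xgrid_%d", nodes_per_cell)
  got <- get0(key, envir = .dfeload_cache)
  if (!is.null(got)) return(got)
  brk <- c(0, 10^seq(-8, -1, by = 0.5), seq(0.2, 0.9, by = 0.1),
           0.99, 0.999, 0.9999, 1)
  xs <- ws <- numeric(0)
  for (j in seq_len(length(brk) - 1L)) {
    r <- gl_rule(nodes_per_cell, brk[j], brk[j + 1L])
    xs <- c(xs, r$x); ws <- c(ws, r$w)
  }
  out <- list(x = xs, w = ws)
  assign(key, out, envir = .dfeload_cache)
  out
}

# Composite Gauss-Legendre grid on the quantile (probability) scale used for
# the outer integral over the DFE: graded towards both endpoints, where the
# quantile transform of a gamma with small/large shape has algebraic
# singularities in its higher derivatives.
u_grid <- function(n_nodes = 384) {
  key <- sprintf("ugrid_%d", n_nodes)
  got <- get0(key, envir = .dfeload_cache)
  if (!is.null(got)) return(got)
  brk <- c(0, 10^seq(-12, -2, by = 0.5), 0.02, 0.03, 0.05, 0.07,
           seq(0.1, 0.9, by = 0.05), 0.95, 0.99, 0.999, 0.9999, 0.999999, 1)
  per_cell <- max(2L, round(n_nodes / (length(brk) - 1L)))
  xs <- ws <- numeric(0)
  for (j in seq_len(length(brk) - 1L)) {
    r <- gl_rule(per_cell, brk[j], brk[j + 1L])
    xs <- c(xs, r$x); ws <- c(ws, r$w)
  }
  out <- list(x = xs, w = ws)
  assign(key, out, envir = .dfeload_cache)
  out
}

# Binomial-kernel weight matrix for the PRF sampling integral at sample size n:
# W[i, k] = choose(n, i) x_k^(i-1) (1-x_k)^(n-i-1) w_k, i = 1..n-1.
# The 1/(x(1-x)) factor of the integrand is cancelled analytically here.
prf_weight_matrix <- function(n, nodes_per_cell = 12) {
  key <- sprintf("prfW_%d_%d", n, nodes_per_cell)
  got <- get0(key, envir = .dfeload_cache)
  if (!is.null(got)) return(got)
  g <- x_grid(nodes_per_cell)
  i <- seq_len(n - 1L)
  lw <- outer(i, g$x, function(ii, xx) {
    lchoose(n, ii) + (ii - 1) * log(xx) + (n - ii - 1) * log1p(-xx)
  })
  W <- exp(lw) * rep(g$w, each = n - 1L)
  out <- list(W = W, x = g$x)
  assign(key, out, envir = .dfeload_cache)
  out
}

# (e^S - e^(Sx)) / (e^S - 1), evaluated stably for either sign of S.
# Limit S -> 0 is (1 - x); no overflow for |S| up to the clipping bound.
prf_kernel <- function(S, x) {
  # returns length(S) x length(x) matrix
  nS <- length(S); nx <- length(x)
  G <- matrix(0, nS, nx)
  tiny <- abs(S) < 1e-10
  if (any(tiny)) G[tiny, ] <- matrix(rep(1 - x, each = sum(tiny)), sum(tiny), nx)
  neg <- S < 0 & !tiny
  if (any(neg)) {
    Sn <- S[neg]
    G[neg, ] <- exp(outer(Sn, x)) * expm1(outer(Sn, 1 - x)) / expm1(Sn)
  }
  pos <- S > 0 & !tiny
  if (any(pos)) {
    Sp <- S[pos]
    G[pos, ] <- expm1(outer(Sp, x - 1)) / expm1(-Sp)
  }
  G
}

# Relative fixation rate of a semidominant mutation with scaled effect S
# (units Ne*s): omega(S) = S / (1 - e^(-S)), omega(0) = 1.
fixation_weight <- function(S) {
  out <- ifelse(abs(S) < 1e-10, 1, S / (-expm1(-S)))
  out[is.nan(out)] <- 0 # S very negative: e^(-S) overflows, rate -> 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dfeload <- function(...) abort(paste0(...), class = "dfeload_error")
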