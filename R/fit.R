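# Fitting protocol: multi-start box-constrained maximization of the profiled
# Poisson likelihood, the four-model set (full/deleterious-only DFE, with and
# without the ancestral-error rate), and AIC model averaging.
#
# theta and the distortion vector r enter the expected spectrum only through a
# per-frequency-class scale factor c_i = theta * r_i that multiplies both site
# classes. For fixed shape parameters the Poisson MLE of each c_i is
# closed-form, so the optimizer only ever sees the shape parameters
# (b, S_d, and optionally p_b, S_b, eps_anc); the profiled maximum equals the
# joint maximum because (theta, r_2..r_(n-1)) <-> (c_1..c_(n-1)) is a
# bijection.

#' The four DFE model specifications
#'
#' Model 1: full DFE (deleterious + beneficial) with ancestral-error rate
#' `eps_anc`; model 2: full DFE without `eps_anc`; model 3: deleterious-only
#' with `eps_anc`; model 4: deleterious-only without `eps_anc`.
#'
#' @param include_beneficial Fit the exponential beneficial component.
#' @param include_eps Fit the ancestral misidentification rate.
#' @return A `dfe_model_spec` object.
#' @export
dfe_model_spec <- function(include_beneficial = TRUE, include_eps = TRUE) {
  id <- paste0(if (include_beneficial) "full" else "del",
               if (include_eps) "_eps" else "")
  structure(list(include_beneficial = include_beneficial,
                 include_eps = include_eps, id = id),
            class = "dfe_model_spec")
}

#' @rdname dfe_model_spec
#' @export
dfe_model_set <- function() {
  list(m1 = dfe_model_spec(TRUE, TRUE),  m2 = dfe_model_spec(TRUE, FALSE),
       m3 = dfe_model_spec(FALSE, TRUE), m4 = dfe_model_spec(FALSE, FALSE))
}

# default parameter boxes (original scale)
dfe_bounds <- function() {
  list(b = c(0.01, 10), S_d_abs = c(1e-2, 1e8), p_b = c(0, 0.5),
       S_b = c(1e-3, 100), eps_anc = c(0, 0.3))
}

# transformed-space boxes and names for a model spec
spec_box <- function(spec, bounds = dfe_bounds()) {
  nm <- c("log_b", "log_Sd")
  lo <- c(log(bounds$b[1]), log(bounds$S_d_abs[1]))
  hi <- c(log(bounds$b[2]), log(bounds$S_d_abs[2]))
  if (spec$include_beneficial) {
    nm <- c(nm, "p_b", "log_Sb")
    lo <- c(lo, bounds$p_b[1], log(bounds$S_b[1]))
    hi <- c(hi, bounds$p_b[2], log(bounds$S_b[2]))
  }
  if (spec$include_eps) {
    nm <- c(nm, "eps")
    lo <- c(lo, bounds$eps_anc[1])
    hi <- c(hi, bounds$eps_anc[2])
  }
  list(names = nm, lower = setNames(lo, nm), upper = setNames(hi, nm))
}

# transformed vector -> shape parameter list; linear-scale parameters are
# clamped because L-BFGS-B can overshoot a box bound by rounding error
untransform_par <- function(par, spec) {
  list(b = exp(par[["log_b"]]), S_d = -exp(par[["log_Sd"]]),
       p_b = if (spec$include_beneficial)
         min(max(par[["p_b"]], 0), 0.999) else 0,
       S_b = if (spec$include_beneficial) exp(par[["log_Sb"]]) else 1,
       eps = if (spec$include_eps)
         min(max(par[["eps"]], 0), 0.4999) else 0)
}

# Profiled log-likelihood machinery for one SFS pair. Returns a list of
# closures sharing the prepared data.
profile_objective <- function(sfs_pair, spec, n_nodes = 384,
                              nodes_per_cell = 12, round_counts = TRUE) {
  n <- sfs_pair$neutral$n
  xn <- sfs_pair$neutral$xi
  xs <- sfs_pair$selected$xi
  if (round_counts) { xn <- round(xn); xs <- round(xs) }
  L_n <- sfs_pair$neutral$L
  L_s <- sfs_pair$selected$L
  i <- seq_len(n - 1L)
  un0 <- L_n / i
  lfact <- lgamma(xn + 1) + lgamma(xs + 1)
  xtot <- xn + xs

  # memoized mixture components: gradient steps perturb one coordinate at a
  # time, and in joint (shared-parameter) fits the gamma component is common
  # to every dataset, so caching (b, S_d) and S_b separately saves most evals
  memo <- new.env(parent = emptyenv())
  del_of <- function(b, S_d) {
    key <- sprintf("d%.17g_%.17g", b, S_d)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    if (length(ls(memo)) > 64) rm(list = ls(memo), envir = memo)
    v <- unit_del_sfs(b, S_d, n, n_nodes, nodes_per_cell)
    assign(key, v, envir = memo)
    v
  }
  ben_of <- function(S_b) {
    key <- sprintf("b%.17g", S_b)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    v <- unit_ben_sfs(S_b, n, n_nodes, nodes_per_cell)
    assign(key, v, envir = memo)
    v
  }

  eval_shape <- function(b, S_d, p_b, S_b, eps) {
    sel <- (1 - p_b) * del_of(b, S_d)
    if (p_b > 0) sel <- sel + p_b * ben_of(S_b)
    us <- L_s * sel
    un <- mix_eps(un0, eps)
    us <- mix_eps(us, eps)
    chat <- ifelse(xtot > 0, xtot / (un + us), 0)
    en <- chat * un
    es <- chat * us
    ok_n <- !(xn == 0 & en == 0); ok_s <- !(xs == 0 & es == 0)
    ll <- sum(xn[ok_n] * log(en[ok_n]) - en[ok_n]) +
      sum(xs[ok_s] * log(es[ok_s]) - es[ok_s]) - sum(lfact)
    list(ll = ll, chat = chat)
  }

  nll <- function(par) {
    sh <- untransform_par(setNames(par, spec_box(spec)$names), spec)
    v <- eval_shape(sh$b, sh$S_d, sh$p_b, sh$S_b, sh$eps)$ll
    if (!is.finite(v)) 1e12 else -v
  }

  list(nll = nll, eval_shape = eval_shape, n = n, L_n = L_n, L_s = L_s,
       xn = xn, xs = xs)
}

# deterministic coarse grid scan used as the first start
grid_start <- function(obj, spec) {
  bs <- c(0.05, 0.15, 0.4, 1, 2.5)
  sd <- -10^(0:6)
  best <- NULL; best_ll <- -Inf
  for (b in bs) for (s in sd) {
    ll <- obj$eval_shape(b, s, 0, 1, 0)$ll
    if (ll > best_ll) { best_ll <- ll; best <- c(b = b, S_d = s) }
  }
  par <- c(log_b = log(best[["b"]]), log_Sd = log(-best[["S_d"]]))
  if (spec$include_beneficial) par <- c(par, p_b = 0.02, log_Sb = log(5))
  if (spec$include_eps) par <- c(par, eps = 0.02)
  par
}

near_bound_flags <- function(par, lower, upper) {
  f <- function(p, b) {
    if (b == 0) abs(p) < 1e-4 else abs(p - b) < 0.01 * abs(b)
  }
  mapply(function(p, lo, hi) f(p, lo) || f(p, hi), par, lower, upper)
}

num_gradient <- function(fn, par, h = 1e-5) {
  vapply(seq_along(par), function(k) {
    e <- par; e[k] <- e[k] + h; up <- fn(e)
    e[k] <- par[k] - h; dn <- fn(e)
    (up - dn) / (2 * h)
  }, numeric(1))
}

#' Fit one DFE model to an SFS pair
#'
#' Box-constrained quasi-Newton (L-BFGS-B) maximization of the profiled
#' Poisson likelihood from `n_starts` initial points: one deterministic
#' coarse-grid start plus random starts drawn uniformly within the
#' (log-transformed) parameter boxes. Positive parameters are optimized on
#' the log scale. The best run whose free parameters are not within 1%
#' (relative) of a box bound is returned; if every run is near a bound the
#' best run is returned flagged.
#'
#' @param sfs_pair An [sfs_pair()].
#' @param spec A [dfe_model_spec()]; default model 1 (full DFE with
#'   `eps_anc`).
#' @param n_starts Number of optimizer starts (>= 1, default 5).
#' @param seed Integer seed for the random starts (optional).
#' @param control List: `n_nodes` (quadrature nodes per DFE component, 200),
#'   `nodes_per_cell` (12), `factr`, `maxit` for `optim`, `round_counts`,
#'   and `bounds` to override [dfe_bounds()].
#' @return A `dfe_fit` object: MLE parameters (including the profiled
#'   `theta` and distortion vector `r`), log-likelihood, AIC, gradient norm,
#'   convergence and near-bound flags.
#' @export
fit_dfe <- function(sfs_pair, spec = dfe_model_spec(), n_starts = 5,
                    seed = NULL, control = list()) {
  stopifnot(inherits(sfs_pair, "sfs_pair"), n_starts >= 1)
  ctl <- modifyList(list(n_nodes = 384, nodes_per_cell = 12, factr = 1e7,
                         maxit = 300, round_counts = TRUE,
                         bounds = dfe_bounds()), control)
  box <- spec_box(spec, ctl$bounds)
  obj <- profile_objective(sfs_pair, spec, ctl$n_nodes, ctl$nodes_per_cell,
                           ctl$round_counts)
  starts <- list(grid_start(obj, spec))
  if (n_starts > 1) {
    rand <- withr::with_seed(seed %||% 1L, {
      lapply(seq_len(n_starts - 1L), function(k) {
        setNames(runif(length(box$names), box$lower, box$upper), box$names)
      })
    })
    starts <- c(starts, rand)
  }
  runs <- lapply(starts, function(st) {
    fit <- tryCatch(
      optim(st, obj$nll, method = "L-BFGS-B", lower = box$lower,
            upper = box$upper,
            control = list(factr = ctl$factr, maxit = ctl$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = setNames(fit$par, box$names), value = fit$value,
         conv = fit$convergence == 0)
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (!length(runs)) stop_dfeload("all optimizer runs failed")
  nb <- vapply(runs, function(r)
    any(near_bound_flags(r$par, box$lower, box$upper)), logical(1))
  vals <- vapply(runs, `[[`, numeric(1), "value")
  pick <- if (any(!nb)) which(!nb)[which.min(vals[!nb])] else which.min(vals)
  best <- runs[[pick]]

  sh <- untransform_par(best$par, spec)
  ev <- obj$eval_shape(sh$b, sh$S_d, sh$p_b, sh$S_b, sh$eps)
  theta <- ev$chat[1]
  r <- ev$chat / theta
  r[ev$chat == 0] <- 1
  params <- dfe_params(b = sh$b, S_d = sh$S_d, p_b = sh$p_b, S_b = sh$S_b,
                       eps_anc = sh$eps, r = r, theta = theta)
  g <- num_gradient(obj$nll, best$par)
  gnorm <- sqrt(sum(g^2)) / (1 + abs(best$value))
  k_free <- (obj$n - 2L) + 1L + 2L + 2L * spec$include_beneficial +
    spec$include_eps
  structure(list(
    model = spec$id, spec = spec, mle_params = params,
    loglik = -best$value, n_free_params = k_free,
    aic = 2 * k_free + 2 * best$value,
    gradient_norm = gnorm,
    converged = best$conv && gnorm < 1e-3,
    near_bound = nb[pick],
    n = obj$n, L_neut = obj$L_n, L_sel = obj$L_s,
    n_runs = length(runs), run_logliks = -vals),
    class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat("<dfe_fit> model", x$model, " logLik =", format(x$loglik),
      " AIC =", format(x$aic), "\n")
  print(x$mle_params)
  cat("  converged:", x$converged, " near_bound:", x$near_bound,
      " grad:", signif(x$gradient_norm, 3), "\n")
  invisible(x)
}

#' @export
glance.dfe_fit <- function(x, ...) {
  tibble(model = x$model, loglik = x$loglik, n_free_params = x$n_free_params,
         aic = x$aic, gradient_norm = x$gradient_norm,
         converged = x$converged, near_bound = x$near_bound)
}

#' @export
tidy.dfe_fit <- function(x, ...) {
  p <- x$mle_params
  tibble(term = c("b", "S_d", "p_b", "S_b", "eps_anc", "theta"),
         estimate = c(p$b, p$S_d, p$p_b, p$S_b, p$eps_anc, p$theta))
}

#' Fit the four-model set
#'
#' Runs [fit_dfe()] for models 1-4 on the same data.
#'
#' @inheritParams fit_dfe
#' @return A named list of four `dfe_fit` objects (`m1`..`m4`).
#' @export
fit_dfe_models <- function(sfs_pair, n_starts = 5, seed = NULL,
                           control = list()) {
  specs <- dfe_model_set()
  purrr::imap(specs, function(sp, nm) {
    fit_dfe(sfs_pair, sp, n_starts = n_starts, seed = seed, control = control)
  })
}

#' AIC model averaging over the four-model set
#'
#' Computes Akaike weights `w_k = exp(-(AIC_k - AIC_min)/2) / sum(...)` and
#' model-averaged parameters, discretized DFE masses and `alpha_DFE`.
#' Discretized masses and `alpha` are averaged as quantities (weighted sums of
#' the per-model values), not recomputed from averaged parameters;
#' deleterious-only models contribute `p_b = 0` and `alpha = 0`.
#'
#' @param fits A list of `dfe_fit` objects fitted to the same data (typically
#'   from [fit_dfe_models()]).
#' @param bin_edges Scaled-effect bin edges for the discretized DFE.
#' @param S_min Lower beneficial-effect bound for `alpha_DFE`.
#' @return A `dfe_avg` object.
#' @export
model_average <- function(fits, bin_edges = c(-Inf, -100, -10, -1, 0, 1, Inf),
                          S_min = 5) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "dfe_fit")))
  Ls <- vapply(fits, function(f) f$L_sel, numeric(1))
  if (length(unique(Ls)) != 1)
    stop_dfeload("fits being averaged must come from identical data")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  w <- exp(-(aics - min(aics)) / 2)
  w <- w / sum(w)
  pars <- lapply(fits, `[[`, "mle_params")
  avg_scalar <- function(f) sum(w * vapply(pars, f, numeric(1)))
  avg_params <- list(
    b = avg_scalar(function(p) p$b),
    S_d = avg_scalar(function(p) p$S_d),
    p_b = avg_scalar(function(p) p$p_b),
    S_b = avg_scalar(function(p) p$S_b),
    eps_anc = avg_scalar(function(p) p$eps_anc),
    theta = avg_scalar(function(p) p$theta))
  masses <- vapply(pars, function(p) discretize_dfe(p, bin_edges)$mass,
                   numeric(length(bin_edges) - 1L))
  alphas <- vapply(pars, function(p) alpha_dfe(p, S_min), numeric(1))
  disc <- tibble(lower = bin_edges[-length(bin_edges)], upper = bin_edges[-1],
                 mass = as.numeric(masses %*% w))
  structure(list(fits = fits,
                 weights = tibble(model = vapply(fits, `[[`, character(1), "model"),
                                  aic = aics, weight = w),
                 avg_params = avg_params,
                 avg_discretized = disc,
                 avg_alpha = sum(w * alphas),
                 per_model_alpha = alphas),
            class = "dfe_avg")
}

#' @export
print.dfe_avg <- function(x, ...) {
  cat("<dfe_avg> model-averaged DFE\n")
  print(x$weights)
  cat("  b =", signif(x$avg_params$b, 4),
      " S_d =", signif(x$avg_params$S_d, 4),
      " p_b =", signif(x$avg_params$p_b, 4),
      " alpha_DFE =", signif(x$avg_alpha, 4), "\n")
  invisible(x)
}

#' @export
tidy.dfe_avg <- function(x, ...) {
  tibble(term = names(x$avg_params),
         estimate = unlist(x$avg_params, use.names = FALSE))
}

#' @export
glance.dfe_avg <- function(x, ...) {
  tibble(b = x$avg_params$b, S_d = x$avg_params$S_d, p_b = x$avg_params$p_b,
         alpha_dfe = x$avg_alpha,
         best_model = x$weights$model[which.max(x$weights$weight)])
}
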