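# Shared-vs-independent DFE comparisons: joint maximization with selected
# parameters tied across datasets, nuisance distortions and the ancestral
# error rate free per dataset, and a chi-square likelihood-ratio test.

#' Likelihood-ratio test for a shared DFE across datasets
#'
#' Independent fit: one full-model ([dfe_model_spec()] 1) fit per dataset,
#' log-likelihoods summed. Shared fit: joint maximization with the parameters
#' named in `shared` (subset of `b`, `S_d`) tied across the datasets while
#' the beneficial component, `eps_anc`, `theta` and every distortion vector
#' stay dataset-specific. Deviance `2 (l_indep - l_shared)` is referred to a
#' chi-square with `|shared| * (K - 1)` degrees of freedom. Because the
#' shared fit starts from (and can polish) the independent solutions, each
#' independent fit is symmetrically re-polished from the shared solution
#' before the deviance is formed; without this the deviance is biased
#' downward by one-sided optimizer slack and the test becomes conservative.
#'
#' @param datasets A list of two or more [sfs_pair()] objects.
#' @param shared Character subset of `c("b", "S_d")` to tie (default both).
#' @param spec Model specification used throughout (default full model with
#'   `eps_anc`).
#' @param n_starts,seed,control As in [fit_dfe()].
#' @param n_shared_starts Number of starts for the joint shared fit (default:
#'   one from the averaged independent solutions plus one per dataset).
#' @param n_tests Bonferroni family size for the adjusted p-value (optional).
#' @return A `dfe_lrt` object: per-dataset fits, shared parameters, deviance,
#'   df, `p_value` (and `bonferroni_adjusted_p` when `n_tests` is given).
#' @export
lrt_shared <- function(datasets, shared = c("b", "S_d"),
                       spec = dfe_model_spec(TRUE, TRUE), n_starts = 5,
                       seed = NULL, control = list(), n_tests = NULL,
                       n_shared_starts = NULL) {
  stopifnot(length(datasets) >= 2,
            all(vapply(datasets, inherits, logical(1), "sfs_pair")),
            length(shared) >= 1, all(shared %in% c("b", "S_d")))
  K <- length(datasets)
  ctl <- modifyList(list(n_nodes = 384, nodes_per_cell = 12, factr = 1e7,
                         maxit = 300, round_counts = TRUE,
                         bounds = dfe_bounds()), control)

  indep <- lapply(seq_len(K), function(k)
    fit_dfe(datasets[[k]], spec, n_starts = n_starts, seed = seed,
            control = ctl))
  ll_indep <- sum(vapply(indep, `[[`, numeric(1), "loglik"))

  box1 <- spec_box(spec, ctl$bounds)
  shared_idx <- match(c(b = "log_b", S_d = "log_Sd")[shared], box1$names)
  free_idx <- setdiff(seq_along(box1$names), shared_idx)
  objs <- lapply(datasets, profile_objective, spec = spec,
                 n_nodes = ctl$n_nodes, nodes_per_cell = ctl$nodes_per_cell,
                 round_counts = ctl$round_counts)

  # joint parameter vector: shared block, then per-dataset free blocks
  assemble <- function(par, k) {
    full <- numeric(length(box1$names))
    full[shared_idx] <- par[seq_along(shared_idx)]
    nf <- length(free_idx)
    full[free_idx] <- par[length(shared_idx) + (k - 1) * nf + seq_len(nf)]
    setNames(full, box1$names)
  }
  joint_nll <- function(par) {
    sum(vapply(seq_len(K), function(k) objs[[k]]$nll(assemble(par, k)),
               numeric(1)))
  }
  lower <- c(box1$lower[shared_idx], rep(box1$lower[free_idx], K))
  upper <- c(box1$upper[shared_idx], rep(box1$upper[free_idx], K))

  # starts: from the independent MLEs (averaging the shared block), plus the
  # per-dataset solutions imposed as common values
  indep_tpars <- lapply(indep, function(f) {
    p <- f$mle_params
    tp <- c(log_b = log(p$b), log_Sd = log(-p$S_d))
    if (spec$include_beneficial)
      tp <- c(tp, p_b = p$p_b, log_Sb = log(p$S_b))
    if (spec$include_eps) tp <- c(tp, eps = p$eps_anc)
    tp[box1$names]
  })
  mk_start <- function(sh_vals) {
    c(sh_vals, unlist(lapply(indep_tpars, function(tp) tp[free_idx])))
  }
  sh_mat <- matrix(vapply(indep_tpars, function(tp) tp[shared_idx],
                          numeric(length(shared_idx))),
                   nrow = length(shared_idx))
  starts <- c(list(mk_start(rowMeans(sh_mat))),
              lapply(indep_tpars, function(tp) mk_start(tp[shared_idx])))
  if (!is.null(n_shared_starts))
    starts <- starts[seq_len(min(n_shared_starts, length(starts)))]
  runs <- lapply(starts, function(st) {
    st <- pmin(pmax(st, lower), upper)
    tryCatch(optim(st, joint_nll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = ctl$factr, maxit = ctl$maxit)),
             error = function(e) NULL)
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (!length(runs)) stop_dfeload("shared-model optimization failed")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  ll_shared <- -best$value

  # symmetrize convergence: the shared fit starts from (and can polish) the
  # independent solutions, so each independent fit is likewise re-polished
  # from the shared solution; otherwise the deviance is biased downward by
  # one-sided optimizer slack
  indep <- lapply(seq_len(K), function(k) {
    st <- assemble(best$par, k)
    op <- tryCatch(
      optim(st, objs[[k]]$nll, method = "L-BFGS-B",
            lower = box1$lower, upper = box1$upper,
            control = list(factr = ctl$factr, maxit = ctl$maxit)),
      error = function(e) NULL)
    f <- indep[[k]]
    if (!is.null(op) && -op$value > f$loglik) f$loglik <- -op$value
    f
  })
  ll_indep <- sum(vapply(indep, `[[`, numeric(1), "loglik"))

  dev <- 2 * (ll_indep - ll_shared)
  df <- length(shared) * (K - 1)
  p <- pchisq(max(dev, 0), df, lower.tail = FALSE)
  sh <- untransform_par(setNames(assemble(best$par, 1), box1$names), spec)
  structure(list(loglik_independent = ll_indep, loglik_shared = ll_shared,
                 deviance = dev, df = df, p_value = p,
                 bonferroni_adjusted_p = if (!is.null(n_tests))
                   min(1, p * n_tests) else NULL,
                 shared = shared,
                 shared_estimates = list(b = sh$b, S_d = sh$S_d)[shared],
                 independent_fits = indep),
            class = "dfe_lrt")
}

#' @export
print.dfe_lrt <- function(x, ...) {
  cat("<dfe_lrt> shared:", paste(x$shared, collapse = ", "),
      "\n  logLik independent =", format(x$loglik_independent),
      " shared =", format(x$loglik_shared),
      "\n  deviance =", signif(x$deviance, 5), " df =", x$df,
      " p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' @export
glance.dfe_lrt <- function(x, ...) {
  tibble(deviance = x$deviance, df = x$df, p_value = x$p_value,
         loglik_independent = x$loglik_independent,
         loglik_shared = x$loglik_shared)
}
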