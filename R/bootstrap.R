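# Parametric-free bootstrap over sites: multinomial resampling within each
# SFS class (totals preserved), refitting the model set, model averaging,
# and percentile confidence intervals on the averaged quantities.

# one multinomial resample of an sfs (categories: the n-1 frequency bins plus
# the monomorphic remainder)
resample_sfs <- function(s) {
  xi <- round(s$xi)
  mono <- s$L - sum(xi)
  stopifnot(mono >= 0)
  pr <- c(xi, mono) / s$L
  draw <- as.numeric(rmultinom(1, size = s$L, prob = pr))
  new_sfs(draw[seq_len(s$n - 1L)], s$n, s$L, s$class_label)
}

#' Bootstrap confidence intervals for model-averaged DFE quantities
#'
#' Each replicate resamples sites multinomially within the neutral and
#' selected classes (class totals preserved), refits every model in
#' `models`, and model-averages. Percentile intervals are returned for the
#' averaged parameters, `alpha_DFE`, and the discretized-DFE masses.
#' Replicate-level fit failures are dropped; more than 20% failures raises a
#' warning.
#'
#' @param sfs_pair An [sfs_pair()].
#' @param B Number of bootstrap replicates (>= 2, default 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param models List of [dfe_model_spec()]s (default the four-model set).
#' @param n_starts,control As in [fit_dfe()].
#' @param bin_edges,S_min As in [model_average()].
#' @return A `dfe_bootstrap` object with `ci` (tibble: quantity, lower,
#'   upper) and `replicates` (tibble of per-replicate averaged quantities).
#' @export
bootstrap_ci <- function(sfs_pair, B = 100, level = 0.95, seed = 1L,
                         models = dfe_model_set(), n_starts = 2,
                         control = list(),
                         bin_edges = c(-Inf, -100, -10, -1, 0, 1, Inf),
                         S_min = 5) {
  stopifnot(B >= 2)
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, B))
  reps <- lapply(seq_len(B), function(rep_i) {
    pair <- withr::with_seed(seeds[rep_i], {
      sfs_pair(resample_sfs(sfs_pair$neutral), resample_sfs(sfs_pair$selected))
    })
    tryCatch({
      fits <- lapply(models, function(sp)
        fit_dfe(pair, sp, n_starts = n_starts, seed = seeds[rep_i],
                control = control))
      avg <- model_average(fits, bin_edges = bin_edges, S_min = S_min)
      out <- tibble(replicate = rep_i,
                    b = avg$avg_params$b, S_d = avg$avg_params$S_d,
                    p_b = avg$avg_params$p_b, S_b = avg$avg_params$S_b,
                    eps_anc = avg$avg_params$eps_anc,
                    alpha_dfe = avg$avg_alpha)
      for (j in seq_len(nrow(avg$avg_discretized)))
        out[[sprintf("mass_%g_%g", avg$avg_discretized$lower[j],
                     avg$avg_discretized$upper[j])]] <-
          avg$avg_discretized$mass[j]
      out
    }, error = function(e) NULL)
  })
  fails <- sum(vapply(reps, is.null, logical(1)))
  if (fails > 0.2 * B)
    warn(sprintf("%d of %d bootstrap replicates failed to fit", fails, B))
  reps <- dplyr::bind_rows(reps)
  if (!nrow(reps)) stop_dfeload("every bootstrap replicate failed")
  a <- (1 - level) / 2
  qcols <- setdiff(names(reps), "replicate")
  ci <- purrr::map_dfr(qcols, function(qq) {
    tibble(quantity = qq,
           lower = as.numeric(quantile(reps[[qq]], a, na.rm = TRUE, type = 1)),
           upper = as.numeric(quantile(reps[[qq]], 1 - a, na.rm = TRUE,
                                       type = 1)))
  })
  structure(list(ci = ci, replicates = reps, B = B, level = level,
                 n_failed = fails),
            class = "dfe_bootstrap")
}

#' @export
print.dfe_bootstrap <- function(x, ...) {
  cat("<dfe_bootstrap>", nrow(x$replicates), "of", x$B,
      "replicates;", 100 * x$level, "% percentile intervals:\n")
  print(x$ci, n = 8)
  invisible(x)
}

#' @export
tidy.dfe_bootstrap <- function(x, ...) x$ci
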