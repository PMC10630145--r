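# Ancestral-allele polarization by maximum likelihood over outgroup states
# under a Kimura 2-parameter substitution model, with per-minor-count-class
# priors estimated jointly (EM), and posterior-based assignment with a
# configurable drop band.
#
# The two-outgroup phylogeny is simplified to independent star-topology
# branches from the ancestral node, each with its own divergence t and a
# shared transition/transversion ratio kappa.

NUCS <- c("A", "C", "G", "T")

#' Kimura 2-parameter transition probability matrix
#'
#' Probability of observing each nucleotide after evolving for `d` expected
#' substitutions per site with transition/transversion rate ratio `kappa`.
#' Rows (starting nucleotide) sum to 1.
#'
#' @param d Branch length in expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return A 4x4 matrix with dimnames A, C, G, T.
#' @export
k2p_matrix <- function(d, kappa) {
  stopifnot(d >= 0, kappa > 0)
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- c(A = "G", C = "T", G = "A", T = "C")
  P <- matrix(p_tv, 4, 4, dimnames = list(NUCS, NUCS))
  diag(P) <- p_same
  for (a in NUCS) P[a, ts[[a]]] <- p_ts
  P
}

#' Downsample a site's haplotype counts to at most `n_max`
#'
#' If a site has more than `n_max` called haplotypes, a single hypergeometric
#' draw subsamples `n_max` haplotypes without replacement; otherwise the site
#' is unchanged. Major/minor labels are re-assigned if the draw reverses the
#' count order.
#'
#' @param site_counts Tibble with columns `major`, `minor`, `major_count`,
#'   `minor_count` (and any others, carried through).
#' @param n_max Maximum haplotype count (default 100).
#' @param seed Integer seed (one draw per site, reproducible).
#' @return The tibble with counts (and possibly labels) updated.
#' @export
downsample_haplotypes <- function(site_counts, n_max = 100, seed = 1L) {
  tb <- as_tibble(site_counts)
  tot <- tb$major_count + tb$minor_count
  stopifnot(all(tot >= 1))
  over <- tot > n_max
  if (!any(over)) return(tb)
  withr::with_seed(seed, {
    new_minor <- rhyper(sum(over), m = tb$minor_count[over],
                        n = tb$major_count[over], k = n_max)
    new_major <- n_max - new_minor
    swap <- new_minor > new_major
    mj <- ifelse(swap, tb$minor[over], tb$major[over])
    mn <- ifelse(swap, tb$major[over], tb$minor[over])
    tb$major[over] <- mj
    tb$minor[over] <- mn
    tb$major_count[over] <- pmax(new_major, new_minor)
    tb$minor_count[over] <- pmin(new_major, new_minor)
  })
  tb
}

# per-site outgroup log-likelihoods given candidate ancestral allele columns;
# missing outgroup states contribute a factor of 1
outgroup_lik <- function(sites, cand, t, kappa) {
  lik <- rep(1, nrow(sites))
  for (o in seq_along(t)) {
    col <- paste0("outgroup", o)
    if (!col %in% names(sites)) next
    P <- k2p_matrix(t[o], kappa)
    st <- sites[[col]]
    okk <- !is.na(st) & !is.na(cand)
    lik[okk] <- lik[okk] * P[cbind(cand[okk], st[okk])]
  }
  lik
}

#' Fit the polarization model by maximum likelihood
#'
#' Maximizes, over branch lengths `t` (one per outgroup), a shared `kappa`,
#' and per-minor-count-class priors `P(major ancestral | class)`, the
#' marginal likelihood `sum_sites log sum_(a in {major, minor}) prior(a) *
#' prod_outgroups P(state | ancestral = a)`. Priors and branch parameters are
#' updated alternately (EM) until the log-likelihood changes by less than
#' `tol` or `max_iter` iterations. Class priors are shrunk towards the global
#' mean (pseudo-count `prior_shrink`) to avoid overfitting sparse classes.
#' Sites whose outgroup states are all missing are excluded from the fit
#' (with a warning) but still receive a class prior in [polarize_sites()].
#'
#' @param sites Tibble with columns `major`, `minor`, `major_count`,
#'   `minor_count` and `outgroup1` (optionally `outgroup2`); `NA` = missing.
#' @param n_outgroups Number of outgroup columns to use (default: autodetect).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param prior_shrink Pseudo-count for class-prior smoothing (default 5).
#' @return A `polarization_model`: `t`, `kappa`, `priors` (tibble
#'   `minor_count`, `prior`), `global_prior`, `loglik`, `n_sites_used`.
#' @export
fit_polarization_model <- function(sites, n_outgroups = NULL, tol = 1e-8,
                                   max_iter = 500, prior_shrink = 5) {
  tb <- as_tibble(sites)
  og_cols <- grep("^outgroup[0-9]+$", names(tb), value = TRUE)
  if (!is.null(n_outgroups)) og_cols <- og_cols[seq_len(n_outgroups)]
  stopifnot(length(og_cols) >= 1)
  has_og <- Reduce(`|`, lapply(og_cols, function(cc) !is.na(tb[[cc]])))
  if (!any(has_og)) stop_dfeload("no site has an informative outgroup state")
  if (any(!has_og))
    warn(sprintf("%d site(s) with all outgroup states missing excluded from the fit",
                 sum(!has_og)))
  fitdat <- tb[has_og, , drop = FALSE]
  cls <- fitdat$minor_count
  ucls <- sort(unique(cls))
  n_og <- length(og_cols)

  t_cur <- rep(0.1, n_og)
  kappa_cur <- 2
  pri <- setNames(rep(0.8, length(ucls)), ucls)
  ll_old <- -Inf

  marg_ll <- function(t, kappa, pri) {
    lmaj <- outgroup_lik(fitdat, fitdat$major, t, kappa)
    lmin <- outgroup_lik(fitdat, fitdat$minor, t, kappa)
    p <- pri[as.character(cls)]
    list(ll = sum(log(p * lmaj + (1 - p) * lmin)),
         w = p * lmaj / (p * lmaj + (1 - p) * lmin))
  }

  for (it in seq_len(max_iter)) {
    m <- marg_ll(t_cur, kappa_cur, pri)
    w <- m$w
    # M-step 1: smoothed class priors
    wbar <- mean(w)
    agg <- tapply(w, cls, sum)
    cnt <- tapply(rep(1, length(w)), cls, sum)
    pri <- (agg + prior_shrink * wbar) / (cnt + prior_shrink)
    pri <- setNames(pmin(pmax(as.numeric(pri), 1e-6), 1 - 1e-6),
                    names(agg))
    # M-step 2: branch parameters, expected complete-data log-likelihood
    obj <- function(par) {
      t <- exp(par[seq_len(n_og)]); kap <- exp(par[n_og + 1L])
      lmaj <- outgroup_lik(fitdat, fitdat$major, t, kap)
      lmin <- outgroup_lik(fitdat, fitdat$minor, t, kap)
      -sum(w * log(pmax(lmaj, 1e-300)) + (1 - w) * log(pmax(lmin, 1e-300)))
    }
    op <- optim(c(log(pmax(t_cur, 1e-6)), log(kappa_cur)), obj,
                method = "L-BFGS-B",
                lower = c(rep(log(1e-8), n_og), log(0.05)),
                upper = c(rep(log(10), n_og), log(50)))
    t_cur <- exp(op$par[seq_len(n_og)])
    kappa_cur <- exp(op$par[n_og + 1L])
    ll_new <- marg_ll(t_cur, kappa_cur, pri)$ll
    if (abs(ll_new - ll_old) < tol) break
    ll_old <- ll_new
  }
  structure(list(t = t_cur, kappa = kappa_cur,
                 priors = tibble(minor_count = as.integer(names(pri)),
                                 prior = as.numeric(pri)),
                 global_prior = mean(marg_ll(t_cur, kappa_cur, pri)$w),
                 loglik = ll_new, n_sites_used = nrow(fitdat),
                 n_outgroups = n_og, iterations = it),
            class = "polarization_model")
}

#' @export
print.polarization_model <- function(x, ...) {
  cat("<polarization_model>  t =", paste(signif(x$t, 4), collapse = ", "),
      " kappa =", signif(x$kappa, 4), "\n  logLik =", format(x$loglik),
      " sites =", x$n_sites_used, " iterations =", x$iterations, "\n")
  invisible(x)
}

#' Assign ancestral/derived alleles from the fitted model
#'
#' Computes, per site, the posterior probability that the major allele is
#' ancestral (Bayes' rule from the class prior and outgroup likelihoods) and
#' assigns: `assigned_major` if `p >= drop_band[2]`, `assigned_minor` if
#' `p <= drop_band[1]`, otherwise `dropped` (open interval: sites strictly
#' inside the band cannot be polarized with confidence). Sites with no
#' outgroup data get `p` equal to their class prior, i.e. are polarized on
#' minor-allele frequency alone.
#'
#' @param sites Tibble as in [fit_polarization_model()].
#' @param model A fitted `polarization_model`.
#' @param drop_band Posterior band (default `c(0.4, 0.6)`) inside which sites
#'   are dropped.
#' @return The input tibble plus `p_major_ancestral`, `status`
#'   (`assigned_major` / `assigned_minor` / `dropped`), `derived_allele`, and
#'   `derived_count` (count of the derived allele; `NA` when dropped).
#' @export
polarize_sites <- function(sites, model, drop_band = c(0.4, 0.6)) {
  stopifnot(inherits(model, "polarization_model"),
            length(drop_band) == 2, drop_band[1] < drop_band[2])
  tb <- as_tibble(sites)
  pri_map <- setNames(model$priors$prior, model$priors$minor_count)
  p_cls <- unname(pri_map[as.character(tb$minor_count)])
  p_cls[is.na(p_cls)] <- model$global_prior
  lmaj <- outgroup_lik(tb, tb$major, model$t, model$kappa)
  lmin <- outgroup_lik(tb, tb$minor, model$t, model$kappa)
  p <- p_cls * lmaj / (p_cls * lmaj + (1 - p_cls) * lmin)
  status <- dplyr::case_when(
    p >= drop_band[2] ~ "assigned_major",
    p <= drop_band[1] ~ "assigned_minor",
    TRUE ~ "dropped")
  tb$p_major_ancestral <- p
  tb$status <- status
  tb$derived_allele <- dplyr::case_when(
    status == "assigned_major" ~ tb$minor,
    status == "assigned_minor" ~ tb$major,
    TRUE ~ NA_character_)
  tb$derived_count <- dplyr::case_when(
    status == "assigned_major" ~ as.numeric(tb$minor_count),
    status == "assigned_minor" ~ as.numeric(tb$major_count),
    TRUE ~ NA_real_)
  tb
}
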