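# Synthetic-data generators with recorded truth: Poisson SFS datasets under a
# known DFE, multi-population per-site derived-allele frequencies on scaffolds
# (Balding-Nichols divergence), and outgroup states evolved under a Kimura
# 2-parameter model. Every generator is keyed by a single integer seed.

#' Simulate an SFS dataset under a known DFE
#'
#' Draws observed counts Poisson-distributed around the expected spectra of
#' [expected_sfs()], matching the Poisson-random-field likelihood. The noise
#' is per-entry Poisson rather than haplotype resampling, which keeps the
#' generator aligned with the inference model (a stated limitation for
#' emulating real data).
#'
#' @param truth A [dfe_params()] object (the generating truth).
#' @param n Haplotype sample size (default 40).
#' @param L_sel,L_neut Selected / neutral site totals (defaults 1e5 and 4e4,
#'   the scale of a ~3 Mb exome-capture class split).
#' @param seed Integer seed.
#' @param n_nodes Quadrature nodes for the expected spectrum.
#' @return A list with `sfs_pair` (the observed [sfs_pair()]) and `truth`
#'   (the generating parameters plus the seed), class `sim_sfs_dataset`.
#' @export
simulate_sfs_dataset <- function(truth, n = 40, L_sel = 1e5, L_neut = 4e4,
                                 seed = 1L, n_nodes = 384) {
  stopifnot(inherits(truth, "dfe_params"))
  e <- expected_sfs(truth, n, L_sel, L_neut, n_nodes = n_nodes)
  xi <- withr::with_seed(seed, rpois(nrow(e), e$expected))
  en <- xi[e$class == "neutral_4fold"]
  es <- xi[e$class == "selected_0fold"]
  pair <- sfs_pair(new_sfs(en, n, L_neut, "neutral_4fold"),
                   new_sfs(es, n, L_sel, "selected_0fold"))
  structure(list(sfs_pair = pair,
                 truth = list(params = truth, n = n, L_sel = L_sel,
                              L_neut = L_neut, seed = seed)),
            class = "sim_sfs_dataset")
}

# density ~ 1/x on [lo, hi]: neutral-like ancestral frequency distribution
r_neutral_freq <- function(m, lo = 0.02, hi = 0.98) {
  lo * (hi / lo)^runif(m)
}

#' Simulate polarized per-site frequencies for several populations
#'
#' Ancestral derived-allele frequencies are drawn from a neutral-like density
#' (proportional to 1/x); each population's frequency is then drawn from a
#' Balding-Nichols beta kernel with divergence `divergence`, and observed
#' frequencies are binomial samples of `n_hap` haplotypes. An optional
#' selection asymmetry multiplies the first population's 0-fold frequencies
#' by a factor < 1, emulating stronger purging. Positions are uniform on the
#' supplied scaffolds.
#'
#' @param n_pops Number of populations (>= 2).
#' @param sites_per_class Named vector or list: number of `zero_fold` and
#'   `four_fold` sites (e.g. `c(zero_fold = 5e4, four_fold = 2e4)`).
#' @param scaffold_lengths Numeric vector of scaffold lengths in bp (names
#'   optional; default 20 scaffolds of 10 Mb).
#' @param divergence Balding-Nichols divergence (FST-like, in `[0, 1)`);
#'   scalar or per-population vector.
#' @param selection_asymmetry Multiplier applied to population 1's 0-fold
#'   derived frequencies (1 = exchangeable populations).
#' @param demographic_asymmetry Multiplier applied to population 1's derived
#'   frequencies in *both* classes, emulating a class-blind displacement
#'   (population structure, reference bias) that the neutral-normalized
#'   R'xy is designed to absorb.
#' @param n_hap Haplotypes sampled per population per site (binomial
#'   sampling; default 40).
#' @param seed Integer seed.
#' @return A list with `freq_table` (tibble: scaffold, position, degeneracy,
#'   `freq_<pop>`, `n_<pop>`) and `truth`, class `sim_population_sites`.
#' @export
simulate_population_sites <- function(n_pops = 2,
                                      sites_per_class = c(zero_fold = 5e4,
                                                          four_fold = 2e4),
                                      scaffold_lengths = rep(1e7, 20),
                                      divergence = 0.05,
                                      selection_asymmetry = 1,
                                      demographic_asymmetry = 1,
                                      n_hap = 40, seed = 1L) {
  stopifnot(n_pops >= 2, all(divergence >= 0), all(divergence < 1))
  divergence <- rep_len(divergence, n_pops)
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("scaf%02d", seq_along(scaffold_lengths))
  m <- sum(unlist(sites_per_class))
  withr::with_seed(seed, {
    scaf <- sample(names(scaffold_lengths), m, replace = TRUE,
                   prob = scaffold_lengths / sum(scaffold_lengths))
    pos <- floor(runif(m, 1, scaffold_lengths[scaf] + 1))
    x <- r_neutral_freq(m)
    cls <- rep(c("zero_fold", "four_fold"),
               times = c(sites_per_class[["zero_fold"]],
                         sites_per_class[["four_fold"]]))
    out <- tibble(scaffold = scaf, position = as.integer(pos),
                  degeneracy = cls)
    for (k in seq_len(n_pops)) {
      Fk <- divergence[k]
      p <- if (Fk == 0) x else
        rbeta(m, x * (1 - Fk) / Fk, (1 - x) * (1 - Fk) / Fk)
      if (k == 1 && selection_asymmetry != 1)
        p <- ifelse(cls == "zero_fold", p * selection_asymmetry, p)
      if (k == 1 && demographic_asymmetry != 1)
        p <- pmin(p * demographic_asymmetry, 1)
      obs <- rbinom(m, n_hap, p) / n_hap
      out[[paste0("freq_pop", k)]] <- obs
      out[[paste0("n_pop", k)]] <- n_hap
    }
    out <- dplyr::arrange(out, .data$scaffold, .data$position)
    structure(list(freq_table = out,
                   truth = list(n_pops = n_pops, divergence = divergence,
                                selection_asymmetry = selection_asymmetry,
                                demographic_asymmetry = demographic_asymmetry,
                                n_hap = n_hap, seed = seed,
                                scaffold_lengths = scaffold_lengths)),
              class = "sim_population_sites")
  })
}

#' Simulate ingroup counts plus outgroup states under a K2P model
#'
#' Each site gets an ancestral nucleotide (uniform) and a derived allele
#' chosen with transition:transversion odds `kappa:1` per transversion
#' pathway. The ingroup derived-allele count is drawn from a neutral-like
#' spectrum (`P(i) ~ 1/i`) on `n_hap` haplotypes; each outgroup's state
#' evolves from the ancestral nucleotide under a Kimura 2-parameter model
#' with its own divergence `t` (expected substitutions/site) and shared
#' `kappa`. The truth (ancestral state per site) is recorded.
#'
#' @param n_sites Number of polymorphic sites.
#' @param n_hap Ingroup haplotype count.
#' @param t_per_outgroup Numeric vector of outgroup divergences (length 1
#'   or 2).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param missing_rate Fraction of outgroup states set missing at random.
#' @param seed Integer seed.
#' @return A list with `sites` (tibble: site, major/minor alleles and counts,
#'   `outgroup1` (+ `outgroup2`), and truth columns `ancestral`, `derived`,
#'   `derived_count`) and `truth`, class `sim_outgroup_alignment`.
#' @export
simulate_outgroup_alignment <- function(n_sites = 10000, n_hap = 40,
                                        t_per_outgroup = c(0.05, 0.1),
                                        kappa = 2, missing_rate = 0,
                                        seed = 1L) {
  stopifnot(all(t_per_outgroup >= 0), kappa > 0,
            length(t_per_outgroup) %in% 1:2)
  nt <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    anc <- sample(nt, n_sites, replace = TRUE)
    der <- vapply(anc, mutate_k2p, character(1), kappa = kappa)
    i <- sample(seq_len(n_hap - 1L), n_sites, replace = TRUE,
                prob = 1 / seq_len(n_hap - 1L))
    major_is_anc <- i < n_hap - i | (i == n_hap - i & runif(n_sites) < 0.5)
    major <- ifelse(major_is_anc, anc, der)
    minor <- ifelse(major_is_anc, der, anc)
    major_count <- pmax(i, n_hap - i)
    minor_count <- pmin(i, n_hap - i)
    sites <- tibble(site = seq_len(n_sites), major = major, minor = minor,
                    major_count = major_count, minor_count = minor_count)
    for (o in seq_along(t_per_outgroup)) {
      P <- k2p_matrix(t_per_outgroup[o], kappa)
      st <- vapply(anc, function(a) sample(nt, 1, prob = P[a, ]), character(1))
      if (missing_rate > 0)
        st[runif(n_sites) < missing_rate] <- NA_character_
      sites[[paste0("outgroup", o)]] <- st
    }
    sites$ancestral <- anc
    sites$derived <- der
    sites$derived_count <- i
    structure(list(sites = sites,
                   truth = list(t = t_per_outgroup, kappa = kappa,
                                n_hap = n_hap, seed = seed)),
              class = "sim_outgroup_alignment")
  })
}

# pick a derived nucleotide from ancestral `a` with transition odds kappa
mutate_k2p <- function(a, kappa) {
  nt <- c("A", "C", "G", "T")
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  others <- setdiff(nt, a)
  pr <- ifelse(others == ts[[a]], kappa, 1)
  sample(others, 1, prob = pr / sum(pr))
}
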