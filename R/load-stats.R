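# Genetic-load and differentiation statistics between populations: Rxy and
# R'xy derived-allele load ratios, Hudson's FST, and the weighted block
# jackknife over consecutive 2-Mb genomic chunks.

freq_col <- function(tb, pop) {
  cc <- paste0("freq_", pop)
  if (!cc %in% names(tb)) stop_dfeload("no frequency column for population ", pop)
  cc
}

#' Rxy: relative accumulation of derived alleles in two populations
#'
#' `L_XnotY = sum_sites p_X (1 - p_Y)` and `L_YnotX = sum_sites p_Y (1 - p_X)`
#' are the expected numbers of derived alleles carried by one genome sampled
#' from X but not by one genome sampled from Y, and vice versa;
#' `Rxy = L_XnotY / L_YnotX`. Under equally effective selection and equal
#' mutation rates the expectation is 1; values above 1 indicate an excess of
#' derived alleles in X.
#'
#' @param freq_table Tibble with a `degeneracy` column and per-population
#'   derived-frequency columns `freq_<pop>`.
#' @param pop_x,pop_y Population identifiers (suffix of the `freq_` columns).
#' @param class Degeneracy class to use (`"zero_fold"` or `"four_fold"`);
#'   `NULL` = all sites.
#' @return Scalar Rxy (`NA` with a warning if the denominator is zero).
#' @export
rxy <- function(freq_table, pop_x, pop_y, class = "zero_fold") {
  tb <- as_tibble(freq_table)
  if (!is.null(class)) tb <- tb[tb$degeneracy == class, , drop = FALSE]
  px <- tb[[freq_col(tb, pop_x)]]
  py <- tb[[freq_col(tb, pop_y)]]
  keep <- !is.na(px) & !is.na(py)
  if (!any(keep)) stop_dfeload("no sites with data in both populations")
  num <- sum(px[keep] * (1 - py[keep]))
  den <- sum(py[keep] * (1 - px[keep]))
  if (den == 0) {
    warn("Rxy denominator is zero; returning NA")
    return(NA_real_)
  }
  num / den
}

#' R'xy: Rxy at selected sites normalized by neutral sites
#'
#' `R'xy = Rxy(0-fold) / Rxy(4-fold)`: dividing by the 4-fold ratio absorbs
#' demography and population structure that displace both classes alike.
#'
#' @inheritParams rxy
#' @return Scalar R'xy.
#' @export
rxy_prime <- function(freq_table, pop_x, pop_y) {
  rxy(freq_table, pop_x, pop_y, class = "zero_fold") /
    rxy(freq_table, pop_x, pop_y, class = "four_fold")
}

#' Hudson's FST between two populations
#'
#' Ratio-of-sums estimator over 4-fold sites:
#' `sum[(pa - pb)^2 - pa(1-pa)/(na-1) - pb(1-pb)/(nb-1)] /
#'  sum[pa(1-pb) + pb(1-pa)]`, where `na`, `nb` are haplotype sample sizes
#' (taken from `n_<pop>` columns; assumed large if absent).
#'
#' @inheritParams rxy
#' @param pop_a,pop_b Population identifiers.
#' @param class Degeneracy class (default `"four_fold"`).
#' @return Scalar FST estimate (`NA` with a warning on a degenerate
#'   denominator).
#' @export
fst_pairwise <- function(freq_table, pop_a, pop_b, class = "four_fold") {
  tb <- as_tibble(freq_table)
  if (!is.null(class)) tb <- tb[tb$degeneracy == class, , drop = FALSE]
  pa <- tb[[freq_col(tb, pop_a)]]
  pb <- tb[[freq_col(tb, pop_b)]]
  na_col <- paste0("n_", pop_a); nb_col <- paste0("n_", pop_b)
  na <- if (na_col %in% names(tb)) tb[[na_col]] else rep(Inf, nrow(tb))
  nb <- if (nb_col %in% names(tb)) tb[[nb_col]] else rep(Inf, nrow(tb))
  keep <- !is.na(pa) & !is.na(pb)
  stopifnot(any(keep))
  pa <- pa[keep]; pb <- pb[keep]; na <- na[keep]; nb <- nb[keep]
  num <- sum((pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1))
  den <- sum(pa * (1 - pb) + pb * (1 - pa))
  if (den <= 0) {
    warn("FST denominator is degenerate; returning NA")
    return(NA_real_)
  }
  num / den
}

#' Group sites into consecutive genomic blocks
#'
#' Cuts each scaffold into consecutive chunks of `chunk_bp` base pairs and
#' assembles the chunks, in genome order, into `n_blocks` groups of similar
#' total length, keeping consecutive chunks together (chunks from different
#' scaffolds may share a group). If there are fewer chunks than blocks,
#' `n_blocks` is reduced with a warning.
#'
#' @param freq_table Tibble with `scaffold` and `position` columns.
#' @param n_blocks Target number of jackknife blocks (default 100).
#' @param chunk_bp Chunk length in base pairs (default 2e6).
#' @return The tibble with a `block_id` column (integer in `1..n_blocks`).
#' @export
assign_blocks <- function(freq_table, n_blocks = 100, chunk_bp = 2e6) {
  tb <- dplyr::arrange(as_tibble(freq_table), .data$scaffold, .data$position)
  chunk_key <- paste0(tb$scaffold, "#", (tb$position - 1) %/% chunk_bp)
  uk <- unique(chunk_key) # already in genome order
  n_chunks <- length(uk)
  if (n_chunks < n_blocks) {
    warn(sprintf("only %d chunks; reducing n_blocks from %d", n_chunks, n_blocks))
    n_blocks <- n_chunks
  }
  # consecutive chunks -> blocks of near-equal chunk count
  block_of_chunk <- ceiling(seq_along(uk) / (n_chunks / n_blocks))
  tb$block_id <- as.integer(block_of_chunk[match(chunk_key, uk)])
  tb
}

#' Weighted block jackknife for a per-site statistic
#'
#' Delete-one-block estimates over the consecutive genomic blocks of
#' [assign_blocks()], combined with block-size weights (site counts) using
#' the weighted delete-m jackknife; returns the point estimate, the
#' jackknife standard error, and a normal-approximation 95% confidence
#' interval.
#'
#' @param freq_table Tibble with `scaffold`, `position` (or a precomputed
#'   `block_id`) and whatever columns `statistic` needs.
#' @param statistic Function `freq_table -> scalar` (e.g. a partialised
#'   [rxy()]).
#' @param n_blocks,chunk_bp Passed to [assign_blocks()] when `block_id` is
#'   absent.
#' @param level Confidence level (default 0.95).
#' @return A `jackknife_result`: `point_estimate`, `jackknife_se`, `ci_low`,
#'   `ci_high`, `n_blocks`.
#' @export
block_jackknife <- function(freq_table, statistic, n_blocks = 100,
                            chunk_bp = 2e6, level = 0.95) {
  tb <- as_tibble(freq_table)
  if (!"block_id" %in% names(tb))
    tb <- assign_blocks(tb, n_blocks = n_blocks, chunk_bp = chunk_bp)
  blocks <- sort(unique(tb$block_id))
  G <- length(blocks)
  if (G < 2) stop_dfeload("need at least 2 non-empty blocks")
  theta_hat <- statistic(tb)
  m <- vapply(blocks, function(b) sum(tb$block_id == b), numeric(1))
  ntot <- sum(m)
  theta_del <- vapply(blocks, function(b) {
    statistic(tb[tb$block_id != b, , drop = FALSE])
  }, numeric(1))
  # weighted delete-m_j jackknife (Busing et al. 1999)
  h <- ntot / m
  theta_jack <- G * theta_hat - sum((1 - m / ntot) * theta_del)
  pseudo <- h * theta_hat - (h - 1) * theta_del
  var_j <- sum((pseudo - theta_jack)^2 / (h - 1)) / G
  se <- sqrt(var_j)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(point_estimate = theta_hat, jackknife_se = se,
                 ci_low = theta_hat - z * se, ci_high = theta_hat + z * se,
                 n_blocks = G, level = level),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> estimate %.6g  SE %.3g  %g%% CI [%.6g, %.6g]  (%d blocks)\n",
              x$point_estimate, x$jackknife_se, 100 * x$level, x$ci_low,
              x$ci_high, x$n_blocks))
  invisible(x)
}

#' @export
tidy.jackknife_result <- function(x, ...) {
  tibble(estimate = x$point_estimate, std.error = x$jackknife_se,
         conf.low = x$ci_low, conf.high = x$ci_high, n_blocks = x$n_blocks)
}

#' Load statistics for a focal vs a reference population
#'
#' Convenience wrapper computing jackknifed Rxy (0-fold and 4-fold), R'xy,
#' and FST (4-fold) between a focal and a reference population.
#'
#' @inheritParams rxy
#' @param focal,reference Population identifiers.
#' @param n_blocks,chunk_bp Jackknife blocking parameters.
#' @return A tibble (statistic, class, estimate, se, ci_low, ci_high).
#' @export
load_statistics <- function(freq_table, focal, reference, n_blocks = 100,
                            chunk_bp = 2e6) {
  tb <- assign_blocks(freq_table, n_blocks = n_blocks, chunk_bp = chunk_bp)
  one <- function(name, cls, f) {
    j <- block_jackknife(tb, f, n_blocks = n_blocks, chunk_bp = chunk_bp)
    tibble(statistic = name, class = cls %||% "all",
           estimate = j$point_estimate, se = j$jackknife_se,
           ci_low = j$ci_low, ci_high = j$ci_high)
  }
  dplyr::bind_rows(
    one("rxy", "zero_fold", function(d) rxy(d, focal, reference, "zero_fold")),
    one("rxy", "four_fold", function(d) rxy(d, focal, reference, "four_fold")),
    one("rxy_prime", "zero_fold", function(d) rxy_prime(d, focal, reference)),
    one("fst", "four_fold", function(d) fst_pairwise(d, focal, reference)))
}
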