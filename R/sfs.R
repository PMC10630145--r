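# Unfolded site frequency spectra: containers, hypergeometric projection,
# construction from polarized variant data, and pairwise diversity.

#' Unfolded site frequency spectrum
#'
#' Container for an unfolded SFS: counts `xi[i]` of sites with `i` copies of
#' the derived allele in a sample of `n` haplotypes (`i = 1..n-1`, possibly
#' fractional after projection), together with the total number of sites `L`
#' in the class (monomorphic plus polymorphic) and a class label.
#'
#' @param xi Numeric vector of length `n - 1` of (possibly fractional) counts.
#' @param n Haplotype sample size (>= 2).
#' @param L Total sites in the class; must satisfy `sum(xi) <= L`.
#' @param class_label `"neutral_4fold"`, `"selected_0fold"`, or another label.
#' @return An object of class `sfs`.
#' @export
new_sfs <- function(xi, n, L, class_label = "neutral_4fold") {
  stopifnot(n >= 2, length(xi) == n - 1, all(xi >= -1e-9), L >= 0)
  if (sum(xi) > L + 1e-6) stop_dfeload("sum(xi) exceeds L")
  structure(list(xi = pmax(xi, 0), n = as.integer(n), L = L,
                 class_label = class_label),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("<sfs> ", x$class_label, ": n =", x$n, ", L =", format(x$L),
      ", segregating =", format(round(sum(x$xi), 2)), "\n")
  invisible(x)
}

#' @rdname new_sfs
#' @param neutral,selected Two `sfs` objects with equal `n` (4-fold neutral
#'   and 0-fold selected classes).
#' @export
sfs_pair <- function(neutral, selected) {
  stopifnot(inherits(neutral, "sfs"), inherits(selected, "sfs"))
  if (neutral$n != selected$n)
    stop_dfeload("the two spectra of a pair must share the haplotype count n")
  structure(list(neutral = neutral, selected = selected), class = "sfs_pair")
}

#' @export
print.sfs_pair <- function(x, ...) {
  cat("<sfs_pair> n =", x$neutral$n, "\n")
  print(x$neutral); print(x$selected)
  invisible(x)
}

#' @export
tidy.sfs <- function(x, ...) {
  tibble(class = x$class_label, i = seq_len(x$n - 1L), count = x$xi)
}

#' @export
tidy.sfs_pair <- function(x, ...) {
  dplyr::bind_rows(tidy(x$neutral), tidy(x$selected))
}

#' Project an SFS down to a smaller sample size
#'
#' Hypergeometric projection: the average spectrum over every possible
#' subsample of `n_target` haplotypes out of `n`,
#' `xi'[j] = sum_i xi[i] P(Hypergeom(i, n - i, n_target) = j)`.
#' Mass landing on `j = 0` or `j = n_target` leaves the polymorphic spectrum
#' but stays in `L`.
#'
#' @param sfs An [new_sfs()] object.
#' @param n_target Target haplotype count, `2 <= n_target <= n`.
#' @return A projected `sfs` at sample size `n_target`.
#' @export
project_sfs <- function(sfs, n_target) {
  stopifnot(inherits(sfs, "sfs"))
  n <- sfs$n
  if (n_target > n) stop_dfeload("cannot project up: n_target > n")
  stopifnot(n_target >= 2)
  if (n_target == n) return(sfs)
  P <- outer(seq_len(n - 1L), seq_len(n_target - 1L), function(i, j) {
    dhyper(j, i, n - i, n_target)
  })
  new_sfs(as.numeric(sfs$xi %*% P), n_target, sfs$L, sfs$class_label)
}

# Project a single site's derived count k out of m called haplotypes onto the
# 0..n_target bins (expected counts); returns a vector of length n_target + 1.
project_site <- function(k, m, n_target) {
  dhyper(0:n_target, k, m - k, n_target)
}

#' Build neutral and selected spectra for one population
#'
#' Tallies derived-allele counts per degeneracy class from a polarized
#' per-site table and projects every site down to a common sample size
#' `n_target` by hypergeometric averaging, which also absorbs per-site
#' missingness. Sites with fewer than `n_target` called haplotypes are
#' dropped from both the spectrum and `L`. Monomorphic (and fixed-derived)
#' sites count in `L` but not in the polymorphic spectrum. Sites whose
#' polarization was dropped (ambiguous ancestral state) are excluded from
#' both, unless `count_dropped_in_L = TRUE`.
#'
#' @param site_counts A data frame with one row per site and columns
#'   `degeneracy` (`"zero_fold"`/`"four_fold"`), `derived_count`,
#'   `called_haplotypes`, and optionally `status` (from [polarize_sites()];
#'   `"dropped"` rows are excluded).
#' @param n_target Target haplotype count (default 40, i.e. 20 diploids).
#' @param count_dropped_in_L Keep polarization-dropped SNPs in the site total
#'   `L` (default FALSE).
#' @return An [sfs_pair()].
#' @export
build_sfs <- function(site_counts, n_target = 40, count_dropped_in_L = FALSE) {
  stopifnot(all(c("degeneracy", "derived_count", "called_haplotypes") %in%
                  names(site_counts)))
  tb <- as_tibble(site_counts)
  if (!nrow(tb)) stop_dfeload("no sites supplied")
  tb <- tb[tb$called_haplotypes >= n_target, , drop = FALSE]
  dropped <- if ("status" %in% names(tb)) tb$status == "dropped" else
    rep(FALSE, nrow(tb))
  one_class <- function(cls, label) {
    sub <- tb[tb$degeneracy == cls, , drop = FALSE]
    drp <- dropped[tb$degeneracy == cls]
    L <- sum(!drp) + if (count_dropped_in_L) sum(drp) else 0
    if (L == 0) stop_dfeload("no usable ", cls, " sites")
    xi <- numeric(n_target - 1L)
    poly <- sub[!drp & sub$derived_count > 0, , drop = FALSE]
    if (nrow(poly)) {
      agg <- dplyr::count(poly, .data$derived_count, .data$called_haplotypes)
      for (row in seq_len(nrow(agg))) {
        pr <- project_site(agg$derived_count[row],
                           agg$called_haplotypes[row], n_target)
        xi <- xi + agg$n[row] * pr[2:n_target]
      }
    }
    new_sfs(xi, n_target, L, label)
  }
  sfs_pair(neutral = one_class("four_fold", "neutral_4fold"),
           selected = one_class("zero_fold", "selected_0fold"))
}

#' Pairwise nucleotide diversity from an SFS pair
#'
#' Per-site heterozygosity `pi = sum_i xi[i] 2 i (n - i) / (n (n - 1)) / L`
#' for each class, and the ratio `pi0/pi4` (the efficiency of purifying
#' selection; `NA` with a warning when `pi4 = 0`).
#'
#' @param sfs_pair An [sfs_pair()].
#' @return A one-row tibble with columns `pi0`, `pi4`, `pi0_pi4`.
#' @export
pairwise_diversity <- function(sfs_pair) {
  stopifnot(inherits(sfs_pair, "sfs_pair"))
  pi_one <- function(s) {
    stopifnot(s$L > 0)
    i <- seq_len(s$n - 1L)
    sum(s$xi * 2 * i * (s$n - i) / (s$n * (s$n - 1))) / s$L
  }
  pi4 <- pi_one(sfs_pair$neutral)
  pi0 <- pi_one(sfs_pair$selected)
  ratio <- if (pi4 == 0) {
    warn("pi4 is zero; pi0/pi4 undefined")
    NA_real_
  } else pi0 / pi4
  tibble(pi0 = pi0, pi4 = pi4, pi0_pi4 = ratio)
}
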