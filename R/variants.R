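# Variant input/output: VCF + degeneracy annotation + sample metadata in,
# per-site QC filters, per-population allele counts, and plain-text writers
# used by the synthetic generator (round-trip safe).

DEGENERACY_LEVELS <- c("zero_fold", "four_fold", "other")

parse_degeneracy_class <- function(x) {
  dplyr::case_when(
    x %in% c("0fold", "0-fold", "zero_fold", "0") ~ "zero_fold",
    x %in% c("4fold", "4-fold", "four_fold", "4") ~ "four_fold",
    TRUE ~ "other")
}

#' Read variants, degeneracy annotation and sample metadata
#'
#' Reads a VCF 4.x file (biallelic SNPs and annotated monomorphic sites; any
#' other record is skipped), a degeneracy table (TSV: `scaffold`, `position`,
#' `class` in `{0fold, 4fold}`), and sample metadata (TSV: `sample_id`,
#' `country`, `admixture_group`, `lat`, `lon`). Sites absent from the
#' degeneracy table get class `"other"`.
#'
#' @param vcf_path,degeneracy_table_path,metadata_path File paths; a missing
#'   file is fatal, as is a VCF sample absent from the metadata.
#' @return A list with `variants` (tibble: `scaffold`, `position`, `ref`,
#'   `alt`, `degeneracy`, plus matrix columns `gt` (diploid derived-dosage
#'   0/1/2, `NA` missing), `dp`, `gq`, one column per sample) and `metadata`
#'   (tibble).
#' @export
read_variant_data <- function(vcf_path, degeneracy_table_path, metadata_path) {
  for (f in c(vcf_path, degeneracy_table_path, metadata_path))
    if (!file.exists(f)) stop_dfeload("file not found: ", f)
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "country", "admixture_group", "lat", "lon")
                %in% names(metadata)))
  stopifnot(all(metadata$lat >= -90 & metadata$lat <= 90),
            all(metadata$lon >= -180 & metadata$lon <= 180))
  deg <- readr::read_tsv(degeneracy_table_path, show_col_types = FALSE,
                         col_types = readr::cols(scaffold = "c"))
  stopifnot(all(c("scaffold", "position", "class") %in% names(deg)))

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    empty <- tibble(scaffold = character(), position = integer(),
                    ref = character(), alt = character(),
                    degeneracy = character())
    return(list(variants = empty, metadata = metadata))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) stop_dfeload("malformed position in VCF: ",
                               fix$POS[which(is.na(pos))[1]])
  alt <- fix$ALT
  alt[alt %in% c(".", "")] <- NA_character_
  keep <- fix$REF %in% NUCS & (is.na(alt) | alt %in% NUCS)
  samples <- colnames(v@gt)[-1]
  missing_meta <- setdiff(samples, metadata$sample_id)
  if (length(missing_meta))
    stop_dfeload("VCF sample(s) absent from metadata: ",
                 paste(missing_meta, collapse = ", "))

  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  dose <- matrix(NA_real_, nrow(gt_chr), ncol(gt_chr),
                 dimnames = dimnames(gt_chr))
  clean <- gsub("\\|", "/", gt_chr)
  dose[clean %in% c("0/0")] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean %in% c("1/1")] <- 2

  tb <- tibble(scaffold = fix$CHROM, position = pos, ref = fix$REF, alt = alt)
  tb$gt <- dose; tb$dp <- dp; tb$gq <- gq
  tb <- tb[keep, , drop = FALSE]
  key <- paste0(tb$scaffold, ":", tb$position)
  dkey <- paste0(deg$scaffold, ":", deg$position)
  cls <- parse_degeneracy_class(deg$class[match(key, dkey)])
  cls[is.na(match(key, dkey))] <- "other"
  tb$degeneracy <- cls
  tb <- tb[, c("scaffold", "position", "ref", "alt", "degeneracy",
               "gt", "dp", "gq")]
  if (anyDuplicated(key))
    warn("duplicate (scaffold, position) records in VCF")
  list(variants = tb, metadata = metadata)
}

#' Apply the per-call and per-site quality filters
#'
#' A per-sample call is retained iff `depth > min_depth` OR
#' `genotype quality > min_gq` (strict inequalities; set
#' `combine = "and"` to require both). A site is then removed iff its
#' fraction of missing calls exceeds `max_missing`. Degeneracy is restricted
#' to 0-fold/4-fold classes. With `gc_conservative = TRUE` only SNPs whose
#' ref/alt pair is `{A,T}` or `{C,G}` — substitutions that leave GC content
#' unchanged — are kept (monomorphic sites are unaffected).
#'
#' @param variants Variant tibble from [read_variant_data()].
#' @param min_depth,min_gq Per-call thresholds (strict `>`; defaults 8, 20).
#' @param max_missing Maximum tolerated missing-call fraction (strict `>`
#'   removal; default 0.5).
#' @param gc_conservative Restrict SNPs to GC-conservative changes.
#' @param combine `"or"` (default, a call passes on either criterion) or
#'   `"and"`.
#' @return The filtered variant tibble (possibly empty).
#' @export
filter_sites <- function(variants, min_depth = 8, min_gq = 20,
                         max_missing = 0.5, gc_conservative = FALSE,
                         combine = c("or", "and")) {
  combine <- match.arg(combine)
  stopifnot(min_depth >= 0, min_gq >= 0, max_missing >= 0)
  tb <- variants
  if (!nrow(tb)) return(tb)
  dp <- tb$dp; gq <- tb$gq; gt <- tb$gt
  dp[is.na(dp)] <- -Inf; gq[is.na(gq)] <- -Inf
  pass <- if (combine == "or") (dp > min_depth) | (gq > min_gq) else
    (dp > min_depth) & (gq > min_gq)
  gt[!pass] <- NA_real_
  tb$gt <- gt
  miss_frac <- rowMeans(is.na(gt))
  tb <- tb[miss_frac <= max_missing, , drop = FALSE]
  tb <- tb[tb$degeneracy %in% c("zero_fold", "four_fold"), , drop = FALSE]
  if (gc_conservative && nrow(tb)) {
    is_snp <- !is.na(tb$alt)
    pair <- paste0(pmin(tb$ref, tb$alt), pmax(tb$ref, tb$alt))
    tb <- tb[!is_snp | pair %in% c("AT", "CG"), , drop = FALSE]
  }
  tb
}

#' Per-site allele counts for a sample subset
#'
#' Tallies, per site, the called haplotypes and alternate-allele count over
#' `samples` (default: all), and derives major/minor allele identities and
#' counts — the polarization input.
#'
#' @param variants Variant tibble (post-filtering).
#' @param samples Character vector of sample ids (columns of the genotype
#'   matrix) or `NULL` for all.
#' @return Tibble: `scaffold`, `position`, `ref`, `alt`, `degeneracy`,
#'   `called_haplotypes`, `alt_count`, `major`, `minor`, `major_count`,
#'   `minor_count`.
#' @export
allele_counts <- function(variants, samples = NULL) {
  tb <- variants
  gt <- tb$gt
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing)) stop_dfeload("unknown sample(s): ",
                                      paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  called <- 2 * rowSums(!is.na(gt))
  altc <- rowSums(gt, na.rm = TRUE)
  out <- tibble(scaffold = tb$scaffold, position = tb$position,
                ref = tb$ref, alt = tb$alt, degeneracy = tb$degeneracy,
                called_haplotypes = called, alt_count = altc)
  alt_major <- altc > called - altc
  out$major <- ifelse(is.na(tb$alt) | !alt_major, tb$ref, tb$alt)
  out$minor <- ifelse(is.na(tb$alt), NA_character_,
                      ifelse(alt_major, tb$ref, tb$alt))
  out$major_count <- pmax(altc, called - altc)
  out$minor_count <- pmin(altc, called - altc)
  out
}

#' Derived-allele counts per site for one population
#'
#' Joins population allele counts with a polarized site table
#' ([polarize_sites()] output keyed by scaffold/position) and returns the
#' per-site derived counts that feed [build_sfs()]. Monomorphic sites get
#' derived count 0 (their ref allele is taken as ancestral unless polarized
#' otherwise).
#'
#' @param variants Filtered variant tibble.
#' @param polarized Output of [polarize_sites()] with `scaffold` and
#'   `position` columns.
#' @param samples Sample ids of the population (`NULL` = all).
#' @return Tibble with `scaffold`, `position`, `degeneracy`,
#'   `derived_count`, `called_haplotypes`, `status`.
#' @export
derived_site_counts <- function(variants, polarized, samples = NULL) {
  ac <- allele_counts(variants, samples)
  key <- paste0(ac$scaffold, ":", ac$position)
  pkey <- paste0(polarized$scaffold, ":", polarized$position)
  idx <- match(key, pkey)
  der <- polarized$derived_allele[idx]
  status <- polarized$status[idx]
  is_mono <- is.na(ac$alt)
  status[is_mono] <- "monomorphic"
  derived_count <- dplyr::case_when(
    is_mono ~ 0,
    is.na(der) ~ NA_real_,
    der == ac$alt ~ ac$alt_count,
    TRUE ~ ac$called_haplotypes - ac$alt_count)
  status[!is_mono & is.na(status)] <- "dropped"
  derived_count[status == "dropped"] <- NA_real_
  tibble(scaffold = ac$scaffold, position = ac$position,
         degeneracy = ac$degeneracy, derived_count = derived_count,
         called_haplotypes = ac$called_haplotypes, status = status)
}

#' Per-population derived-allele frequency table
#'
#' Builds the input of the load statistics: one `freq_<label>` and
#' `n_<label>` column per population, using only sites whose ancestral state
#' was assigned for all populations.
#'
#' @param variants Filtered variant tibble.
#' @param polarized Output of [polarize_sites()].
#' @param population_map Tibble from [pool_populations()] (columns `label`,
#'   `samples`).
#' @return Tibble: `scaffold`, `position`, `degeneracy`, then per-population
#'   frequency and haplotype-count columns.
#' @export
derived_freq_table <- function(variants, polarized, population_map) {
  base <- NULL
  for (k in seq_len(nrow(population_map))) {
    lab <- population_map$label[k]
    dc <- derived_site_counts(variants, polarized,
                              samples = population_map$samples[[k]])
    if (is.null(base))
      base <- dc[, c("scaffold", "position", "degeneracy")]
    base[[paste0("freq_", lab)]] <- dc$derived_count / dc$called_haplotypes
    base[[paste0("n_", lab)]] <- dc$called_haplotypes
  }
  fcols <- grep("^freq_", names(base))
  base[stats::complete.cases(base[, fcols]), , drop = FALSE]
}

# ---- plain-text writers (used by the synthetic generator; round-trip safe) --

#' Write a variant tibble as an uncompressed VCF 4.2 file
#'
#' @param variants Variant tibble (`gt` dosage, `dp`, `gq` matrix columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  samples <- colnames(variants$gt)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[variants$gt + 1],
                   nrow(variants$gt), ncol(variants$gt))
  gt_str[is.na(variants$gt)] <- "./."
  cells <- matrix(paste0(gt_str, ":", variants$dp, ":", variants$gq),
                  nrow(gt_str), ncol(gt_str))
  body <- vapply(seq_len(nrow(variants)), function(s) {
    paste(c(variants$scaffold[s], variants$position[s], ".",
            variants$ref[s], variants$alt[s] %|NA|% ".", ".", "PASS", ".",
            "GT:DP:GQ", cells[s, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' @rdname write_variant_vcf
#' @export
write_degeneracy_table <- function(variants, path) {
  cls <- c(zero_fold = "0fold", four_fold = "4fold", other = "other")
  tb <- tibble(scaffold = variants$scaffold, position = variants$position,
               class = unname(cls[variants$degeneracy]))
  readr::write_tsv(tb[tb$class != "other", ], path)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @param metadata Sample metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path)
  invisible(path)
}
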