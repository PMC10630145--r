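# Sample pooling into populations and choice of the "central" reference
# population for load-statistic comparisons.

#' Pool samples into populations
#'
#' Groups samples by country; a country containing more than one admixture
#' group is split by group (labels `<country>-<group>`). Pools with fewer
#' than `min_size` individuals are dropped. Mean sampling coordinates are
#' recorded per retained population.
#'
#' @param metadata Tibble with `sample_id`, `country`, `admixture_group`,
#'   `lat`, `lon`.
#' @param min_size Minimum individuals per retained population (default 20).
#' @return A tibble (`label`, `n`, `mean_lat`, `mean_lon`, `samples`
#'   list-column); error if no population is retained.
#' @export
pool_populations <- function(metadata, min_size = 20) {
  stopifnot(nrow(metadata) > 0)
  md <- as_tibble(metadata)
  md <- md %>%
    dplyr::group_by(.data$country) %>%
    dplyr::mutate(label = if (dplyr::n_distinct(.data$admixture_group) > 1)
      paste0(.data$country, "-", .data$admixture_group) else .data$country) %>%
    dplyr::ungroup()
  pools <- md %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean_lat = mean(.data$lat), mean_lon = mean(.data$lon),
                     samples = list(.data$sample_id), .groups = "drop") %>%
    dplyr::filter(.data$n >= min_size) %>%
    dplyr::arrange(.data$label)
  if (!nrow(pools)) stop_dfeload("no populations retained (all pools < ",
                                 min_size, " individuals)")
  pools
}

#' Select the central reference population
#'
#' The population whose mean sampling coordinates lie closest (great-circle /
#' haversine distance) to the median latitude and longitude over all retained
#' samples' sampling locations. Ties break to the lexicographically smallest
#' label.
#'
#' @param population_map Tibble from [pool_populations()].
#' @param metadata Sample metadata tibble.
#' @return The central population's label (character scalar).
#' @export
select_central_population <- function(population_map, metadata) {
  stopifnot(nrow(population_map) >= 1)
  retained <- unlist(population_map$samples)
  md <- metadata[metadata$sample_id %in% retained, , drop = FALSE]
  centre <- c(median(md$lon), median(md$lat))
  d <- geosphere::distHaversine(
    centre, cbind(population_map$mean_lon, population_map$mean_lat))
  cand <- population_map$label[d == min(d)]
  sort(cand)[1]
}
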