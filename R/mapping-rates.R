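#' Compare per-sample read mapping rates between two assemblies
#'
#' For each metric (all-read mapping rate, properly-mapped rate) the
#' per-sample rates of the two assemblies are compared with the
#' two-sided Mann-Whitney U test and the direction of the median
#' difference is reported.
#'
#' @param rates tibble with columns `sample_id`, `assembly_id`,
#'   `all_read_rate`, `properly_mapped_rate` (percent), covering exactly
#'   two assemblies with at least two samples each.
#' @return tibble with one row per metric: `metric`, `U`, `p_value`,
#'   `method`, per-assembly medians and `higher_assembly`.
#' @export
compare_mapping_rates <- function(rates) {
  asms <- sort(unique(rates$assembly_id))
  if (length(asms) != 2) abort("rates table must cover exactly two assemblies")
  counts <- table(rates$assembly_id)
  if (any(counts < 2)) abort("need at least two samples per assembly")
  purrr::map_dfr(c("all_read_rate", "properly_mapped_rate"), function(metric) {
    a <- rates[[metric]][rates$assembly_id == asms[1]]
    b <- rates[[metric]][rates$assembly_id == asms[2]]
    t <- mwu_test(a, b)
    tibble::tibble(
      metric = metric, U = t$U, p_value = t$p_value, method = t$method,
      median_1 = t$median_x, median_2 = t$median_y,
      assembly_1 = asms[1], assembly_2 = asms[2],
      higher_assembly = dplyr::case_when(
        t$median_x > t$median_y ~ asms[1],
        t$median_x < t$median_y ~ asms[2],
        TRUE ~ NA_character_
      )
    )
  })
}
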