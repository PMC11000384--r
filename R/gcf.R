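#' Variant carrier frequency
#'
#' The fraction of called subjects carrying at least one alternate allele,
#' computed from allele counts as `(AC - Hom) / (0.5 * AN)` where `Hom` is
#' the number of homozygous individuals. This equals
#' `(n_het + n_hom) / n_called`.
#'
#' @param ac Allele count(s).
#' @param n_hom Homozygous-individual count(s).
#' @param an Total allele number(s); must be positive.
#' @return Numeric carrier frequency, vectorised.
#' @export
variant_carrier_frequency <- function(ac, n_hom, an) {
  if (any(an <= 0)) abort("AN must be positive")
  (ac - n_hom) / (0.5 * an)
}

#' Screening-tier category for a gene carrier frequency
#'
#' Tier boundaries follow carrier-screening practice: category 1 above 1/50,
#' category 2 in (1/100, 1/50], category 3 in (1/150, 1/100], category 4 in
#' (1/200, 1/150], `below` otherwise. Intervals are half-open with the upper
#' endpoint belonging to the lower tier (strict ">" at each boundary).
#'
#' @param gcf Non-negative gene carrier frequency (vectorised).
#' @return Character vector in
#'   `c("cat1", "cat2", "cat3", "cat4", "below")`.
#' @export
gcf_tier <- function(gcf) {
  if (any(gcf < 0, na.rm = TRUE)) abort("gcf must be non-negative")
  dplyr::case_when(
    gcf > 1 / 50 ~ "cat1",
    gcf > 1 / 100 ~ "cat2",
    gcf > 1 / 150 ~ "cat3",
    gcf > 1 / 200 ~ "cat4",
    TRUE ~ "below"
  )
}

#' Cumulative gene carrier frequency per subpopulation
#'
#' Sums [variant_carrier_frequency()] over a gene's known-P/LP variants
#' within each subpopulation, restricted to unrelated subjects by default.
#' The sum-of-frequencies definition can exceed 1 when many common variants
#' accumulate in one gene; such values are reported uncapped with a warning.
#'
#' @param cohort A `mendel_cohort`.
#' @param classified Output of [select_known_plp()].
#' @param conditions Inheritance modes of the genes scored (default
#'   recessive-condition genes, including `"both"`).
#' @param categories Catalogue categories contributing.
#' @param unrelated_only Exclude subjects flagged `related`.
#' @param min_n Subpopulations with fewer called subjects than this are
#'   flagged `low_confidence` (small samples overestimate GCF).
#' @return Tibble with one row per (gene, subpopulation): `gcf`,
#'   `n_variants`, `tier`, `low_confidence`, plus a nested
#'   `contributing` list-column of per-variant carrier frequencies.
#' @export
gene_gcf <- function(cohort, classified, conditions = recessive_modes,
                     categories = c(1, 2), unrelated_only = TRUE,
                     min_n = 100) {
  cl <- filter(classified, .data$is_known_plp,
               .data$plp_category %in% categories,
               .data$inheritance %in% conditions)
  subs <- subpop_allele_counts(cohort, unrelated_only = unrelated_only) %>%
    filter(.data$variant_id %in% cl$variant_id, .data$AN > 0) %>%
    mutate(carrier_freq = variant_carrier_frequency(.data$AC, .data$n_hom,
                                                    .data$AN)) %>%
    left_join(select(cl, "variant_id", "gene"), by = "variant_id")
  group_n <- cohort$subjects
  if (unrelated_only) group_n <- filter(group_n, !.data$related)
  group_n <- count(group_n, .data$subpopulation, name = "n_subpop")
  out <- subs %>%
    group_by(.data$gene, .data$subpopulation) %>%
    summarise(
      gcf = sum(.data$carrier_freq),
      n_variants = dplyr::n(),
      contributing = list(dplyr::pick(dplyr::all_of(c("variant_id",
                                                      "carrier_freq")))),
      .groups = "drop"
    ) %>%
    left_join(group_n, by = "subpopulation") %>%
    mutate(
      tier = gcf_tier(.data$gcf),
      low_confidence = .data$n_subpop < min_n
    )
  if (any(out$gcf > 1)) {
    warn("gene carrier frequency exceeds 1 for some (gene, subpopulation)")
  }
  out
}
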