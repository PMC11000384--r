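#' Founder-allele screen
#'
#' A known-P/LP variant is a founder-allele candidate in a subpopulation when
#' its within-subpopulation allele frequency exceeds `subpop_af_min` while
#' its maximum allele frequency in external global databases stays below
#' `global_af_max`. Variants absent from every external database are flagged
#' `absent_global`.
#'
#' @param cohort A `mendel_cohort`.
#' @param classified Output of [select_known_plp()].
#' @param subpop_af_min Within-subpopulation AF floor (default 1%).
#' @param global_af_max External AF ceiling (default 1%).
#' @param unrelated_only Restrict counts to unrelated subjects.
#' @return Tibble of hits, one row per (variant, subpopulation).
#' @export
find_founder_alleles <- function(cohort, classified, subpop_af_min = 0.01,
                                 global_af_max = 0.01,
                                 unrelated_only = FALSE) {
  mx <- tibble(variant_id = cohort$variants$variant_id,
               max_global_af = max_global_af(cohort$variants))
  subpop_allele_counts(cohort, unrelated_only = unrelated_only) %>%
    inner_join(select(classified, "variant_id", "gene", "plp_category"),
               by = "variant_id") %>%
    left_join(mx, by = "variant_id") %>%
    filter(.data$af > subpop_af_min,
           is.na(.data$max_global_af) | .data$max_global_af < global_af_max) %>%
    mutate(screen = "founder", absent_global = is.na(.data$max_global_af))
}

#' Exceedingly common P/LP variant screen
#'
#' Retains known-P/LP variants whose maximum within-cohort subpopulation AF
#' reaches `af_min`; those above `reclassify_af` are flagged as candidates
#' for benign reclassification.
#'
#' @param cohort A `mendel_cohort`.
#' @param classified Output of [select_known_plp()].
#' @param af_min Subpopulation AF threshold for a hit (default 2%).
#' @param reclassify_af AF above which the reclassification flag is set
#'   (default 5%).
#' @return Tibble of hits with `max_subpop_af`, `n_hom` and
#'   `reclassify_candidate`.
#' @export
find_common_plp <- function(cohort, classified, af_min = 0.02,
                            reclassify_af = 0.05) {
  subpop_allele_counts(cohort) %>%
    inner_join(select(classified, "variant_id", "gene", "plp_category"),
               by = "variant_id") %>%
    group_by(.data$variant_id, .data$gene, .data$plp_category) %>%
    summarise(max_subpop_af = max(.data$af, na.rm = TRUE),
              n_hom = sum(.data$n_hom), .groups = "drop") %>%
    filter(.data$max_subpop_af >= af_min) %>%
    mutate(screen = "common_plp",
           reclassify_candidate = .data$max_subpop_af > reclassify_af)
}

#' Correlation of cohort and global allele frequencies
#'
#' Pearson correlation (reported squared) between within-subpopulation allele
#' frequencies and a global database frequency, by default restricted to
#' variants rare (< 1%) in both.
#'
#' @param cohort A `mendel_cohort`.
#' @param classified Output of [select_known_plp()] (the variant set
#'   correlated).
#' @param global_db `"max"` for the maximum across all `af_*` columns, or the
#'   name of one column (e.g. `"af_gnomad"`).
#' @param rare_only Restrict to variants with AF < `rare_af` in both vectors.
#' @param rare_af Rarity cutoff (default 1%).
#' @return One-row tibble with `r2` and `n_variants`.
#' @export
af_correlation <- function(cohort, classified, global_db = "max",
                           rare_only = TRUE, rare_af = 0.01) {
  glob <- if (identical(global_db, "max")) {
    tibble(variant_id = cohort$variants$variant_id,
           global_af = max_global_af(cohort$variants))
  } else {
    tibble(variant_id = cohort$variants$variant_id,
           global_af = cohort$variants[[global_db]])
  }
  dat <- subpop_allele_counts(cohort) %>%
    filter(.data$variant_id %in% classified$variant_id, .data$AN > 0) %>%
    left_join(glob, by = "variant_id") %>%
    filter(!is.na(.data$global_af))
  if (rare_only) {
    dat <- filter(dat, .data$af < rare_af, .data$global_af < rare_af)
  }
  if (nrow(dat) < 3) abort("fewer than 3 variants after filtering")
  if (stats::sd(dat$af) == 0 || stats::sd(dat$global_af) == 0) {
    warn("zero variance in an allele-frequency vector")
    return(tibble(r2 = NA_real_, n_variants = nrow(dat)))
  }
  tibble(r2 = stats::cor(dat$af, dat$global_af)^2, n_variants = nrow(dat))
}

#' Homozygosity-depletion screen
#'
#' For globally rare variants, compares observed homozygote counts with the
#' random-mating expectation `n_called * q^2` (pooled-cohort `q`); a hit is a
#' variant with zero observed homozygotes but at least `min_expected`
#' expected, suggesting selection against the homozygous state. A
#' per-subpopulation variant of the screen (expectation computed within each
#' subpopulation, summed) is available behind `by_subpop`.
#'
#' @param cohort A `mendel_cohort`.
#' @param min_expected Expectation threshold (default 3).
#' @param global_af_max Global rarity cutoff (default 1%).
#' @param by_subpop Use within-subpopulation frequencies for the expectation.
#' @return Tibble of hits with `cohort_af`, `n_hom_observed`,
#'   `n_hom_expected`.
#' @export
depleted_homozygosity <- function(cohort, min_expected = 3,
                                  global_af_max = 0.01, by_subpop = FALSE) {
  rare <- globally_rare(cohort$variants, global_af_max)
  counts <- variant_counts(cohort$gt)
  expected <- if (!by_subpop) {
    counts$n_called * counts$af^2
  } else {
    subpop_allele_counts(cohort) %>%
      group_by(.data$variant_id) %>%
      summarise(e = sum(.data$n_called * .data$af^2, na.rm = TRUE),
                .groups = "drop") %>%
      { .$e[match(counts$variant_id, .$variant_id)] }
  }
  hits <- counts %>%
    mutate(n_hom_expected = expected,
           gene = cohort$variants$gene[match(.data$variant_id,
                                             cohort$variants$variant_id)]) %>%
    filter(rare[match(.data$variant_id, counts$variant_id)],
           .data$n_hom == 0,
           !is.na(.data$n_hom_expected),
           .data$n_hom_expected >= min_expected)
  hits %>%
    transmute(.data$variant_id, .data$gene, screen = "depleted_hom",
              cohort_af = .data$af, n_hom_observed = .data$n_hom,
              .data$n_hom_expected, .data$n_called)
}

#' Loss-of-function carrier and knockout catalogue
#'
#' Per-subject counts of rare LoF variants carried, overall and restricted to
#' panel genes; the list of LoF variants with at least one homozygote
#' ("human knockouts") together with carrier subject IDs; and
#' per-subpopulation mean and variance of homozygous-LoF counts.
#'
#' @param cohort A `mendel_cohort`.
#' @param af_threshold Global AF cutoff defining rare LoF.
#' @return List with tibbles `per_subject`, `homozygous_lof`, `by_subpop`.
#' @export
knockout_catalog <- function(cohort, af_threshold = 0.01) {
  is_lof <- lof_flag(cohort$variants, af_threshold)
  lof_ids <- cohort$variants$variant_id[is_lof]
  panel_genes <- if (!is.null(cohort$panels)) cohort$panels$gene else character()
  in_panel <- cohort$variants$gene[is_lof] %in% panel_genes
  gt <- cohort$gt[, lof_ids, drop = FALSE]
  carried <- !is.na(gt) & gt >= 1L
  hom <- !is.na(gt) & gt == 2L
  per_subject <- tibble(
    subject_id = rownames(gt),
    subpopulation = cohort$subjects$subpopulation[
      match(rownames(gt), cohort$subjects$subject_id)],
    n_lof = as.integer(rowSums(carried)),
    n_lof_panel = as.integer(rowSums(carried[, in_panel, drop = FALSE])),
    n_hom_lof = as.integer(rowSums(hom))
  )
  hom_any <- colSums(hom) > 0
  homozygous_lof <- tibble(
    variant_id = lof_ids[hom_any],
    gene = cohort$variants$gene[is_lof][hom_any],
    n_hom = as.integer(colSums(hom)[hom_any]),
    carriers = purrr::map(which(hom_any), ~ rownames(gt)[hom[, .x]])
  )
  by_subpop <- per_subject %>%
    group_by(.data$subpopulation) %>%
    summarise(mean_hom_lof = mean(.data$n_hom_lof),
              var_hom_lof = stats::var(.data$n_hom_lof),
              mean_lof = mean(.data$n_lof),
              mean_lof_panel = mean(.data$n_lof_panel),
              .groups = "drop")
  list(per_subject = per_subject, homozygous_lof = homozygous_lof,
       by_subpop = by_subpop)
}
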