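recessive_modes <- c("recessive", "both")
dominant_modes <- c("dominant", "both")

#' Per-subject P/LP carrier burden
#'
#' For each subject, counts the known-P/LP variants carried (a variant counts
#' once whether heterozygous or homozygous), the homozygous P/LP genotypes in
#' genes for autosomal recessive conditions, and the heterozygous P/LP
#' genotypes in genes for dominant conditions. Genes with inheritance
#' `"both"` contribute to both tallies.
#'
#' @param cohort A `mendel_cohort`.
#' @param classified Output of [select_known_plp()].
#' @param categories Catalogue categories counted (default 1 and 2, the
#'   currently-P/LP ones).
#' @return Tibble: `subject_id`, `subpopulation`, `n_plp_alleles`,
#'   `n_hom_recessive`, `n_het_dominant`, `carries_arc_allele`.
#' @export
subject_burdens <- function(cohort, classified, categories = c(1, 2)) {
  cl <- filter(classified, .data$is_known_plp,
               .data$plp_category %in% categories)
  gt <- cohort$gt[, cl$variant_id, drop = FALSE]
  carried <- !is.na(gt) & gt >= 1L
  hom <- !is.na(gt) & gt == 2L
  het <- !is.na(gt) & gt == 1L
  rec <- cl$inheritance %in% recessive_modes
  dom <- cl$inheritance %in% dominant_modes
  tibble(
    subject_id = rownames(gt),
    subpopulation = cohort$subjects$subpopulation[
      match(rownames(gt), cohort$subjects$subject_id)],
    n_plp_alleles = as.integer(rowSums(carried)),
    n_hom_recessive = as.integer(rowSums(hom[, rec, drop = FALSE])),
    n_het_dominant = as.integer(rowSums(het[, dom, drop = FALSE])),
    carries_arc_allele = unname(rowSums(carried[, rec, drop = FALSE]) > 0)
  )
}

#' Subpopulation carrier-burden summary from raw counts
#'
#' Computes the percentage and fold-enrichment surface of the subpopulation
#' burden table from its integer counts. The denominator for homozygote and
#' dominant-heterozygote percentages is the number of *carriers* in the
#' subpopulation (not its full size); fold enrichments compare those
#' per-carrier rates against the reference subpopulation.
#'
#' @param counts Tibble with one row per subpopulation: `subpopulation`,
#'   `n_subjects`, `n_carriers`, `n_hom_recessive_subjects`,
#'   `n_het_dominant_subjects`. Optional `mean_plp`, `min_plp`, `max_plp`
#'   columns are carried through.
#' @param ref_label Reference subpopulation for the fold columns (the study
#'   design uses the admixed group).
#' @return The input with `pct_carriers`, `pct_hom_recessive`,
#'   `pct_het_dominant`, `fold_hom_vs_ref` and `fold_het_vs_ref` appended
#'   (full precision; round only at presentation).
#' @export
summarise_subpop_counts <- function(counts, ref_label = "ADM") {
  counts <- as_tibble(counts)
  if (!ref_label %in% counts$subpopulation) {
    abort(paste("reference subpopulation not present:", ref_label))
  }
  ref <- counts[counts$subpopulation == ref_label, ]
  ref_hom_rate <- ref$n_hom_recessive_subjects / ref$n_carriers
  ref_het_rate <- ref$n_het_dominant_subjects / ref$n_carriers
  if (!is.finite(ref_hom_rate) || ref_hom_rate == 0) {
    warn("reference subpopulation has no homozygotes; hom folds undefined")
    ref_hom_rate <- NA_real_
  }
  counts %>%
    mutate(
      pct_carriers = 100 * .data$n_carriers / .data$n_subjects,
      pct_hom_recessive =
        100 * .data$n_hom_recessive_subjects / .data$n_carriers,
      pct_het_dominant =
        100 * .data$n_het_dominant_subjects / .data$n_carriers,
      fold_hom_vs_ref =
        (.data$n_hom_recessive_subjects / .data$n_carriers) / ref_hom_rate,
      fold_het_vs_ref =
        (.data$n_het_dominant_subjects / .data$n_carriers) / ref_het_rate
    )
}

#' Subpopulation carrier-burden summary from per-subject burdens
#'
#' Tallies [subject_burdens()] by subpopulation, then applies
#' [summarise_subpop_counts()].
#'
#' @param burdens Output of [subject_burdens()].
#' @param ref_label Reference subpopulation for fold enrichments.
#' @return One row per subpopulation with counts, percentages and folds.
#' @export
subpop_summary <- function(burdens, ref_label = "ADM") {
  counts <- burdens %>%
    group_by(.data$subpopulation) %>%
    summarise(
      n_subjects = dplyr::n(),
      n_carriers = sum(.data$n_plp_alleles >= 1),
      mean_plp = mean(.data$n_plp_alleles),
      min_plp = min(.data$n_plp_alleles),
      max_plp = max(.data$n_plp_alleles),
      n_hom_recessive_subjects = sum(.data$n_hom_recessive >= 1),
      n_het_dominant_subjects = sum(.data$n_het_dominant >= 1),
      .groups = "drop"
    )
  summarise_subpop_counts(counts, ref_label = ref_label)
}

#' Cohort-level carrier shares
#'
#' Overall carrier percentage, the share of subjects carrying at least one
#' recessive-condition P/LP allele (reported against both the carrier and the
#' whole-cohort denominator, since either reading occurs in practice), and
#' the dominant-heterozygote and recessive-homozygote shares of the cohort.
#'
#' @param n_subjects,n_carriers,n_arc_carriers,n_hom_recessive_subjects,n_het_dominant_subjects
#'   Integer counts (cohort-wide).
#' @return One-row tibble of percentages (full precision).
#' @export
cohort_carrier_summary <- function(n_subjects, n_carriers, n_arc_carriers,
                                   n_hom_recessive_subjects = NA_integer_,
                                   n_het_dominant_subjects = NA_integer_) {
  tibble(
    n_subjects = n_subjects,
    n_carriers = n_carriers,
    pct_carriers = 100 * n_carriers / n_subjects,
    pct_arc_of_carriers = 100 * n_arc_carriers / n_carriers,
    pct_arc_of_cohort = 100 * n_arc_carriers / n_subjects,
    pct_hom_recessive = 100 * n_hom_recessive_subjects / n_subjects,
    pct_het_dominant = 100 * n_het_dominant_subjects / n_subjects
  )
}

#' Homozygote-enrichment rank test between two subject groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on per-subject counts of
#' homozygous recessive P/LP genotypes. The exact null distribution is used
#' when both groups have at most `exact_max` observations and no ties occur;
#' otherwise the normal approximation with tie and continuity correction is
#' applied.
#'
#' @param burdens Output of [subject_burdens()].
#' @param group_a,group_b Subpopulation labels, or `"rest"` for the
#'   complement of `group_a`.
#' @param value Column of `burdens` to compare (default `n_hom_recessive`).
#' @param exact_max Size bound for exact enumeration.
#' @return One-row tibble: `U` (statistic for group A), `p_two_sided`, `n_a`,
#'   `n_b`, `method`.
#' @export
homozygote_enrichment_test <- function(burdens, group_a, group_b = "rest",
                                       value = "n_hom_recessive",
                                       exact_max = 12) {
  x <- burdens[[value]][burdens$subpopulation == group_a]
  y <- if (identical(group_b, "rest")) {
    burdens[[value]][burdens$subpopulation != group_a]
  } else {
    burdens[[value]][burdens$subpopulation == group_b]
  }
  rank_sum_test(x, y, exact_max = exact_max)
}

# Mann-Whitney core shared by the exported wrapper and tests.
rank_sum_test <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble(U = unname(wt$statistic), p_two_sided = wt$p.value,
         n_a = length(x), n_b = length(y),
         method = if (use_exact) "exact" else "normal_tie_corrected")
}

#' Screen dominant-condition P/LP variants rare within the cohort
#'
#' Retains known-P/LP variants in dominant-condition genes whose allele
#' frequency is below `subpop_af_max` in every cohort subpopulation, listing
#' heterozygous carrier counts.
#'
#' @param cohort A `mendel_cohort`.
#' @param classified Output of [select_known_plp()].
#' @param subpop_af_max Within-subpopulation AF ceiling (default 0.5%).
#' @param categories Catalogue categories considered.
#' @return Tibble of retained variants with `max_subpop_af`, `n_het`,
#'   `n_hom`.
#' @export
dominant_screen <- function(cohort, classified, subpop_af_max = 0.005,
                            categories = c(1, 2)) {
  cl <- filter(classified, .data$is_known_plp,
               .data$plp_category %in% categories,
               .data$inheritance %in% dominant_modes)
  if (nrow(cl) == 0) return(mutate(cl, max_subpop_af = numeric(0),
                                   n_het = integer(0), n_hom = integer(0)))
  af <- subpop_allele_counts(cohort) %>%
    filter(.data$variant_id %in% cl$variant_id) %>%
    group_by(.data$variant_id) %>%
    summarise(max_subpop_af = max(.data$af, na.rm = TRUE), .groups = "drop")
  tot <- variant_counts(cohort$gt) %>%
    select("variant_id", "n_het", "n_hom")
  cl %>%
    inner_join(af, by = "variant_id") %>%
    inner_join(tot, by = "variant_id") %>%
    filter(.data$max_subpop_af < subpop_af_max)
}
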