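#' Empirical trait percentiles
#'
#' Nearest-rank percentiles (quantile type 1: the smallest value with
#' cumulative proportion at least `p`) over all non-missing cohort values.
#' Nearest-rank is used rather than an interpolating definition because
#' extreme-value flags near the boundary depend on the choice; it is fixed
#' and documented here.
#'
#' @param traits Trait tibble (`subject_id` + trait columns).
#' @param trait Trait column name.
#' @param probs Probabilities (default 5th and 95th).
#' @param min_n Minimum number of non-missing values required.
#' @return Named numeric vector of thresholds.
#' @export
trait_percentiles <- function(traits, trait, probs = c(0.05, 0.95),
                              min_n = 20) {
  x <- traits[[trait]]
  if (is.null(x)) abort(paste("unknown trait:", trait))
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    abort(paste0("too few non-missing values for ", trait, " (",
                 length(x), " < ", min_n, ")"))
  }
  stats::quantile(x, probs = probs, type = 1, names = TRUE)
}

#' Extreme-trait screen over homozygotes of candidate variants
#'
#' For each (candidate variant, trait) pair, collects the trait values of
#' homozygous-alternate subjects and emits a hit when they are all (rule
#' `"all"`) or mostly (rule `"majority"`, strictly more than half) beyond the
#' same cohort percentile threshold: above the upper percentile
#' (`above_95th`-style) or below the lower one. One hit per (variant, trait,
#' direction). Variants without homozygotes are skipped.
#'
#' @param cohort A `mendel_cohort` with traits attached.
#' @param candidates Tibble of candidate variants (from
#'   [select_novel_candidates()]), or a character vector of variant IDs.
#' @param traits Trait names to screen (default: all attached traits).
#' @param probs Lower/upper percentile pair (default 0.05 and 0.95).
#' @param rule `"all"` or `"majority"`.
#' @return Tibble of hits: `variant_id`, `gene`, `trait`, `direction`,
#'   `n_hom`, `n_hom_extreme`, `threshold`, `hom_values` (list-column).
#' @export
extreme_homozygote_screen <- function(cohort, candidates,
                                      traits = trait_names(cohort),
                                      probs = c(0.05, 0.95),
                                      rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (is.null(cohort$traits)) abort("cohort has no trait table")
  ids <- if (is.character(candidates)) candidates else candidates$variant_id
  genes <- cohort$variants$gene[match(ids, cohort$variants$variant_id)]
  thresholds <- purrr::map(traits, function(tr) {
    trait_percentiles(cohort$traits, tr, probs = probs)
  })
  names(thresholds) <- traits
  hits <- list()
  for (i in seq_along(ids)) {
    g <- cohort$gt[, ids[i]]
    hom_ids <- rownames(cohort$gt)[!is.na(g) & g == 2L]
    if (length(hom_ids) == 0) next
    rows <- match(hom_ids, cohort$traits$subject_id)
    for (tr in traits) {
      vals <- cohort$traits[[tr]][rows]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      lo <- thresholds[[tr]][1]; hi <- thresholds[[tr]][2]
      for (dir in c("below_lower", "above_upper")) {
        extreme <- if (dir == "below_lower") vals < lo else vals > hi
        n_ext <- sum(extreme)
        ok <- if (rule == "all") all(extreme) else n_ext > length(vals) / 2
        if (ok && n_ext > 0) {
          hits[[length(hits) + 1L]] <- tibble(
            variant_id = ids[i], gene = genes[i], trait = tr,
            direction = if (dir == "below_lower")
              sprintf("below_%gth", 100 * probs[1]) else
              sprintf("above_%gth", 100 * probs[2]),
            n_hom = length(vals), n_hom_extreme = n_ext,
            threshold = unname(if (dir == "below_lower") lo else hi),
            hom_values = list(vals)
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(variant_id = character(), gene = character(),
                  trait = character(), direction = character(),
                  n_hom = integer(), n_hom_extreme = integer(),
                  threshold = numeric(), hom_values = list()))
  }
  bind_rows(hits)
}

#' Percentile flags for traits of known-P/LP carriers
#'
#' A screening aid (not a clinical call): for each known-P/LP variant with at
#' least one homozygote (recessive-condition genes) or heterozygote
#' (dominant-condition genes), reports the carriers' values of the traits
#' mapped to the gene, with percentile flags.
#'
#' @param cohort A `mendel_cohort` with traits.
#' @param classified Output of [select_known_plp()].
#' @param trait_map Tibble with `gene` and `trait` (one row per mapped
#'   trait). Unmapped genes are skipped.
#' @param probs Percentile pair used for flagging.
#' @return Tibble with one row per (variant, carrier, trait): the value, its
#'   empirical percentile and an `extreme` flag (`NA` value rows carry no
#'   flag).
#' @export
plp_carrier_trait_flags <- function(cohort, classified, trait_map,
                                    probs = c(0.05, 0.95)) {
  trait_map <- as_tibble(trait_map)
  cl <- classified %>%
    filter(.data$is_known_plp, .data$gene %in% trait_map$gene)
  rows <- list()
  for (i in seq_len(nrow(cl))) {
    g <- cohort$gt[, cl$variant_id[i]]
    want <- if (cl$inheritance[i] %in% recessive_modes) 2L else 1L
    carriers <- rownames(cohort$gt)[!is.na(g) & g == want]
    if (length(carriers) == 0) next
    for (tr in trait_map$trait[trait_map$gene == cl$gene[i]]) {
      th <- trait_percentiles(cohort$traits, tr, probs = probs)
      all_vals <- cohort$traits[[tr]]
      vals <- all_vals[match(carriers, cohort$traits$subject_id)]
      pctl <- vapply(vals, function(v) {
        if (is.na(v)) NA_real_ else
          100 * mean(all_vals[!is.na(all_vals)] <= v)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = cl$variant_id[i], gene = cl$gene[i],
        inheritance = cl$inheritance[i], zygosity = if (want == 2L) "hom" else "het",
        subject_id = carriers, trait = tr, value = vals, percentile = pctl,
        extreme = ifelse(is.na(vals), NA, vals < th[1] | vals > th[2])
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(variant_id = character(), gene = character(),
                  inheritance = character(), zygosity = character(),
                  subject_id = character(), trait = character(),
                  value = numeric(), percentile = numeric(),
                  extreme = logical()))
  }
  bind_rows(rows)
}
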