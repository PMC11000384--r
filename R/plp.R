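#' Mapping from ClinVar review-status strings to star counts
#'
#' ClinVar review status is consumed as an integer star count throughout the
#' package; this table documents the conversion applied when an input
#' annotation table carries the textual status instead.
#'
#' @return Tibble with `review_status` and `stars`.
#' @export
clinvar_star_table <- function() {
  tibble(
    review_status = c(
      "no assertion criteria provided",
      "no assertion provided",
      "criteria provided, single submitter",
      "criteria provided, conflicting interpretations",
      "criteria provided, multiple submitters, no conflicts",
      "reviewed by expert panel",
      "practice guideline"
    ),
    stars = c(0L, 0L, 1L, 1L, 2L, 3L, 4L)
  )
}

plp_classes <- c("pathogenic", "likely_pathogenic")
benign_classes <- c("benign", "likely_benign")
coding_consequences <- c("missense", "nonsense", "frameshift", "splice_site")
lof_consequences <- c("nonsense", "frameshift", "splice_site")

#' Classify variants into known-P/LP catalogue categories
#'
#' A variant enters the known-P/LP catalogue when it is disease-causing in
#' HGMD (`DM`/`DM_q`) and its ClinVar record supports (or historically
#' supported) a pathogenic call. The current ClinVar status then assigns the
#' category: 1 = P/LP with at least 2 review stars, 2 = P/LP with fewer than
#' 2 stars, 3 = conflicting interpretations or VUS, 4 = benign/likely benign
#' but previously annotated P/LP. Variants failing the database intersection
#' get `NA` (not in the catalogue).
#'
#' @param variants Annotation tibble (columns `clinvar_class`,
#'   `clinvar_stars`, `clinvar_prior_plp`, `hgmd_class`).
#' @return Integer vector of categories (1-4) with `NA` for non-catalogue
#'   variants.
#' @export
classify_plp_category <- function(variants) {
  cv <- variants$clinvar_class %||% rep("absent", nrow(variants))
  cv[is.na(cv)] <- "absent"
  stars <- variants$clinvar_stars %||% rep(NA_integer_, nrow(variants))
  prior <- variants$clinvar_prior_plp %||% rep(FALSE, nrow(variants))
  prior[is.na(prior)] <- FALSE
  hgmd <- variants$hgmd_class %||% rep("absent", nrow(variants))
  hgmd[is.na(hgmd)] <- "absent"
  dm <- hgmd %in% c("DM", "DM_q")
  cat <- rep(NA_integer_, nrow(variants))
  cat[dm & cv %in% plp_classes & !is.na(stars) & stars >= 2] <- 1L
  cat[dm & cv %in% plp_classes & (is.na(stars) | stars < 2)] <- 2L
  cat[dm & cv %in% c("conflicting", "vus")] <- 3L
  cat[dm & cv %in% benign_classes & prior] <- 4L
  cat
}

#' Select known pathogenic/likely pathogenic variants
#'
#' Applies the catalogue filters: maximum allele frequency below
#' `af_threshold` in every external global database (absence counts as rare),
#' a coding consequence (missense, nonsense, frameshift, splice-site) or an
#' explicit non-coding pathogenic flag, and the ClinVar-HGMD intersection
#' encoded by [classify_plp_category()]. Panel membership and inheritance are
#' joined from the cohort's gene-panel table when available.
#'
#' @param cohort A `mendel_cohort` (or an annotation tibble when `panels` is
#'   given explicitly).
#' @param af_threshold Global allele-frequency cutoff (default 1%).
#' @param categories Categories retained in the catalogue; summaries usually
#'   restrict to `c(1, 2)` downstream but all four are kept here.
#' @return Tibble of classified variants: `variant_id`, `gene`,
#'   `consequence`, `plp_category`, `is_known_plp`, `is_lof`,
#'   `max_global_af`, `inheritance`, `panels`.
#' @export
select_known_plp <- function(cohort, af_threshold = 0.01,
                             categories = 1:4) {
  ann <- if (inherits(cohort, "mendel_cohort")) cohort$variants else
    as_tibble(cohort)
  panels <- if (inherits(cohort, "mendel_cohort")) cohort$panels else NULL
  mx <- max_global_af(ann)
  rare <- globally_rare(ann, af_threshold)
  csq_ok <- ann$consequence %in% coding_consequences |
    (ann$noncoding_plp %||% rep(FALSE, nrow(ann))) %in% TRUE
  cat <- classify_plp_category(ann)
  keep <- rare & csq_ok & !is.na(cat) & cat %in% categories
  out <- ann[keep, c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                     "consequence")]
  out$plp_category <- cat[keep]
  out$is_known_plp <- TRUE
  out$max_global_af <- mx[keep]
  out$is_lof <- lof_flag(ann)[keep]
  if (!is.null(panels)) {
    out <- left_join(out, select(panels, "gene", "panels", "inheritance"),
                     by = "gene")
  } else {
    warn("no gene-panel table available; panel fields left empty")
    out$panels <- NA_character_
    out$inheritance <- NA_character_
  }
  as_tibble(out)
}

#' Flag loss-of-function variants
#'
#' LoF = nonsense, splice-site or frameshift consequence with maximum global
#' allele frequency below 1% (absence from all databases counts as rare).
#'
#' @param variants Annotation tibble.
#' @param af_threshold Global AF cutoff.
#' @return Logical vector.
#' @export
lof_flag <- function(variants, af_threshold = 0.01) {
  variants$consequence %in% lof_consequences &
    globally_rare(variants, af_threshold)
}

#' Select novel candidate deleterious variants
#'
#' Retains panel-gene variants that are rare (or absent) in every global
#' database, have CADD above `cadd_min` and GERP above `gerp_min`, at least
#' `min_hom` homozygotes in the cohort, no benign/likely-benign ClinVar
#' class, and are not already in the known-P/LP catalogue.
#'
#' @param cohort A `mendel_cohort`.
#' @param min_hom Minimum cohort homozygote count (default 3; the screening
#'   figure-level variant of the rule uses 2 — override here if wanted).
#' @param cadd_min,gerp_min In-silico deleteriousness cutoffs.
#' @param af_threshold Global AF cutoff.
#' @return Tibble of candidate variants with `n_hom` attached.
#' @export
select_novel_candidates <- function(cohort, min_hom = 3, cadd_min = 20,
                                    gerp_min = 3, af_threshold = 0.01) {
  ann <- cohort$variants
  counts <- variant_counts(cohort$gt)
  known <- select_known_plp(cohort, af_threshold = af_threshold)
  in_panel <- if (!is.null(cohort$panels)) ann$gene %in% cohort$panels$gene else
    rep(TRUE, nrow(ann))
  cadd <- ann$cadd %||% rep(NA_real_, nrow(ann))
  gerp <- ann$gerp %||% rep(NA_real_, nrow(ann))
  cv <- ann$clinvar_class %||% rep("absent", nrow(ann))
  keep <- in_panel &
    globally_rare(ann, af_threshold) &
    !is.na(cadd) & cadd > cadd_min &
    !is.na(gerp) & gerp > gerp_min &
    !(cv %in% benign_classes) &
    !(ann$variant_id %in% known$variant_id) &
    counts$n_hom[match(ann$variant_id, counts$variant_id)] >= min_hom
  out <- ann[keep, c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                     "consequence", "cadd", "gerp")]
  out$n_hom <- counts$n_hom[match(out$variant_id, counts$variant_id)]
  out$max_global_af <- max_global_af(ann)[keep]
  out$is_novel_candidate <- TRUE
  as_tibble(out)
}

#' Per-gene P/LP variant counts with gene-length adjustment
#'
#' Length adjustment is the P/LP count per kilobase of coding sequence
#' (`n_plp / (coding_length_bp / 1000)`).
#'
#' @param classified Output of [select_known_plp()] (optionally filtered to a
#'   category subset).
#' @param panel_genes Gene-panel tibble (`gene`, `coding_length_bp`); all its
#'   genes appear in the output, with zero counts where no P/LP variant
#'   exists.
#' @return Tibble `gene`, `n_plp`, `coding_length_bp`, `length_adjusted`.
#' @export
gene_plp_counts <- function(classified, panel_genes) {
  counts <- classified %>%
    filter(.data$is_known_plp) %>%
    count(.data$gene, name = "n_plp")
  out <- panel_genes %>%
    select("gene", "coding_length_bp") %>%
    left_join(counts, by = "gene") %>%
    mutate(
      n_plp = tidyr::replace_na(.data$n_plp, 0L),
      length_adjusted = ifelse(
        is.na(.data$coding_length_bp), NA_real_,
        .data$n_plp / (.data$coding_length_bp / 1000)
      )
    )
  if (any(is.na(out$length_adjusted) & out$n_plp > 0)) {
    warn("genes with P/LP variants but missing coding length: adjusted value NA")
  }
  as_tibble(out)
}

#' Summarise the distribution of P/LP variants over genes
#'
#' Computed over genes carrying at least one catalogue variant.
#'
#' @param gene_counts Output of [gene_plp_counts()] or any tibble with `gene`
#'   and `n_plp`.
#' @param lt Threshold for the "fewer than `lt` variants" share (default 5).
#' @return One-row tibble: `n_genes`, `n_variants`, `n_lt`, `pct_lt`,
#'   `pct_single` (share of genes with exactly one variant).
#' @export
gene_plp_distribution <- function(gene_counts, lt = 5) {
  g <- filter(gene_counts, .data$n_plp >= 1)
  tibble(
    n_genes = nrow(g),
    n_variants = sum(g$n_plp),
    n_lt = sum(g$n_plp < lt),
    pct_lt = 100 * sum(g$n_plp < lt) / nrow(g),
    pct_single = 100 * sum(g$n_plp == 1) / nrow(g)
  )
}

#' Share of cohort variants overlapping the panel genes
#'
#' @param n_snvs,n_indels Cohort-wide variant counts.
#' @param n_overlap_rare Number of variants overlapping the panel genes and
#'   rare in public databases.
#' @return One-row tibble with `n_total` and `pct_overlap`.
#' @export
panel_overlap_summary <- function(n_snvs, n_indels, n_overlap_rare) {
  n_total <- n_snvs + n_indels
  tibble(n_snvs = n_snvs, n_indels = n_indels, n_total = n_total,
         n_overlap_rare = n_overlap_rare,
         pct_overlap = 100 * n_overlap_rare / n_total)
}
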