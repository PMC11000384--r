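#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' Build a cohort object
#'
#' A `mendel_cohort` bundles everything the burden analyses consume: a
#' subjects-by-variants genotype matrix (with optional per-call depth/quality
#' matrices), the variant annotation table, the subject table (covariates),
#' the quantitative-trait table and the gene-panel table.
#'
#' Genotypes are coded `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `NA` (missing call). Variants are identified
#' throughout by the string `chrom:pos:ref:alt`; multi-allelic sites must be
#' decomposed to one alternate allele per entry before construction (the VCF
#' loader does this).
#'
#' @param gt Integer matrix, subjects x variants, values in `c(0, 1, 2, NA)`.
#'   Row names are subject IDs, column names variant IDs (`chrom:pos:ref:alt`).
#' @param variants Tibble of variant annotations; must contain `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt` and may carry `gene`, `consequence`,
#'   `clinvar_class`, `clinvar_stars`, `clinvar_prior_plp`, `hgmd_class`,
#'   `cadd`, `gerp`, `noncoding_plp` and any number of global allele-frequency
#'   columns prefixed `af_` (e.g. `af_gnomad`, `af_1kg`).
#' @param subjects Tibble with `subject_id`, `subpopulation`, `sex`
#'   (`"male"`/`"female"`), `age`, `PC1`..`PC4` and optionally a logical
#'   `related` column (used by the unrelated-only carrier-frequency paths).
#' @param traits Optional tibble with `subject_id` plus one numeric column per
#'   quantitative trait. `NULL` when no phenotypes are attached.
#' @param panels Optional tibble of panel genes with columns `gene`, `panels`
#'   (semicolon-separated panel names), `inheritance`
#'   (`recessive`/`dominant`/`both`/`other`) and `coding_length_bp`.
#' @param ad_ref,ad_alt,gq,dp Optional numeric matrices with the same
#'   dimensions as `gt`: reference/alternate allele depths, genotype quality
#'   and total depth per call. Required only by the QC filters.
#'
#' @return An object of class `mendel_cohort`.
#' @export
new_cohort <- function(gt, variants, subjects, traits = NULL, panels = NULL,
                       ad_ref = NULL, ad_alt = NULL, gq = NULL, dp = NULL) {
  if (!is.matrix(gt)) abort("`gt` must be a matrix")
  storage.mode(gt) <- "integer"
  bad <- gt[!is.na(gt)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  variants <- as_tibble(variants)
  subjects <- as_tibble(subjects)
  req_v <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(req_v %in% names(variants))) {
    abort(paste("`variants` must contain:", paste(req_v, collapse = ", ")))
  }
  req_s <- c("subject_id", "subpopulation", "sex", "age",
             paste0("PC", 1:4))
  if (!all(req_s %in% names(subjects))) {
    abort(paste("`subjects` must contain:", paste(req_s, collapse = ", ")))
  }
  if (anyDuplicated(variants$variant_id)) {
    abort("duplicate variant_id in annotation table")
  }
  if (is.null(rownames(gt))) rownames(gt) <- subjects$subject_id
  if (is.null(colnames(gt))) colnames(gt) <- variants$variant_id
  if (!identical(colnames(gt), variants$variant_id)) {
    abort("gt column names must match variants$variant_id (same order)")
  }
  if (!identical(rownames(gt), subjects$subject_id)) {
    abort("gt row names must match subjects$subject_id (same order)")
  }
  if (any(variants$pos < 1)) abort("positions must be >= 1")
  if (any(variants$ref == variants$alt)) abort("ref and alt must differ")
  for (m in list(ad_ref = ad_ref, ad_alt = ad_alt, gq = gq, dp = dp)) {
    if (!is.null(m) && !identical(dim(m), dim(gt))) {
      abort("per-call matrices must have the same dimensions as gt")
    }
  }
  if (!"related" %in% names(subjects)) subjects$related <- FALSE
  if (!is.null(traits)) {
    traits <- as_tibble(traits)
    if (!"subject_id" %in% names(traits)) abort("`traits` needs subject_id")
    if (!identical(traits$subject_id, subjects$subject_id)) {
      traits <- traits[match(subjects$subject_id, traits$subject_id), ]
    }
  }
  structure(
    list(gt = gt, variants = variants, subjects = subjects, traits = traits,
         panels = if (is.null(panels)) NULL else as_tibble(panels),
         ad_ref = ad_ref, ad_alt = ad_alt, gq = gq, dp = dp),
    class = "mendel_cohort"
  )
}

#' @export
print.mendel_cohort <- function(x, ...) {
  cat("<mendel_cohort>\n")
  cat("  subjects:", nrow(x$gt), "  variants:", ncol(x$gt), "\n")
  cat("  subpopulations:",
      paste(sort(unique(x$subjects$subpopulation)), collapse = ", "), "\n")
  if (!is.null(x$traits)) {
    cat("  traits:", ncol(x$traits) - 1L, "\n")
  }
  if (!is.null(x$panels)) {
    cat("  panel genes:", nrow(x$panels), "\n")
  }
  invisible(x)
}

#' @export
dim.mendel_cohort <- function(x) dim(x$gt)

#' Names of the quantitative traits attached to a cohort
#' @param cohort A `mendel_cohort`.
#' @return Character vector of trait names (empty if none).
#' @export
trait_names <- function(cohort) {
  if (is.null(cohort$traits)) return(character())
  setdiff(names(cohort$traits), "subject_id")
}

#' Allele and genotype counts for one variant
#'
#' Counts follow the gnomAD convention: missing calls are excluded, so
#' `AN = 2 * n_called` and `AC = n_het + 2 * n_hom`.
#'
#' @param cohort A `mendel_cohort`.
#' @param variant A variant ID (`chrom:pos:ref:alt`).
#' @param subject_subset Optional character vector of subject IDs to restrict
#'   the tally to.
#' @return One-row tibble with `variant_id`, `AC`, `AN`, `af`, `n_hom`,
#'   `n_het`, `n_called`.
#' @export
allele_counts <- function(cohort, variant, subject_subset = NULL) {
  if (!variant %in% colnames(cohort$gt)) {
    abort(paste0("variant not in cohort: ", variant))
  }
  g <- cohort$gt[, variant]
  if (!is.null(subject_subset)) {
    if (length(subject_subset) == 0) abort("empty subject_subset")
    missing_ids <- setdiff(subject_subset, rownames(cohort$gt))
    if (length(missing_ids)) {
      abort(paste("unknown subjects:", paste(missing_ids, collapse = ", ")))
    }
    g <- g[subject_subset]
  }
  gt_tally(g) %>% mutate(variant_id = variant, .before = 1)
}

# Vectorised tally for a genotype vector.
gt_tally <- function(g) {
  n_called <- sum(!is.na(g))
  n_hom <- sum(g == 2L, na.rm = TRUE)
  n_het <- sum(g == 1L, na.rm = TRUE)
  ac <- n_het + 2L * n_hom
  an <- 2L * n_called
  tibble(AC = ac, AN = an, af = if (an > 0) ac / an else NA_real_,
         n_hom = n_hom, n_het = n_het, n_called = n_called)
}

# Per-variant counts for the whole matrix (optionally a subject subset),
# returned as a tibble keyed by variant_id. Much faster than looping
# allele_counts().
variant_counts <- function(gt, subjects = NULL) {
  if (!is.null(subjects)) gt <- gt[subjects, , drop = FALSE]
  called <- colSums(!is.na(gt))
  n_hom <- colSums(gt == 2L, na.rm = TRUE)
  n_het <- colSums(gt == 1L, na.rm = TRUE)
  ac <- n_het + 2L * n_hom
  an <- 2L * called
  tibble(
    variant_id = colnames(gt),
    AC = as.integer(ac), AN = as.integer(an),
    af = unname(ifelse(an > 0, ac / an, NA_real_)),
    n_hom = as.integer(n_hom), n_het = as.integer(n_het),
    n_called = as.integer(called)
  )
}

#' Per-subpopulation allele frequencies
#'
#' @param cohort A `mendel_cohort`.
#' @param unrelated_only Drop subjects flagged `related` before counting.
#' @return Tibble with one row per (variant, subpopulation):
#'   `variant_id`, `subpopulation`, `AC`, `AN`, `af`, `n_hom`, `n_het`,
#'   `n_called`.
#' @export
subpop_allele_counts <- function(cohort, unrelated_only = FALSE) {
  subj <- cohort$subjects
  if (unrelated_only) subj <- filter(subj, !.data$related)
  split_ids <- split(subj$subject_id, subj$subpopulation)
  purrr::imap_dfr(split_ids, function(ids, label) {
    variant_counts(cohort$gt, ids) %>%
      mutate(subpopulation = label, .after = "variant_id")
  })
}

# max AF across the annotation table's af_* columns; NA when the variant is
# absent from every database.
max_global_af <- function(variants) {
  af_cols <- grep("^af_", names(variants), value = TRUE)
  if (length(af_cols) == 0) return(rep(NA_real_, nrow(variants)))
  m <- as.matrix(variants[af_cols])
  out <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

# TRUE where a variant is rare in every external database; absence from all
# databases counts as frequency zero.
globally_rare <- function(variants, af_threshold = 0.01) {
  mx <- max_global_af(variants)
  ifelse(is.na(mx), 0, mx) < af_threshold
}
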