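#' Load a cohort from standard files
#'
#' Reads a multi-sample VCF (FORMAT fields `GT`, and where present `AD`, `GQ`,
#' `DP`), a variant annotation TSV, a subject TSV and a gene-panel TSV, and
#' assembles them into a [new_cohort()] object. Multi-allelic VCF records are
#' decomposed into one entry per alternate allele, with genotypes recoded
#' against each alternate separately (other alternates count as reference).
#'
#' The subject table may carry any number of extra numeric columns beyond the
#' reserved ones (`subject_id`, `subpopulation`, `sex`, `age`, `PC1`-`PC4`,
#' `related`); these are treated as the quantitative-trait manifest.
#'
#' @param vcf_path Path to a VCF 4.2 file (plain or gzipped).
#' @param annotation_path Path to the variant annotation TSV (columns `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `consequence`, `clinvar_class`,
#'   `clinvar_stars`, `clinvar_prior_plp`, `hgmd_class`, `cadd`, `gerp`,
#'   optional `noncoding_plp`, plus `af_*` global-frequency columns), or
#'   `NULL` to retain all variants unannotated.
#' @param subjects_path Path to the subject TSV.
#' @param panels_path Path to the gene-panel TSV (columns `gene`, `panels`,
#'   `inheritance`, `coding_length_bp`), or `NULL`.
#' @param known_subpops Labels that are recognised without a warning.
#' @return A `mendel_cohort`.
#' @export
load_cohort <- function(vcf_path, annotation_path = NULL, subjects_path,
                        panels_path = NULL,
                        known_subpops = c("GAR", "WEP", "ADM", "PAR",
                                          "AFR", "SAS")) {
  for (p in c(vcf_path, annotation_path, subjects_path, panels_path)) {
    if (!is.null(p) && !file.exists(p)) abort(paste("file not found:", p))
  }
  subjects <- read_subjects(subjects_path, known_subpops = known_subpops)
  geno <- read_vcf_genotypes(vcf_path)

  missing_subj <- setdiff(subjects$subjects$subject_id, rownames(geno$gt))
  if (length(missing_subj)) {
    abort(paste("subjects in table but absent from VCF:",
                paste(missing_subj, collapse = ", ")))
  }
  keep <- subjects$subjects$subject_id
  gt <- geno$gt[keep, , drop = FALSE]
  sub_mat <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]

  variants <- geno$variants
  if (!is.null(annotation_path)) {
    ann <- read_annotations(annotation_path)
    ann$variant_id <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
    if (anyDuplicated(ann$variant_id)) {
      dups <- ann$variant_id[duplicated(ann$variant_id)]
      abort(paste("duplicate annotation rows for:",
                  paste(unique(dups), collapse = ", ")))
    }
    variants <- left_join(
      variants,
      select(ann, -"chrom", -"pos", -"ref", -"alt"),
      by = "variant_id"
    )
    # unannotated variants keep NA database fields; normalise the controlled
    # vocabularies to explicit "absent" and fix column types (an empty
    # annotation file reads back as all-character)
    for (col in c("clinvar_class", "hgmd_class")) {
      if (col %in% names(variants)) {
        variants[[col]] <- tidyr::replace_na(as.character(variants[[col]]),
                                             "absent")
      }
    }
    for (col in c("clinvar_prior_plp", "noncoding_plp")) {
      if (col %in% names(variants)) {
        variants[[col]] <- tidyr::replace_na(as.logical(variants[[col]]),
                                             FALSE)
      }
    }
    for (col in c(grep("^af_", names(variants), value = TRUE),
                  "cadd", "gerp", "clinvar_stars")) {
      if (col %in% names(variants)) {
        variants[[col]] <- as.numeric(variants[[col]])
      }
    }
  }
  panels <- if (is.null(panels_path)) NULL else read_panels(panels_path)

  new_cohort(gt, variants, subjects$subjects, traits = subjects$traits,
             panels = panels, ad_ref = sub_mat(geno$ad_ref),
             ad_alt = sub_mat(geno$ad_alt), gq = sub_mat(geno$gq),
             dp = sub_mat(geno$dp))
}

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Parse a VCF into decomposed per-alt genotype/depth matrices.
read_vcf_genotypes <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_chr <- vcfR::extract.gt(v, "GT")
  has_fmt <- function(f) any(grepl(f, v@gt[, "FORMAT"]))
  ad_chr <- if (has_fmt("AD")) vcfR::extract.gt(v, "AD") else NULL
  gq_num <- if (has_fmt("GQ")) vcfR::extract.gt(v, "GQ", as.numeric = TRUE) else NULL
  dp_num <- if (has_fmt("DP")) vcfR::extract.gt(v, "DP", as.numeric = TRUE) else NULL

  samples <- colnames(gt_chr)
  rows <- list(); gts <- list(); ads_r <- list(); ads_a <- list()
  gqs <- list(); dps <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gstr <- gt_chr[i, ]
    alleles <- strsplit(gstr, "[/|]")
    adstr <- if (is.null(ad_chr)) NULL else strsplit(ad_chr[i, ], ",", fixed = TRUE)
    for (k in seq_along(alts)) {
      code <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k]
      )
      gts[[length(gts) + 1L]] <- code
      if (!is.null(adstr)) {
        ads_r[[length(ads_r) + 1L]] <- vapply(adstr, function(a) {
          if (length(a) < k + 1 || anyNA(a)) NA_real_ else as.numeric(a[1])
        }, numeric(1))
        ads_a[[length(ads_a) + 1L]] <- vapply(adstr, function(a) {
          if (length(a) < k + 1 || anyNA(a)) NA_real_ else as.numeric(a[k + 1])
        }, numeric(1))
      }
      if (!is.null(gq_num)) gqs[[length(gqs) + 1L]] <- gq_num[i, ]
      if (!is.null(dp_num)) dps[[length(dps) + 1L]] <- dp_num[i, ]
    }
  }
  variants <- bind_rows(rows)
  variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  bind_mat <- function(lst) {
    if (length(lst) == 0) return(NULL)
    m <- do.call(cbind, lst)
    rownames(m) <- samples
    colnames(m) <- variants$variant_id
    m
  }
  gt <- bind_mat(gts)
  storage.mode(gt) <- "integer"
  list(
    gt = gt,
    variants = select(variants, "variant_id", "chrom", "pos", "ref", "alt"),
    ad_ref = bind_mat(ads_r), ad_alt = bind_mat(ads_a),
    gq = bind_mat(gqs), dp = bind_mat(dps)
  )
}

read_subjects <- function(path, known_subpops) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  reserved <- c("subject_id", "subpopulation", "sex", "age",
                paste0("PC", 1:4), "related")
  req <- setdiff(reserved, "related")
  if (!all(req %in% names(tab))) {
    abort(paste("subject table must contain:", paste(req, collapse = ", ")))
  }
  tab$sex <- tolower(tab$sex)
  if (!all(tab$sex %in% c("male", "female"))) {
    abort("sex must be male/female (case-insensitive)")
  }
  tab$subpopulation <- toupper(tab$subpopulation)
  unknown <- setdiff(unique(tab$subpopulation), toupper(known_subpops))
  if (length(unknown)) {
    warn(paste("unknown subpopulation labels:", paste(unknown, collapse = ", ")))
  }
  trait_cols <- setdiff(names(tab), reserved)
  traits <- NULL
  if (length(trait_cols)) {
    traits <- tab[c("subject_id", trait_cols)]
  }
  list(subjects = tab[intersect(reserved, names(tab))], traits = traits)
}

read_annotations <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
           "clinvar_class", "clinvar_stars", "hgmd_class")
  if (!all(req %in% names(tab))) {
    abort(paste("annotation table must contain:", paste(req, collapse = ", ")))
  }
  af_cols <- grep("^af_", names(tab), value = TRUE)
  for (col in af_cols) {
    bad <- !is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 1)
    if (any(bad)) abort(paste("allele frequencies outside [0,1] in", col))
  }
  if (any(!is.na(tab$clinvar_stars) & !tab$clinvar_stars %in% 0:4)) {
    abort("clinvar_stars must be integers 0-4")
  }
  tab
}

read_panels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene", "panels", "inheritance", "coding_length_bp")
  if (!all(req %in% names(tab))) {
    abort(paste("panel table must contain:", paste(req, collapse = ", ")))
  }
  if (any(!is.na(tab$coding_length_bp) & tab$coding_length_bp <= 0)) {
    abort("coding_length_bp must be positive")
  }
  tab
}

#' Write an analysis table to disk
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @param digits Number of decimal digits used for floating-point columns.
#' @return Invisibly, the path.
#' @export
write_report <- function(table, path, format = c("tsv", "json"), digits = 6) {
  format <- match.arg(format)
  table <- as_tibble(table)
  if (nrow(table) == 0) warn(paste("writing empty table to", path))
  table <- mutate(table, across(where(is.double), ~ round(.x, digits)))
  ok <- tryCatch({
    if (format == "tsv") {
      readr::write_tsv(table, path, progress = FALSE)
    } else {
      jsonlite::write_json(table, path, digits = NA, na = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste("cannot write", path, ":", conditionMessage(ok)))
  invisible(path)
}

#' Write a cohort's genotypes back to VCF
#'
#' Produces a bgzip-compressed VCF 4.2 with FORMAT `GT:AD:GQ:DP` (fields
#' dropped when the corresponding matrices are absent). Entries are written
#' as biallelic records in cohort order.
#'
#' @param cohort A `mendel_cohort`.
#' @param path Output path; `.gz` is appended if missing.
#' @return Invisibly, the path written.
#' @export
write_cohort_vcf <- function(cohort, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  v <- cohort$variants
  n_var <- nrow(v); n_sub <- nrow(cohort$gt)
  fix <- cbind(
    CHROM = as.character(v$chrom), POS = as.character(v$pos), ID = ".",
    REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS", INFO = "."
  )
  fields <- c("GT",
              if (!is.null(cohort$ad_ref) && !is.null(cohort$ad_alt)) "AD",
              if (!is.null(cohort$gq)) "GQ",
              if (!is.null(cohort$dp)) "DP")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cohort$gt + 1L],
                   nrow = n_sub, ncol = n_var)
  gt_str[is.na(cohort$gt)] <- "./."
  cell <- gt_str
  fmt_num <- function(m) {
    s <- matrix(as.character(m), nrow = n_sub)
    s[is.na(m)] <- "."
    s
  }
  if ("AD" %in% fields) {
    ad <- matrix(paste(fmt_num(cohort$ad_ref), fmt_num(cohort$ad_alt),
                       sep = ","), nrow = n_sub)
    ad[is.na(cohort$ad_ref) | is.na(cohort$ad_alt)] <- "."
    cell <- matrix(paste(cell, ad, sep = ":"), nrow = n_sub)
  }
  if ("GQ" %in% fields) {
    cell <- matrix(paste(cell, fmt_num(cohort$gq), sep = ":"), nrow = n_sub)
  }
  if ("DP" %in% fields) {
    cell <- matrix(paste(cell, fmt_num(cohort$dp), sep = ":"), nrow = n_sub)
  }
  gt_mat <- cbind(paste(fields, collapse = ":"), t(cell))
  colnames(gt_mat) <- c("FORMAT", rownames(cohort$gt))
  meta <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
  )
  loadNamespace("vcfR")
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt_mat)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}
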