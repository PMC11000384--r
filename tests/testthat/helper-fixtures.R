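# Hand-built fixtures and independent oracles used across the suite.

# A small cohort with fully controlled genotypes. `gt` is subjects x variants;
# annotations default to a well-behaved known-P/LP profile that can be
# overridden per column via `ann_overrides` (a list of column -> vector).
make_cohort <- function(gt, inheritance = NULL, ann_overrides = list(),
                        traits = NULL, subpop = NULL, genes = NULL,
                        ad_ref = NULL, ad_alt = NULL, gq = NULL, dp = NULL) {
  n <- nrow(gt); v <- ncol(gt)
  ids <- sprintf("S%03d", seq_len(n))
  rownames(gt) <- ids
  genes <- genes %||% sprintf("G%02d", seq_len(v))
  variants <- tibble::tibble(
    chrom = "1", pos = 1000L + seq_len(v), ref = "A", alt = "T",
    gene = genes,
    consequence = "missense",
    clinvar_class = "pathogenic", clinvar_stars = 2L,
    clinvar_prior_plp = TRUE, hgmd_class = "DM",
    cadd = 25, gerp = 4, noncoding_plp = FALSE,
    af_gnomad = 0.001, af_1kg = 0.001
  )
  variants$variant_id <- paste(variants$chrom, variants$pos, variants$ref,
                               variants$alt, sep = ":")
  for (col in names(ann_overrides)) variants[[col]] <- ann_overrides[[col]]
  colnames(gt) <- variants$variant_id
  subjects <- tibble::tibble(
    subject_id = ids,
    subpopulation = subpop %||% rep("GAR", n),
    sex = rep(c("male", "female"), length.out = n),
    age = rep(40, n), PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0,
    related = FALSE
  )
  panels <- tibble::tibble(
    gene = unique(genes), panels = "panel_01",
    inheritance = if (is.null(inheritance)) "recessive" else
      inheritance[match(unique(genes), genes)],
    coding_length_bp = 2000L
  )
  if (!is.null(traits)) {
    traits <- tibble::tibble(subject_id = ids, !!!traits)
  }
  nm <- function(m) { if (!is.null(m)) dimnames(m) <- dimnames(gt); m }
  new_cohort(gt, variants, subjects, traits = traits, panels = panels,
             ad_ref = nm(ad_ref), ad_alt = nm(ad_alt), gq = nm(gq),
             dp = nm(dp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force per-subject / per-variant tally: the loop oracle.
oracle_counts <- function(g) {
  n_hom <- 0L; n_het <- 0L; n_called <- 0L
  for (x in g) {
    if (is.na(x)) next
    n_called <- n_called + 1L
    if (x == 2L) n_hom <- n_hom + 1L
    if (x == 1L) n_het <- n_het + 1L
  }
  list(AC = n_het + 2L * n_hom, AN = 2L * n_called, n_hom = n_hom,
       n_het = n_het, n_called = n_called)
}

# Exact Mann-Whitney p by enumeration of all label arrangements (small n).
oracle_wilcoxon_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  obs <- u_stat(x, y)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  switch(alternative,
         less = mean(us <= obs),
         greater = mean(us >= obs),
         two.sided = min(1, 2 * min(mean(us <= obs), mean(us >= obs))))
}

# Random-pairing simulation of the conditional HWE law: shuffle the 2n
# alleles, pair them, count heterozygotes. Independent of the analytic path.
oracle_hwe_sim <- function(n, n_minor, reps = 20000) {
  alleles <- c(rep(1L, n_minor), rep(0L, 2 * n - n_minor))
  hets <- replicate(reps, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  table(factor(hets, levels = 0:min(n_minor, n))) / reps
}
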