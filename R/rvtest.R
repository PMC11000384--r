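#' QC thresholds for the rare-variant burden scan
#'
#' Defaults are the stringent whole-genome filters used for burden testing:
#' heterozygous calls kept when allele balance lies strictly inside
#' (`het_ab_low`, `het_ab_high`), homozygous-alternate calls when allele
#' balance exceeds `hom_ab_min`, all calls when genotype quality exceeds
#' `gq_min`; variants kept when the post-filter call rate exceeds
#' `call_rate_min`, the Hardy-Weinberg exact-test p-value is at least
#' `hwe_p_min`, and the cohort and all external allele frequencies are below
#' `af_max`; singletons (AC = 1) are always dropped, and doubletons (AC = 2)
#' are kept only when every carrier call has depth at least
#' `doubleton_dp_min` (`doubleton_rule = "keep_high_depth"`; the opposite
#' literal reading is available as `"drop_high_depth"`).
#'
#' @param het_ab_low,het_ab_high,hom_ab_min Allele-balance bounds.
#' @param gq_min Genotype-quality floor (exclusive).
#' @param call_rate_min Variant call-rate floor (exclusive).
#' @param hwe_p_min Hardy-Weinberg exact p floor (inclusive).
#' @param af_max Rarity ceiling for cohort and external AFs (exclusive).
#' @param doubleton_dp_min Carrier-depth requirement for doubletons.
#' @param doubleton_rule See above.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(het_ab_low = 0.2, het_ab_high = 0.8,
                          hom_ab_min = 0.80, gq_min = 10,
                          call_rate_min = 0.90, hwe_p_min = 1e-6,
                          af_max = 0.01, doubleton_dp_min = 10,
                          doubleton_rule = c("keep_high_depth",
                                             "drop_high_depth")) {
  doubleton_rule <- match.arg(doubleton_rule)
  if (het_ab_low < 0 || het_ab_high > 1 || het_ab_low >= het_ab_high ||
      hom_ab_min < 0 || hom_ab_min > 1) {
    abort("allele-balance bounds must satisfy 0 <= low < high <= 1")
  }
  if (call_rate_min < 0 || call_rate_min > 1) abort("call_rate_min in [0,1]")
  structure(list(het_ab_low = het_ab_low, het_ab_high = het_ab_high,
                 hom_ab_min = hom_ab_min, gq_min = gq_min,
                 call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
                 af_max = af_max, doubleton_dp_min = doubleton_dp_min,
                 doubleton_rule = doubleton_rule),
            class = "qc_thresholds")
}

#' Conditional Hardy-Weinberg genotype distribution
#'
#' Exact distribution of the heterozygote count conditional on the sample
#' size and allele counts under random mating; support is every heterozygote
#' count with the same parity as the minor-allele count.
#'
#' @param n Number of genotyped individuals.
#' @param n_minor Minor-allele count (0 to `n`... `2n`).
#' @return Tibble `n_het`, `prob` (sums to 1).
#' @export
hwe_genotype_probs <- function(n, n_minor) {
  if (n <= 0) abort("n must be positive")
  if (n_minor < 0 || n_minor > n) {
    # work on the minor allele: fold if a major count was passed
    if (n_minor > 2 * n) abort("n_minor exceeds allele number")
    n_minor <- 2 * n - n_minor
  }
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  lp <- vapply(hets, function(h) {
    n_aa <- (n_minor - h) / 2
    n_AA <- n - n_aa - h
    lfactorial(n) - lfactorial(n_AA) - lfactorial(h) - lfactorial(n_aa) +
      h * log(2) - lchoose(2 * n, n_minor)
  }, numeric(1))
  tibble(n_het = as.integer(hets), prob = exp(lp))
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: the p-value is the total probability, under the
#' conditional distribution of [hwe_genotype_probs()], of heterozygote counts
#' whose probability does not exceed that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return Two-sided exact p-value.
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) abort("all genotype counts are zero")
  n_alt <- n_het + 2 * n_hom_alt
  n_minor <- min(n_alt, 2 * n - n_alt)
  dist <- hwe_genotype_probs(n, n_minor)
  p_obs <- dist$prob[dist$n_het == n_het]
  if (length(p_obs) == 0) abort("observed heterozygote count impossible given allele counts")
  min(1, sum(dist$prob[dist$prob <= p_obs * (1 + 1e-12)]))
}

#' Apply burden-scan QC filters to a cohort
#'
#' Per-call filters (allele balance, genotype quality) set failing calls
#' missing; calls lacking AD or GQ fail closed. Per-variant filters then
#' remove variants by post-filter call rate, Hardy-Weinberg exact test,
#' cohort and external allele frequency, and the singleton/doubleton rules.
#'
#' @param cohort A `mendel_cohort` with `ad_ref`, `ad_alt`, `gq`, `dp`
#'   matrices.
#' @param thresholds A [qc_thresholds()] list.
#' @return List with `cohort` (calls masked, failing variants dropped) and
#'   `report` (per-variant tibble: call rate, HWE p, AC, pass flag and the
#'   first failing filter).
#' @export
qc_filter <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  gt <- cohort$gt
  if (is.null(cohort$ad_ref) || is.null(cohort$ad_alt) || is.null(cohort$gq)) {
    abort("qc_filter needs AD and GQ matrices")
  }
  tot <- cohort$ad_ref + cohort$ad_alt
  ab <- ifelse(tot > 0, cohort$ad_alt / tot, NA_real_)
  bad <- matrix(FALSE, nrow(gt), ncol(gt))
  het <- !is.na(gt) & gt == 1L
  hom <- !is.na(gt) & gt == 2L
  called <- !is.na(gt)
  bad[het] <- is.na(ab[het]) | ab[het] <= thresholds$het_ab_low |
    ab[het] >= thresholds$het_ab_high
  bad[hom] <- is.na(ab[hom]) | ab[hom] <= thresholds$hom_ab_min
  bad[called] <- bad[called] | is.na(cohort$gq[called]) |
    cohort$gq[called] <= thresholds$gq_min
  gt[bad] <- NA_integer_

  counts <- variant_counts(gt)
  call_rate <- counts$n_called / nrow(gt)
  hwe_p <- vapply(seq_len(nrow(counts)), function(i) {
    nc <- counts$n_called[i]
    if (nc == 0) return(NA_real_)
    hwe_exact_p(nc - counts$n_het[i] - counts$n_hom[i],
                counts$n_het[i], counts$n_hom[i])
  }, numeric(1))
  rare_ext <- globally_rare(cohort$variants, thresholds$af_max)
  rare_coh <- !is.na(counts$af) & counts$af < thresholds$af_max

  dbl_ok <- rep(TRUE, ncol(gt))
  is_dbl <- counts$AC == 2L
  if (any(is_dbl) && !is.null(cohort$dp)) {
    for (j in which(is_dbl)) {
      carrier <- !is.na(gt[, j]) & gt[, j] >= 1L
      high_depth <- all(!is.na(cohort$dp[carrier, j]) &
                          cohort$dp[carrier, j] >= thresholds$doubleton_dp_min)
      dbl_ok[j] <- if (thresholds$doubleton_rule == "keep_high_depth")
        high_depth else !high_depth
    }
  }

  fail <- dplyr::case_when(
    call_rate <= thresholds$call_rate_min ~ "call_rate",
    is.na(hwe_p) | hwe_p < thresholds$hwe_p_min ~ "hwe",
    !rare_coh ~ "cohort_af",
    !rare_ext ~ "global_af",
    counts$AC == 1L ~ "singleton",
    is_dbl & !dbl_ok ~ "doubleton",
    counts$AC == 0L ~ "monomorphic",
    TRUE ~ NA_character_
  )
  report <- counts %>%
    mutate(call_rate = call_rate, hwe_p = hwe_p, pass = is.na(fail),
           fail_reason = fail)
  keep <- which(report$pass)
  out <- cohort
  out$gt <- gt[, keep, drop = FALSE]
  out$variants <- cohort$variants[keep, ]
  for (m in c("ad_ref", "ad_alt", "gq", "dp")) {
    if (!is.null(out[[m]])) out[[m]] <- out[[m]][, keep, drop = FALSE]
  }
  list(cohort = out, report = report)
}

#' Collapse a gene's qualifying variants into a per-subject burden score
#'
#' The burden is the unweighted sum of genotype codes (0/1/2) over the gene's
#' qualifying variants; missing calls contribute 0. Aggregated genotype-class
#' counts (`RR|RA|AA`, summed over variants among called genotypes) are
#' attached as attributes.
#'
#' @param cohort A QC-filtered `mendel_cohort`.
#' @param gene Gene symbol.
#' @return Named numeric vector of burdens (attributes `n_variants`,
#'   `class_counts`, `variant_ids`).
#' @export
collapse_gene <- function(cohort, gene) {
  ids <- cohort$variants$variant_id[cohort$variants$gene %in% gene]
  if (length(ids) == 0) abort(paste("no qualifying variants for gene", gene))
  g <- cohort$gt[, ids, drop = FALSE]
  b <- rowSums(g, na.rm = TRUE)
  cc <- c(RR = sum(g == 0L, na.rm = TRUE), RA = sum(g == 1L, na.rm = TRUE),
          AA = sum(g == 2L, na.rm = TRUE))
  attr(b, "n_variants") <- length(ids)
  attr(b, "class_counts") <- cc
  attr(b, "variant_ids") <- ids
  b
}

# rank inverse-normal transform
rin_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- stats::qnorm((rank(x[ok]) - 0.5) / sum(ok))
  out
}

#' Covariate-adjusted burden regression for one gene and trait
#'
#' Ordinary least squares of the trait on the burden score plus covariates
#' (age, sex, first four principal components) over complete cases — a
#' fixed-effects stand-in for a mixed model, with the PCs absorbing
#' population structure. Reports the burden coefficient, its 1-df Wald
#' chi-square and the corresponding upper-tail p-value.
#'
#' @param b Burden vector from [collapse_gene()] (names = subject IDs).
#' @param trait Numeric trait vector aligned with `b`.
#' @param covariates Data frame of covariates aligned with `b`.
#' @return One-row tibble: `beta`, `se`, `chi_sq`, `p_value`, `n_used`,
#'   `n_variants`, `class_counts` (string `RR|RA|AA`). `NULL`-like row (all
#'   NA) when the burden has zero variance.
#' @export
burden_regression <- function(b, trait, covariates) {
  covariates <- as.data.frame(covariates)
  if ("sex" %in% names(covariates) && !is.numeric(covariates$sex)) {
    covariates$sex <- as.numeric(covariates$sex == "male")
  }
  cc_attr <- attr(b, "class_counts")
  nv <- attr(b, "n_variants") %||% NA_integer_
  keep <- !is.na(trait) & stats::complete.cases(covariates)
  bb <- as.numeric(b)[keep]
  null_row <- tibble(beta = NA_real_, se = NA_real_, chi_sq = NA_real_,
                     p_value = NA_real_, n_used = sum(keep),
                     n_variants = nv,
                     class_counts = if (is.null(cc_attr)) NA_character_ else
                       paste(cc_attr, collapse = "|"))
  if (sum(keep) < ncol(covariates) + 3 || stats::var(bb) == 0) {
    return(null_row)
  }
  X <- cbind(`(Intercept)` = 1, burden = bb,
             as.matrix(covariates[keep, , drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste("collinear covariates:", paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, trait[keep])
  rss <- sum(fit$residuals^2)
  df <- length(bb) - ncol(X)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  beta_hat <- unname(fit$coefficients["burden"])
  se_b <- unname(se[which(colnames(X) == "burden")])
  chi <- (beta_hat / se_b)^2
  out <- null_row
  out$beta <- beta_hat
  out$se <- se_b
  out$chi_sq <- chi
  out$p_value <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out
}

#' Genome-wide gene-level burden scan
#'
#' Runs [qc_filter()], then [collapse_gene()] + [burden_regression()] for
#' every (gene, trait) pair, adjusting for age, sex and PC1-PC4.
#'
#' @param cohort A `mendel_cohort` with traits and per-call QC matrices.
#' @param thresholds A [qc_thresholds()] list, or `NULL` to skip QC (the
#'   cohort is used as-is).
#' @param traits Trait names to scan (default all).
#' @param p_threshold Significance threshold (default 1e-8).
#' @param transform `"none"` (raw traits) or `"rin"` (rank inverse-normal per
#'   trait).
#' @return Object of class `burden_scan`: list with `results` (full sortable
#'   tibble with `significant` flag), `qc_report`, `p_threshold`,
#'   `n_subjects`.
#' @export
genome_wide_scan <- function(cohort, thresholds = qc_thresholds(),
                             traits = trait_names(cohort),
                             p_threshold = 1e-8,
                             transform = c("none", "rin")) {
  transform <- match.arg(transform)
  if (is.null(cohort$traits)) abort("cohort has no trait table")
  qc_report <- NULL
  if (!is.null(thresholds)) {
    qc <- qc_filter(cohort, thresholds)
    qc_report <- qc$report
    cohort_q <- qc$cohort
  } else {
    cohort_q <- cohort
  }
  covars <- cohort_q$subjects %>%
    transmute(age = .data$age, sex = as.numeric(.data$sex == "male"),
              PC1 = .data$PC1, PC2 = .data$PC2, PC3 = .data$PC3,
              PC4 = .data$PC4) %>%
    as.data.frame()
  genes <- sort(unique(cohort_q$variants$gene))
  genes <- genes[!is.na(genes)]
  results <- list()
  for (g in genes) {
    b <- collapse_gene(cohort_q, g)
    for (tr in traits) {
      y <- cohort_q$traits[[tr]]
      if (transform == "rin") y <- rin_transform(y)
      res <- burden_regression(b, y, covars)
      results[[length(results) + 1L]] <- mutate(res, gene = g, trait = tr,
                                                .before = 1)
    }
  }
  results <- bind_rows(results) %>%
    mutate(significant = !is.na(.data$p_value) &
             .data$p_value < p_threshold) %>%
    arrange(.data$p_value)
  structure(list(results = results, qc_report = qc_report,
                 p_threshold = p_threshold, n_subjects = nrow(cohort$gt)),
            class = "burden_scan")
}

#' @export
print.burden_scan <- function(x, ...) {
  cat("<burden_scan>", nrow(x$results), "gene-trait pairs;",
      sum(x$results$significant), "significant at p <", x$p_threshold, "\n")
  print(utils::head(x$results, 5))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a burden scan into its full results table
#' @param x A `burden_scan`.
#' @param ... Unused.
#' @return Tibble of per-(gene, trait) results sorted by p-value.
#' @export
tidy.burden_scan <- function(x, ...) x$results

#' One-row summary of a burden scan
#' @param x A `burden_scan`.
#' @param ... Unused.
#' @return Tibble with counts of pairs tested and significant hits.
#' @export
glance.burden_scan <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$results),
    n_genes = dplyr::n_distinct(x$results$gene),
    n_traits = dplyr::n_distinct(x$results$trait),
    n_significant = sum(x$results$significant),
    p_threshold = x$p_threshold,
    n_subjects = x$n_subjects
  )
}
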