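#' Simulation configuration for a synthetic biobank cohort
#'
#' Builds the parameter list consumed by [simulate_cohort()]. Defaults emulate
#' a consanguineous Middle-Eastern biobank: six genetic subpopulations of
#' unequal size with distinct inbreeding coefficients, panel variants with
#' database-style annotations and subpopulation-divergent allele frequencies,
#' and quantitative traits driven by age, sex and principal components with
#' optional spiked large-effect variants.
#'
#' The default subpopulation sizes follow the 6045-subject cohort composition
#' (GAR 2311, WEP 1372, ADM 1180, PAR 1052, AFR 92, SAS 38), scaled by
#' `n_subjects / 6045`. Default inbreeding coefficients average ~0.018
#' (consistent with ~29% first/second-cousin parental consanguinity at
#' F = 0.0625 per first-cousin union), with the Peninsular-Arab-like group
#' highest; they are illustrative, not estimates.
#'
#' @param seed Integer seed; every draw in the simulation derives from it.
#' @param n_subjects Total cohort size (distributed over subpopulations).
#' @param subpops Tibble with `label`, `prop` (relative size) and `f`
#'   (inbreeding coefficient in `[0, 1)`).
#' @param n_genes,n_variants Panel size of the simulated annotation space.
#' @param af_range Range (min, max) of base alternate-allele frequencies for
#'   rare panel variants, sampled log-uniformly.
#' @param novel_af_range Base-frequency range for designated novel candidate
#'   variants (elevated so homozygotes occur, as for founder-inflated alleles).
#' @param common_af_range Base-frequency range for designated benign common
#'   variants.
#' @param divergence_sdlog Log-normal SD of per-(variant, subpopulation)
#'   frequency multipliers (founder-style divergence).
#' @param frac_known_plp,frac_novel,frac_benign_common Fractions of variants
#'   designated as known P/LP, novel deleterious candidates, and common benign.
#' @param founder_spikes Tibble with `variant` (index), `subpop`, `target_af`;
#'   applied by [spike_founder_allele()] after the base draw.
#' @param n_traits Number of quantitative traits (named `trait_01`, ...).
#' @param trait_sd Residual (noise) standard deviation of each trait; spiked
#'   genetic effects are expressed in these units.
#' @param beta_age,beta_sex,gamma_pc Covariate effects on every trait:
#'   per-year age slope, male offset, and length-4 loadings on PC1-PC4 (all
#'   in trait-SD units).
#' @param effect_spikes Tibble with `variant` (index), `trait` (name),
#'   `effect` (in trait SD) and `model` (`"recessive"` or `"additive"`).
#' @param trait_missingness Fraction of trait values set missing at random.
#' @param gt_missing_rate Fraction of genotype calls set missing at random.
#' @param dp_mean Mean sequencing depth (Poisson).
#' @param gq_mean,gq_sd Genotype-quality distribution (normal, truncated to
#'   0-99 and rounded).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 6045L,
                       subpops = NULL,
                       n_genes = 120L,
                       n_variants = 400L,
                       af_range = c(2e-4, 8e-3),
                       novel_af_range = c(0.015, 0.05),
                       common_af_range = c(0.02, 0.10),
                       divergence_sdlog = 0.4,
                       frac_known_plp = 0.25,
                       frac_novel = 0.10,
                       frac_benign_common = 0.05,
                       founder_spikes = NULL,
                       n_traits = 10L,
                       trait_sd = 1,
                       beta_age = 0.015,
                       beta_sex = 0.4,
                       gamma_pc = c(0.3, 0.2, 0.1, 0.1),
                       effect_spikes = NULL,
                       trait_missingness = 0.02,
                       gt_missing_rate = 0.005,
                       dp_mean = 35,
                       gq_mean = 60,
                       gq_sd = 18) {
  if (is.null(subpops)) {
    subpops <- tibble(
      label = c("GAR", "WEP", "ADM", "PAR", "AFR", "SAS"),
      prop  = c(2311, 1372, 1180, 1052, 92, 38) / 6045,
      f     = c(0.020, 0.008, 0.004, 0.035, 0.012, 0.012)
    )
  }
  subpops <- as_tibble(subpops)
  if (any(subpops$f < 0)) abort("inbreeding coefficient f must be >= 0")
  if (any(subpops$f >= 1)) abort("inbreeding coefficient f must be < 1")
  cfg <- list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    subpops = subpops, n_genes = as.integer(n_genes),
    n_variants = as.integer(n_variants), af_range = af_range,
    novel_af_range = novel_af_range, common_af_range = common_af_range,
    divergence_sdlog = divergence_sdlog, frac_known_plp = frac_known_plp,
    frac_novel = frac_novel, frac_benign_common = frac_benign_common,
    founder_spikes = founder_spikes, n_traits = as.integer(n_traits),
    trait_sd = trait_sd, beta_age = beta_age, beta_sex = beta_sex,
    gamma_pc = gamma_pc, effect_spikes = effect_spikes,
    trait_missingness = trait_missingness,
    gt_missing_rate = gt_missing_rate, dp_mean = dp_mean,
    gq_mean = gq_mean, gq_sd = gq_sd
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Draw genotypes under the inbreeding model
#'
#' For allele frequency `q` and inbreeding coefficient `F`, genotype
#' probabilities are `P(hom-alt) = q^2 + F q (1-q)`,
#' `P(het) = 2 q (1-q)(1-F)`, `P(hom-ref) = (1-q)^2 + F q (1-q)`; draws are
#' independent across subjects and variants. `F = 0` recovers
#' Hardy-Weinberg proportions. Frequencies outside (0, 1) are clipped with a
#' warning.
#'
#' @param n Number of subjects.
#' @param q Allele frequency, one value per variant.
#' @param f Inbreeding coefficient in `[0, 1)`.
#' @return `n` x `length(q)` integer matrix of genotype codes 0/1/2.
#' @export
simulate_genotypes <- function(n, q, f = 0) {
  if (f < 0) abort("inbreeding coefficient must be >= 0")
  out_of_range <- q <= 0 | q >= 1
  if (any(out_of_range)) {
    warn("allele frequencies clipped into (0, 1)")
    q <- pmin(pmax(q, 1e-6), 1 - 1e-6)
  }
  p2 <- q^2 + f * q * (1 - q)
  p1 <- 2 * q * (1 - q) * (1 - f)
  u <- matrix(stats::runif(n * length(q)), nrow = n)
  t2 <- matrix(p2, nrow = n, ncol = length(q), byrow = TRUE)
  t1 <- matrix(p2 + p1, nrow = n, ncol = length(q), byrow = TRUE)
  g <- matrix(0L, nrow = n, ncol = length(q))
  g[u < t1] <- 1L
  g[u < t2] <- 2L
  g
}

#' Simulate a complete synthetic cohort
#'
#' Draws genotypes under the per-subpopulation inbreeding model, applies
#' founder-allele spikes, generates database-style variant annotations and a
#' gene-panel table, simulates quantitative traits with covariate structure
#' and spiked variant effects, and attaches per-call depth/quality noise so
#' the QC filters have non-trivial effect.
#'
#' @param config A [sim_config()] list.
#' @return A list with elements `cohort` (a `mendel_cohort`) and `truth`
#'   (ground-truth tibbles: `subpop_afs` with the frequencies actually used,
#'   `designations` per variant, `founder_spikes`, `effect_spikes`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sp <- config$subpops
  n_per <- pmax(1L, round(config$n_subjects * sp$prop / sum(sp$prop)))
  n_per[which.max(n_per)] <- n_per[which.max(n_per)] +
    config$n_subjects - sum(n_per)
  if (any(n_per < 1)) abort("n_subjects too small for the subpopulation mix")
  V <- config$n_variants

  # variant designations drive both the frequency model and the annotations
  n_plp <- round(V * config$frac_known_plp)
  n_nov <- round(V * config$frac_novel)
  n_common <- round(V * config$frac_benign_common)
  designation <- rep("neutral", V)
  idx <- sample.int(V)
  designation[idx[seq_len(n_plp)]] <- "known_plp"
  designation[idx[n_plp + seq_len(n_nov)]] <- "novel_candidate"
  designation[idx[n_plp + n_nov + seq_len(n_common)]] <- "benign_common"

  log_unif <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
  base_q <- log_unif(V, config$af_range)
  base_q[designation == "novel_candidate"] <-
    log_unif(sum(designation == "novel_candidate"), config$novel_af_range)
  base_q[designation == "benign_common"] <-
    log_unif(sum(designation == "benign_common"), config$common_af_range)

  # per-(variant, subpop) divergence multipliers (founder-style drift)
  q_sub <- sapply(seq_len(nrow(sp)), function(j) {
    pmin(base_q * stats::rlnorm(V, 0, config$divergence_sdlog), 0.5)
  })
  colnames(q_sub) <- sp$label

  subject_id <- sprintf("S%05d", seq_len(sum(n_per)))
  subpop_of <- rep(sp$label, n_per)
  gt <- matrix(NA_integer_, nrow = sum(n_per), ncol = V,
               dimnames = list(subject_id, NULL))
  for (j in seq_len(nrow(sp))) {
    rows <- which(subpop_of == sp$label[j])
    gt[rows, ] <- simulate_genotypes(length(rows), q_sub[, j], sp$f[j])
  }

  variants <- tibble(
    chrom = as.character(1 + (seq_len(V) - 1) %% 22),
    pos = 10000L + 100L * seq_len(V),
    ref = sample(c("A", "C", "G", "T"), V, replace = TRUE),
    alt = NA_character_
  )
  variants$alt <- vapply(variants$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  variants$variant_id <- variant_id(variants$chrom, variants$pos,
                                    variants$ref, variants$alt)
  colnames(gt) <- variants$variant_id

  truth <- list(
    subpop_afs = as_tibble(q_sub) %>%
      mutate(variant_id = variants$variant_id, base_q = base_q) %>%
      tidyr::pivot_longer(cols = all_of(sp$label),
                          names_to = "subpopulation", values_to = "q"),
    designations = tibble(variant_id = variants$variant_id,
                          designation = designation),
    f_used = tibble(subpopulation = sp$label, f = sp$f),
    founder_spikes = tibble(variant_id = character(), subpopulation = character(),
                            target_af = numeric()),
    effect_spikes = tibble(variant_id = character(), trait = character(),
                           effect = numeric(), model = character())
  )

  sim <- list(gt = gt, variants = variants, subpop_of = subpop_of,
              subjects = NULL, truth = truth, config = config)

  if (!is.null(config$founder_spikes)) {
    fs <- as_tibble(config$founder_spikes)
    for (i in seq_len(nrow(fs))) {
      sim <- spike_founder_allele(sim, fs$variant[i], fs$subpop[i],
                                  fs$target_af[i])
    }
  }

  ann <- simulate_annotations(config, variants, designation)
  subjects <- simulate_subjects(config, subject_id, subpop_of)
  traits <- simulate_traits(config, sim$gt, subjects, ann$variants)
  sim$truth$effect_spikes <- attr(traits, "spikes") %||% sim$truth$effect_spikes
  attr(traits, "spikes") <- NULL

  qc <- simulate_call_noise(config, sim$gt)

  cohort <- new_cohort(qc$gt, ann$variants, subjects, traits = traits,
                       panels = ann$panels, ad_ref = qc$ad_ref,
                       ad_alt = qc$ad_alt, gq = qc$gq, dp = qc$dp)
  list(cohort = cohort, truth = sim$truth)
}

#' Re-draw one variant's genotypes in one subpopulation at a founder frequency
#'
#' Internal step of [simulate_cohort()], exported for targeted tests: the
#' variant's genotypes inside the target subpopulation are replaced by a fresh
#' draw at `target_af` under the same inbreeding law; subjects outside the
#' subpopulation are untouched.
#'
#' @param sim Intermediate simulation state (as built inside
#'   [simulate_cohort()]): a list with `gt`, `variants`, `subpop_of`, `truth`
#'   and `config`.
#' @param variant Variant index (column) or variant ID.
#' @param subpop Subpopulation label.
#' @param target_af Spiked allele frequency, in (0, 1).
#' @return The updated simulation state.
#' @export
spike_founder_allele <- function(sim, variant, subpop, target_af) {
  if (target_af >= 1 || target_af <= 0) abort("target_af must be in (0, 1)")
  if (is.character(variant)) variant <- match(variant, sim$variants$variant_id)
  if (is.na(variant) || variant < 1 || variant > ncol(sim$gt)) {
    abort("variant not found")
  }
  if (!subpop %in% sim$config$subpops$label) abort("unknown subpopulation")
  rows <- which(sim$subpop_of == subpop)
  f <- sim$config$subpops$f[sim$config$subpops$label == subpop]
  sim$gt[rows, variant] <- simulate_genotypes(length(rows), target_af, f)[, 1]
  vid <- sim$variants$variant_id[variant]
  sim$truth$subpop_afs <- sim$truth$subpop_afs %>%
    mutate(q = ifelse(.data$variant_id == vid & .data$subpopulation == subpop,
                      target_af, .data$q))
  sim$truth$founder_spikes <- bind_rows(
    sim$truth$founder_spikes,
    tibble(variant_id = vid, subpopulation = subpop, target_af = target_af)
  )
  sim
}

simulate_subjects <- function(config, subject_id, subpop_of) {
  n <- length(subject_id)
  sp <- config$subpops
  centers <- matrix(stats::rnorm(nrow(sp) * 4, 0, 1), nrow = nrow(sp),
                    dimnames = list(sp$label, paste0("PC", 1:4)))
  pcs <- centers[subpop_of, , drop = FALSE] +
    matrix(stats::rnorm(n * 4, 0, 0.3), nrow = n)
  tibble(
    subject_id = subject_id,
    subpopulation = subpop_of,
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(0.563, 0.437)),
    age = pmin(pmax(round(stats::rnorm(n, 40, 12)), 18), 85),
    PC1 = pcs[, 1], PC2 = pcs[, 2], PC3 = pcs[, 3], PC4 = pcs[, 4],
    related = FALSE
  )
}

#' Simulate quantitative traits with covariate structure and spiked effects
#'
#' Each trait follows
#' `trait = beta_age * (age - 40) + beta_sex * male + sum(gamma_k PC_k)
#'  + sum(spike effects) + N(0, trait_sd^2)`,
#' where a recessive spike adds `effect` to homozygous-alternate carriers and
#' an additive spike adds `effect * gt`. Effects are in units of the residual
#' trait SD. A configured fraction of values is then set missing at random.
#'
#' @param config A [sim_config()].
#' @param gt Genotype matrix (subjects x variants) used for spiked effects.
#' @param subjects Subject tibble (covariates).
#' @param variants Variant tibble (for resolving spike variant IDs).
#' @return Tibble `subject_id` + one column per trait; the realised spike
#'   table is attached as attribute `"spikes"`.
#' @export
simulate_traits <- function(config, gt, subjects, variants) {
  n <- nrow(subjects)
  covar <- config$beta_age * (subjects$age - 40) * config$trait_sd +
    config$beta_sex * (subjects$sex == "male") * config$trait_sd +
    as.matrix(subjects[paste0("PC", 1:4)]) %*% config$gamma_pc * config$trait_sd
  covar <- as.numeric(covar)
  trait_nm <- sprintf("trait_%02d", seq_len(config$n_traits))
  vals <- matrix(stats::rnorm(n * config$n_traits, 0, config$trait_sd),
                 nrow = n) + covar
  colnames(vals) <- trait_nm

  spikes <- NULL
  if (!is.null(config$effect_spikes)) {
    es <- as_tibble(config$effect_spikes)
    for (i in seq_len(nrow(es))) {
      tr <- es$trait[i]
      if (!tr %in% trait_nm) abort(paste("unknown trait in spike:", tr))
      v <- es$variant[i]
      if (is.character(v)) v <- match(v, variants$variant_id)
      g <- gt[, v]
      gstar <- if (es$model[i] == "recessive") as.numeric(g == 2L) else
        as.numeric(g)
      gstar[is.na(gstar)] <- 0
      vals[, tr] <- vals[, tr] + es$effect[i] * config$trait_sd * gstar
    }
    spikes <- es
    spikes$variant_id <- if (is.character(es$variant)) es$variant else
      variants$variant_id[as.integer(es$variant)]
  }
  if (config$trait_missingness > 0) {
    drop <- matrix(stats::runif(length(vals)) < config$trait_missingness,
                   nrow = n)
    vals[drop] <- NA_real_
  }
  out <- bind_cols(tibble(subject_id = subjects$subject_id), as_tibble(vals))
  attr(out, "spikes") <- spikes
  out
}

#' Simulate database-style annotations and a gene-panel table
#'
#' Variants designated `known_plp` receive ClinVar P/LP (or
#' conflicting/benign-with-prior-P/LP for category-3/4 examples) together with
#' HGMD DM/DM? and global AFs below 1%; `novel_candidate` variants receive
#' CADD > 20, GERP > 3 and no benign class; `benign_common` variants receive a
#' benign class and global AFs of several percent.
#'
#' @param config A [sim_config()].
#' @param variants Variant key tibble from the genotype draw.
#' @param designation Character vector of construction-time designations.
#' @return List with `variants` (full annotation tibble) and `panels`.
#' @export
simulate_annotations <- function(config, variants, designation) {
  V <- nrow(variants)
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  gene_of <- sample(genes, V, replace = TRUE)
  panel_names <- sprintf("panel_%02d", 1:20)
  panels <- tibble(
    gene = genes,
    panels = vapply(genes, function(g) {
      paste(sample(panel_names, sample(1:2, 1)), collapse = ";")
    }, character(1)),
    inheritance = sample(c("recessive", "dominant", "both", "other"),
                         length(genes), replace = TRUE,
                         prob = c(0.60, 0.25, 0.10, 0.05)),
    coding_length_bp = pmax(300L, round(stats::rlnorm(length(genes),
                                                      log(1500), 0.5)))
  )

  csq_coding <- c("missense", "nonsense", "frameshift", "splice_site")
  ann <- variants %>%
    mutate(
      gene = gene_of,
      designation = designation,
      consequence = dplyr::case_when(
        designation == "known_plp" ~
          sample(csq_coding, V, replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15)),
        designation == "novel_candidate" ~
          sample(c("missense", "splice_site"), V, replace = TRUE,
                 prob = c(0.85, 0.15)),
        TRUE ~ sample(c("missense", "synonymous", "other_noncoding"), V,
                      replace = TRUE, prob = c(0.4, 0.4, 0.2))
      ),
      cadd = dplyr::case_when(
        designation == "known_plp" ~ stats::runif(V, 15, 45),
        designation == "novel_candidate" ~ stats::runif(V, 20.5, 45),
        TRUE ~ stats::runif(V, 0, 25)
      ),
      gerp = dplyr::case_when(
        designation == "known_plp" ~ stats::runif(V, 2, 6),
        designation == "novel_candidate" ~ stats::runif(V, 3.1, 6),
        TRUE ~ stats::runif(V, -2, 5)
      ),
      noncoding_plp = FALSE
    )

  # ClinVar status mix inside the known-P/LP designation produces all four
  # catalogue categories (current P/LP with >=2 or <2 stars, reclassified
  # conflicting/VUS, reclassified benign with a prior P/LP record).
  u <- stats::runif(V)
  ann <- ann %>%
    mutate(
      clinvar_class = dplyr::case_when(
        designation == "known_plp" & u < 0.45 ~ "pathogenic",
        designation == "known_plp" & u < 0.70 ~ "likely_pathogenic",
        designation == "known_plp" & u < 0.85 ~ "conflicting",
        designation == "known_plp" & u < 0.92 ~ "vus",
        designation == "known_plp" ~ "benign",
        designation == "benign_common" ~
          sample(c("benign", "likely_benign"), V, replace = TRUE),
        designation == "novel_candidate" ~
          sample(c("absent", "vus"), V, replace = TRUE, prob = c(0.7, 0.3)),
        TRUE ~ sample(c("absent", "vus", "likely_benign"), V, replace = TRUE,
                      prob = c(0.7, 0.2, 0.1))
      ),
      clinvar_stars = sample(0:3, V, replace = TRUE,
                             prob = c(0.25, 0.35, 0.3, 0.1)),
      clinvar_prior_plp = designation == "known_plp",
      hgmd_class = dplyr::case_when(
        designation == "known_plp" ~
          sample(c("DM", "DM_q"), V, replace = TRUE, prob = c(0.8, 0.2)),
        TRUE ~ sample(c("absent", "other"), V, replace = TRUE,
                      prob = c(0.8, 0.2))
      )
    )

  # global database AFs: rare designations stay below 1 %, benign-common sits
  # at several percent, and a slice of variants is absent from every database
  raw_af <- exp(stats::runif(V, log(1e-5), log(9e-3)))
  raw_af[ann$designation == "benign_common"] <-
    stats::runif(sum(ann$designation == "benign_common"), 0.02, 0.15)
  absent_db <- stats::runif(V) < 0.15 & ann$designation != "benign_common"
  rare_cap <- ifelse(ann$designation == "benign_common", 0.98, 0.0099)
  jitter_af <- function(x) pmin(x * stats::rlnorm(V, 0, 0.3), rare_cap)
  ann$af_gnomad <- jitter_af(raw_af)
  ann$af_1kg <- jitter_af(raw_af)
  ann$af_gme <- jitter_af(raw_af)
  ann$af_gnomad[absent_db] <- NA_real_
  ann$af_1kg[absent_db] <- NA_real_
  ann$af_gme[absent_db] <- NA_real_

  ann$designation <- NULL
  list(variants = ann, panels = panels)
}

simulate_call_noise <- function(config, gt) {
  n <- nrow(gt); V <- ncol(gt)
  dp <- matrix(stats::rpois(n * V, config$dp_mean), nrow = n,
               dimnames = dimnames(gt))
  p_alt <- matrix(0.002, nrow = n, ncol = V)
  p_alt[gt == 1L] <- 0.5
  p_alt[gt == 2L] <- 0.98
  ad_alt <- matrix(stats::rbinom(n * V, as.vector(dp), as.vector(p_alt)),
                   nrow = n, dimnames = dimnames(gt))
  ad_ref <- dp - ad_alt
  gq <- matrix(pmin(99, pmax(0, round(stats::rnorm(n * V, config$gq_mean,
                                                   config$gq_sd)))),
               nrow = n, dimnames = dimnames(gt))
  if (config$gt_missing_rate > 0) {
    miss <- matrix(stats::runif(n * V) < config$gt_missing_rate, nrow = n)
    gt[miss] <- NA_integer_
  }
  list(gt = gt, ad_ref = ad_ref, ad_alt = ad_alt, gq = gq, dp = dp)
}
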