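test_that("genotype draws follow the inbreeding law", {
  # hom-alt fraction at F = 0.0625, q = 0.1 must sit at q^2 + Fq(1-q)
  set.seed(1)
  g <- simulate_genotypes(50000, 0.1, 0.0625)
  p_hom <- 0.1^2 + 0.0625 * 0.1 * 0.9
  expect_equal(p_hom, 0.015625)
  se <- sqrt(p_hom * (1 - p_hom) / 50000)
  expect_lt(abs(mean(g == 2L) - p_hom), 3 * se)
  # F = 0 passes a chi-square HWE check at q = 0.5
  set.seed(1)
  g0 <- simulate_genotypes(10000, 0.5, 0)
  obs <- tabulate(g0 + 1L, 3)
  expected <- 10000 * c(0.25, 0.5, 0.25)
  chi <- sum((obs - expected)^2 / expected)
  expect_gt(stats::pchisq(chi, df = 2, lower.tail = FALSE), 0.001)
  expect_error(simulate_genotypes(10, 0.1, -0.1), "inbreeding")
  expect_warning(simulate_genotypes(10, 1.2, 0), "clipped")
})

test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(seed = 5, n_subjects = 120, n_variants = 30,
                    n_genes = 10, n_traits = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$gt, b$cohort$gt)
  expect_identical(a$cohort$traits, b$cohort$traits)
  expect_identical(a$cohort$variants, b$cohort$variants)
  expect_identical(a$truth$subpop_afs, b$truth$subpop_afs)
})

test_that("realised subpopulation AFs converge to the truth", {
  cfg <- sim_config(seed = 9, n_subjects = 50000, n_variants = 12,
                    n_genes = 6, n_traits = 1,
                    subpops = tibble::tibble(label = c("GAR", "PAR"),
                                             prop = c(0.5, 0.5),
                                             f = c(0, 0.03)),
                    gt_missing_rate = 0)
  sim <- simulate_cohort(cfg)
  obs <- subpop_allele_counts(sim$cohort) |>
    dplyr::left_join(sim$truth$subpop_afs, by = c("variant_id", "subpopulation"))
  f_of <- setNames(cfg$subpops$f, cfg$subpops$label)
  for (i in seq_len(nrow(obs))) {
    q <- obs$q[i]; n <- obs$n_called[i]; f <- f_of[[obs$subpopulation[i]]]
    # allele-frequency variance under inbreeding: (1+F) q(1-q) / 2n
    se <- sqrt((1 + f) * q * (1 - q) / (2 * n))
    expect_lt(abs(obs$af[i] - q), 4 * se)
  }
})

test_that("founder spiking changes only the target subpopulation", {
  cfg <- sim_config(seed = 21, n_subjects = 4000, n_variants = 10,
                    n_genes = 5, n_traits = 1, gt_missing_rate = 0,
                    founder_spikes = tibble::tibble(variant = 1,
                                                    subpop = "PAR",
                                                    target_af = 0.017))
  sim <- simulate_cohort(cfg)
  vid <- sim$cohort$variants$variant_id[1]
  sub <- subpop_allele_counts(sim$cohort) |>
    dplyr::filter(variant_id == vid)
  par_row <- sub[sub$subpopulation == "PAR", ]
  se <- sqrt(0.017 * (1 - 0.017) / par_row$AN)
  expect_lt(abs(par_row$af - 0.017), 3.5 * se)
  expect_equal(sim$truth$founder_spikes$variant_id, vid)
  # locality: the non-spiked draw with the same seed matches elsewhere
  cfg0 <- cfg; cfg0$founder_spikes <- NULL
  sim0 <- simulate_cohort(cfg0)
  others <- sim$cohort$subjects$subject_id[
    sim$cohort$subjects$subpopulation != "PAR"]
  expect_identical(sim$cohort$gt[others, vid], sim0$cohort$gt[others, vid])
  expect_error(spike_founder_allele(list(), 1, "PAR", 1.2), "target_af")
})

test_that("traits carry covariate structure, spikes and missingness", {
  spike <- tibble::tibble(variant = 2, trait = "trait_01", effect = -4,
                          model = "recessive")
  cfg <- sim_config(seed = 13, n_subjects = 3000, n_variants = 12,
                    n_genes = 6, n_traits = 3, effect_spikes = spike,
                    novel_af_range = c(0.04, 0.06), gt_missing_rate = 0,
                    trait_missingness = 0.02)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  vid <- co$variants$variant_id[2]
  homs <- !is.na(co$gt[, vid]) & co$gt[, vid] == 2L
  t1 <- co$traits$trait_01
  if (sum(homs) >= 3) {
    expect_lt(mean(t1[homs], na.rm = TRUE) - mean(t1[!homs], na.rm = TRUE), -2)
  }
  # an unspiked trait shows no genotype correlation
  r <- cor(co$gt[, vid], co$traits$trait_02, use = "complete.obs")
  expect_lt(abs(r), 0.08)
  expect_gt(mean(is.na(t1)), 0.005)
  expect_lt(mean(is.na(t1)), 0.05)
  # unknown trait in a spike errors
  bad <- cfg
  bad$effect_spikes$trait <- "nope"
  expect_error(simulate_cohort(bad), "unknown trait")
})

test_that("annotation designations satisfy their construction contracts", {
  cfg <- sim_config(seed = 17, n_subjects = 2500, n_variants = 200,
                    n_genes = 40, n_traits = 2)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  des <- sim$truth$designations
  known_ids <- des$variant_id[des$designation == "known_plp"]
  sel <- select_known_plp(co)
  # every selected variant was designated, and every designated variant that
  # is not a reclassified benign-without-flag case is selected
  expect_true(all(sel$variant_id %in% known_ids))
  expect_equal(sort(sel$variant_id), sort(known_ids))
  # benign-common designated variants never enter the catalogue
  common_ids <- des$variant_id[des$designation == "benign_common"]
  expect_length(intersect(sel$variant_id, common_ids), 0)
  # novel candidates: selection equals designation intersected with the
  # homozygote requirement
  nov_ids <- des$variant_id[des$designation == "novel_candidate"]
  counts <- dplyr::filter(subpop_allele_counts(co), variant_id %in% nov_ids) |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(n_hom = sum(n_hom))
  expected_nov <- counts$variant_id[counts$n_hom >= 3]
  got <- select_novel_candidates(co)
  expect_setequal(got$variant_id, expected_nov)
  # panel table: one row per gene, at least one panel each
  expect_equal(anyDuplicated(co$panels$gene), 0L)
  expect_true(all(nchar(co$panels$panels) > 0))
  expect_true(all(co$panels$coding_length_bp > 0))
})
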