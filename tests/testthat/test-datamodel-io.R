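write_fixture_vcf <- function(path, records, samples = c("S1", "S2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

write_fixture_subjects <- function(path, ids, subpop = "GAR") {
  readr::write_tsv(tibble::tibble(
    subject_id = ids, subpopulation = subpop, sex = "Male", age = 40,
    PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0
  ), path)
  path
}

test_that("a biallelic VCF round-trips into a genotype matrix", {
  d <- withr::local_tempdir()
  vcf <- write_fixture_vcf(file.path(d, "c.vcf"), c(
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD:GQ:DP\t0/1:10,8:99:18\t0/0:20,0:99:20",
    "1\t200\t.\tG\tC\t.\tPASS\t.\tGT:AD:GQ:DP\t1/1:0,30:99:30\t./.:.:.:.",
    "2\t300\t.\tT\tA\t.\tPASS\t.\tGT:AD:GQ:DP\t0/0:15,0:99:15\t0/1:7,9:80:16"
  ))
  subj <- write_fixture_subjects(file.path(d, "s.tsv"), c("S1", "S2"))
  co <- load_cohort(vcf, NULL, subj)
  expect_equal(dim(co), c(2L, 3L))
  expect_equal(unname(co$gt["S1", ]), c(1L, 2L, 0L))
  expect_equal(unname(co$gt["S2", ]), c(0L, NA_integer_, 1L))
  expect_equal(unname(co$ad_alt["S1", "1:100:A:T"]), 8)
  expect_equal(unname(co$dp["S2", "2:300:T:A"]), 16)
})

test_that("multi-allelic records decompose with per-alt genotype recoding", {
  d <- withr::local_tempdir()
  vcf <- write_fixture_vcf(file.path(d, "c.vcf"), c(
    "1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT:AD:GQ:DP\t1/2:2,8,9:90:19\t0/2:10,0,7:85:17"
  ))
  subj <- write_fixture_subjects(file.path(d, "s.tsv"), c("S1", "S2"))
  co <- load_cohort(vcf, NULL, subj)
  expect_equal(co$variants$variant_id, c("1:100:A:T", "1:100:A:G"))
  # S1 is 1/2: one T allele, one G allele -> het for each decomposed entry
  expect_equal(unname(co$gt["S1", ]), c(1L, 1L))
  # S2 is 0/2: hom-ref against T, het against G
  expect_equal(unname(co$gt["S2", ]), c(0L, 1L))
  # AD picks the matching alt column
  expect_equal(unname(co$ad_alt["S1", "1:100:A:G"]), 9)
  expect_equal(unname(co$ad_alt["S1", "1:100:A:T"]), 8)
})

test_that("loader enforces consistency contracts", {
  d <- withr::local_tempdir()
  vcf <- write_fixture_vcf(file.path(d, "c.vcf"), c(
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD:GQ:DP\t0/1:10,8:99:18\t0/0:20,0:99:20"
  ))
  subj3 <- write_fixture_subjects(file.path(d, "s3.tsv"), c("S1", "S2", "S9"))
  expect_error(load_cohort(vcf, NULL, subj3), "S9")
  expect_error(load_cohort(file.path(d, "nope.vcf"), NULL, subj3),
               "not found")
  # duplicate annotation keys are fatal
  subj <- write_fixture_subjects(file.path(d, "s.tsv"), c("S1", "S2"))
  ann <- tibble::tibble(
    chrom = c("1", "1"), pos = c(100L, 100L), ref = "A", alt = "T",
    gene = "G1", consequence = "missense", clinvar_class = "pathogenic",
    clinvar_stars = 2L, clinvar_prior_plp = TRUE, hgmd_class = "DM",
    cadd = 25, gerp = 4, af_gnomad = 0.001
  )
  readr::write_tsv(ann, file.path(d, "ann.tsv"))
  expect_error(load_cohort(vcf, file.path(d, "ann.tsv"), subj),
               "duplicate")
  # unannotated variants keep absent database fields
  readr::write_tsv(ann[0, ], file.path(d, "ann0.tsv"))
  co <- load_cohort(vcf, file.path(d, "ann0.tsv"), subj)
  expect_equal(co$variants$clinvar_class, "absent")
})

test_that("allele_counts matches hand counts and a brute-force oracle", {
  gt <- matrix(c(0L, 1L, 2L, NA), nrow = 4, ncol = 1)
  co <- make_cohort(gt)
  ac <- allele_counts(co, co$variants$variant_id[1])
  expect_equal(ac$AC, 3L); expect_equal(ac$AN, 6L)
  expect_equal(ac$n_hom, 1L); expect_equal(ac$n_het, 1L)
  expect_equal(ac$n_called, 3L)

  co0 <- make_cohort(matrix(0L, nrow = 5, ncol = 1))
  ac0 <- allele_counts(co0, co0$variants$variant_id[1])
  expect_equal(ac0$AC, 0L); expect_equal(ac0$AN, 10L)

  set.seed(7)
  g <- sample(c(0L, 1L, 2L, NA), 200, replace = TRUE,
              prob = c(0.6, 0.25, 0.1, 0.05))
  co2 <- make_cohort(matrix(g, ncol = 1))
  ac2 <- allele_counts(co2, co2$variants$variant_id[1])
  orc <- oracle_counts(g)
  expect_equal(ac2$AC, orc$AC); expect_equal(ac2$AN, orc$AN)
  expect_equal(ac2$n_hom, orc$n_hom); expect_equal(ac2$n_het, orc$n_het)
  # invariants and order invariance
  expect_lte(ac2$AC, ac2$AN)
  expect_lte(ac2$n_hom + ac2$n_het, ac2$n_called)
  shuf <- sample(rownames(co2$gt))
  ac3 <- allele_counts(co2, co2$variants$variant_id[1], subject_subset = shuf)
  expect_equal(ac3[-1], ac2[-1])
  expect_error(allele_counts(co2, co2$variants$variant_id[1],
                             subject_subset = character()), "empty")
  expect_error(allele_counts(co2, "1:9:A:C"), "not in cohort")
})

test_that("write_report writes TSV/JSON and round-trips values", {
  d <- withr::local_tempdir()
  tab <- tibble::tibble(gene = c("G1"), gcf = 0.0251234567)
  p <- file.path(d, "out.tsv")
  write_report(tab, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(back$gcf, round(tab$gcf, 6))
  expect_warning(write_report(tab[0, ], file.path(d, "empty.tsv")), "empty")
  expect_equal(nrow(readr::read_tsv(file.path(d, "empty.tsv"),
                                    show_col_types = FALSE)), 0)
})

test_that("load -> write -> load is idempotent on a simulated cohort", {
  sim <- simulate_cohort(sim_config(seed = 11, n_subjects = 60,
                                    n_variants = 15, n_genes = 8,
                                    n_traits = 2))
  co <- sim$cohort
  d <- withr::local_tempdir()
  write_cohort_vcf(co, file.path(d, "c.vcf"))
  readr::write_tsv(dplyr::bind_cols(co$subjects,
                                    dplyr::select(co$traits, -subject_id)),
                   file.path(d, "subjects.tsv"))
  readr::write_tsv(dplyr::select(co$variants, -variant_id),
                   file.path(d, "ann.tsv"))
  readr::write_tsv(co$panels, file.path(d, "panels.tsv"))
  co2 <- load_cohort(file.path(d, "c.vcf.gz"), file.path(d, "ann.tsv"),
                     file.path(d, "subjects.tsv"), file.path(d, "panels.tsv"))
  expect_identical(co$gt, co2$gt)
  expect_equal(co$variants$clinvar_class, co2$variants$clinvar_class)
  expect_equal(co$subjects$subpopulation, co2$subjects$subpopulation)
  d2 <- withr::local_tempdir()
  write_cohort_vcf(co2, file.path(d2, "c.vcf"))
  co3 <- load_cohort(file.path(d2, "c.vcf.gz"), file.path(d, "ann.tsv"),
                     file.path(d, "subjects.tsv"), file.path(d, "panels.tsv"))
  expect_identical(co2$gt, co3$gt)
})
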