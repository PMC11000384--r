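#' Default pipeline configuration
#'
#' One nested list drives the whole analysis; every threshold used by any
#' stage is surfaced here with its default. The configuration round-trips
#' through YAML ([yaml::write_yaml()] / [read_run_config()]).
#'
#' @param seed Integer seed (used by the simulation stage).
#' @param out_dir Output directory.
#' @param sim A [sim_config()] list, or `NULL` to load files instead.
#' @param input Named list of paths (`vcf`, `annotations`, `subjects`,
#'   `panels`) when not simulating.
#' @param categories Catalogue categories used by the summaries.
#' @param af_threshold Global-AF cutoff for the P/LP catalogue.
#' @param min_hom Homozygote floor for novel candidates.
#' @param gcf_min_n Low-confidence subpopulation size for GCF.
#' @param founder_subpop_af_min,common_af_min,reclassify_af,depletion_min_expected
#'   Screen thresholds.
#' @param extreme_rule `"all"` or `"majority"` for the extreme-trait screen.
#' @param qc A [qc_thresholds()] list for the burden scan.
#' @param scan_p_threshold Burden-scan significance threshold.
#' @param ref_subpop Reference subpopulation for fold enrichments.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("mendelburden_run_"),
                       sim = sim_config(seed = seed), input = NULL,
                       categories = c(1, 2), af_threshold = 0.01,
                       min_hom = 3, gcf_min_n = 100,
                       founder_subpop_af_min = 0.01, common_af_min = 0.02,
                       reclassify_af = 0.05, depletion_min_expected = 3,
                       extreme_rule = "all", qc = qc_thresholds(),
                       scan_p_threshold = 1e-8, ref_subpop = "ADM") {
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  unknown <- setdiff(names(raw), c(names(cfg), "sim", "qc"))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  for (k in setdiff(names(raw), c("sim", "qc"))) cfg[[k]] <- raw[[k]]
  if (!is.null(raw$sim)) {
    cfg$sim <- do.call(sim_config, c(raw$sim, list(seed = cfg$seed)))
  }
  if (!is.null(raw$qc)) cfg$qc <- do.call(qc_thresholds, raw$qc)
  cfg
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
}

#' Run the full burden-analysis pipeline
#'
#' Stages, in dependency order: simulate (or load) the cohort; build the
#' P/LP catalogue and gene-level counts; summarise carrier burden per
#' subpopulation; compute cumulative gene carrier frequencies; run the
#' founder / common-P/LP / depleted-homozygosity / knockout screens and the
#' allele-frequency correlation; run the extreme-trait homozygote screen on
#' novel candidates; run the genome-wide burden scan. Every stage writes its
#' TSV (or JSON) outputs under `config$out_dir`, and a machine-readable run
#' manifest (seed, thresholds, output checksums, stage timings) is written as
#' `manifest.json`. A stage failure aborts with a partial manifest on disk.
#'
#' @param config A [run_config()] list.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mendelburden")),
                   seed = config$seed,
                   thresholds = config[setdiff(names(config), c("sim", "out_dir"))],
                   stages = list(), outputs = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    flush_manifest()
    res
  }
  out_path <- function(f) file.path(config$out_dir, f)
  emit <- function(tab, file) {
    write_report(tab, out_path(file))
    manifest$outputs[[file]] <<- unname(tools::md5sum(out_path(file)))
  }

  cohortenv <- stage("cohort", function() {
    if (!is.null(config$sim)) {
      pipeline_log("simulating cohort (seed %d)", config$seed)
      sim <- simulate_cohort(config$sim)
      write_cohort_vcf(sim$cohort, out_path("cohort.vcf"))
      jsonlite::write_json(
        purrr::map(sim$truth, ~ if (is.data.frame(.x)) .x else .x),
        out_path("truth.json"), digits = NA, na = "null", force = TRUE)
      sim$cohort
    } else {
      if (is.null(config$input)) abort("neither sim nor input paths given")
      load_cohort(config$input$vcf, config$input$annotations,
                  config$input$subjects, config$input$panels)
    }
  })
  cohort <- cohortenv

  classified <- stage("catalog", function() {
    cl <- select_known_plp(cohort, af_threshold = config$af_threshold)
    if (nrow(cl) == 0) warn("empty P/LP catalogue at this AF threshold")
    pipeline_log("catalog: %d known P/LP variants in %d genes",
                 nrow(cl), dplyr::n_distinct(cl$gene))
    emit(select(cl, -dplyr::any_of("hom_values")), "classified_variants.tsv")
    emit(gene_plp_counts(cl, cohort$panels), "gene_plp_counts.tsv")
    cl
  })

  stage("burden_summary", function() {
    burdens <- subject_burdens(cohort, classified,
                               categories = config$categories)
    emit(burdens, "subject_burden.tsv")
    if (config$ref_subpop %in% burdens$subpopulation &&
        sum(burdens$subpopulation == config$ref_subpop &
              burdens$n_hom_recessive > 0) > 0) {
      emit(subpop_summary(burdens, ref_label = config$ref_subpop),
           "subpop_summary.tsv")
    } else {
      warn("fold enrichments skipped: reference group missing or without homozygotes")
    }
    invisible(NULL)
  })

  stage("gcf", function() {
    g <- gene_gcf(cohort, classified, categories = config$categories,
                  min_n = config$gcf_min_n)
    emit(select(g, -"contributing"), "gcf_by_subpop.tsv")
  })

  stage("screens", function() {
    emit(find_founder_alleles(cohort, classified,
                              subpop_af_min = config$founder_subpop_af_min),
         "founder.tsv")
    emit(find_common_plp(cohort, classified, af_min = config$common_af_min,
                         reclassify_af = config$reclassify_af),
         "common_plp.tsv")
    emit(depleted_homozygosity(cohort,
                               min_expected = config$depletion_min_expected),
         "depleted.tsv")
    ko <- knockout_catalog(cohort)
    emit(ko$by_subpop, "knockouts_by_subpop.tsv")
    emit(select(ko$homozygous_lof, -"carriers"), "knockouts.tsv")
    corr <- tryCatch(af_correlation(cohort, classified),
                     error = function(e) tibble(r2 = NA_real_,
                                                n_variants = 0L))
    write_report(corr, out_path("af_correlation.json"), format = "json")
    manifest$outputs[["af_correlation.json"]] <<-
      unname(tools::md5sum(out_path("af_correlation.json")))
  })

  stage("extreme_traits", function() {
    if (is.null(cohort$traits)) abort("no trait table attached")
    cand <- select_novel_candidates(cohort, min_hom = config$min_hom,
                                    af_threshold = config$af_threshold)
    hits <- extreme_homozygote_screen(cohort, cand, rule = config$extreme_rule)
    emit(select(hits, -"hom_values"), "extreme_hits.tsv")
  })

  scan <- stage("burden_scan", function() {
    if (is.null(cohort$traits)) abort("no trait table attached")
    genome_wide_scan(cohort, thresholds = config$qc,
                     p_threshold = config$scan_p_threshold)
  })
  emit(tidy(scan), "scan_results.tsv")
  if (!is.null(scan$qc_report)) emit(scan$qc_report, "qc_report.tsv")
  flush_manifest()
  pipeline_log("pipeline complete: %s", config$out_dir)
  invisible(manifest)
}
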