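# End-to-end orchestration: validated run configuration, staged pipeline
# execution with a reproducibility manifest, and fixture bundles.

run_config_defaults <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_genes = 30L,
    stages = c("simulate", "erg", "histology", "stress", "climb",
               "integrate", "riskscore"),
    sim = list(),
    erg = list(p_adjust = "holm"),
    histology = list(threshold = 15, rule = "all_heads"),
    stress = list(cutoff = 0.60, alpha = 0.05, min_replicates = 3),
    climb = list(basis = "quadratic", alpha = 0.05, gate = "any"),
    integrate = list(erg_scope = "decreased_only", dedup = TRUE),
    riskscore = list(component = 2, n_individuals = 100L, base_freq = 0.3,
                     missing = "impute_mean", mode = "dosage"),
    strict = FALSE)
}

#' Build and validate a pipeline run configuration
#'
#' Merges user settings into the defaults and rejects unknown keys, at the
#' top level and within each stage block.
#'
#' @param ... Named overrides of the default configuration (see
#'   `run_config_defaults`): `seed`, `n_genes`, `stages`, per-stage
#'   parameter lists (`sim`, `erg`, `histology`, `stress`, `climb`,
#'   `integrate`, `riskscore`), `strict`.
#' @param config Optional list (e.g. parsed from YAML) merged the same way.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(..., config = NULL) {
  user <- c(list(...), config)
  base <- run_config_defaults()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (blk in intersect(names(user), c("erg", "histology", "stress", "climb",
                                       "integrate", "riskscore", "sim"))) {
    allowed <- if (blk == "sim") names(formals(sim_config)) else
      names(base[[blk]])
    bad <- setdiff(names(user[[blk]]), allowed)
    if (length(bad)) {
      abort(sprintf("unknown key(s) in `%s` block: %s", blk,
                    paste(bad, collapse = ", ")))
    }
    base[[blk]] <- modifyList(base[[blk]], user[[blk]])
    user[[blk]] <- NULL
  }
  cfg <- modifyList(base, user)
  bad_stage <- setdiff(cfg$stages, run_config_defaults()$stages)
  if (length(bad_stage)) {
    abort(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return Validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  run_config(config = yaml::read_yaml(path))
}

#' Run the full screen-analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order - simulate, ERG analysis,
#' histology hit calling, stress-resilience pipeline, locomotor modifier
#' analysis, gene-level integration, oligogenic risk scoring - writing each
#' stage's tables under `out_dir` and returning a manifest that records the
#' seed, parameters and md5 hash of every output, sufficient to reproduce
#' the run. A stage failure aborts with the stage named.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("flyrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, code) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim_args <- modifyList(list(seed = config$seed, n_genes = config$n_genes),
                         config$sim)
  ds <- stage("simulate", {
    d <- simulate_screen(do.call(sim_config, sim_args))
    write_screen_dataset(d, file.path(out_dir, "simulated"))
    d
  })
  if (is.null(ds)) abort("the 'simulate' stage is required.")
  res$dataset <- ds
  genes <- ds$genes

  res$erg <- stage("erg", {
    feats <- erg_feature_table(ds$erg_traces,
                               ds$config$stimulus_onset_s,
                               ds$config$stimulus_offset_s)
    ctrl_map <- c(white = "erg_ctrl_w1", orange_red = "erg_ctrl_o1")
    extra_ctrl <- setdiff(ds$erg_meta$genotype[ds$erg_meta$is_control],
                          unname(ctrl_map))
    cmp <- compare_erg_genotypes(feats |>
                                   filter(!.data$genotype %in% extra_ctrl),
                                 ctrl_map,
                                 p_adjust = config$erg$p_adjust)
    cmp <- cmp |>
      left_join(ds$erg_meta |> select("genotype", "gene"), by = "genotype") |>
      filter(!is.na(.data$gene))
    calls <- classify_erg_gene(cmp, genes)
    readr::write_tsv(cmp |> select(-dplyr::any_of("omnibus_p")),
                     file.path(out_dir, "erg_comparisons.tsv"))
    readr::write_tsv(calls |> select("gene", "erg_class"),
                     file.path(out_dir, "erg_calls.tsv"))
    list(comparisons = cmp, calls = calls)
  })

  res$histology <- stage("histology", {
    calls <- call_structure(ds$vacuoles, genes,
                            threshold = config$histology$threshold,
                            rule = config$histology$rule)
    readr::write_tsv(calls |> select("gene", "structure_hit"),
                     file.path(out_dir, "structure_calls.tsv"))
    calls
  })

  res$stress <- stage("stress", {
    ctrl <- grep("^stress_ctrl", unique(ds$stress_trials$genotype),
                 value = TRUE)
    calls <- stress_pipeline(ds$stress_trials, genes, ctrl,
                             cutoff = config$stress$cutoff,
                             alpha = config$stress$alpha,
                             min_replicates = config$stress$min_replicates)
    readr::write_tsv(calls, file.path(out_dir, "stress_calls.tsv"))
    calls
  })

  res$climb <- stage("climb", {
    per_model <- purrr::map(c(abeta = "abeta", tau = "tau"), function(model) {
      cl <- ds$climbing |> filter(.data$disease_model == model)
      ctrl_name <- paste0("ctrl_", model)
      ctrl_rows <- cl |> filter(.data$genotype == ctrl_name)
      strains <- cl |> filter(.data$genotype != ctrl_name) |>
        distinct(.data$gene, .data$genotype)
      strain_res <- purrr::pmap(strains, function(gene, genotype) {
        st <- genotype
        d <- bind_rows(ctrl_rows, cl |> filter(.data$genotype == .env$st)) |>
          select("genotype", "vial_id", "age_days", "mean_speed")
        analyze_strain(d, control = ctrl_name, basis = config$climb$basis,
                       alpha = config$climb$alpha,
                       gate = config$climb$gate) |>
          mutate(gene = gene, model = model, .before = 1)
      }) |> purrr::list_rbind()
      gene_calls <- consolidate_gene(strain_res |>
                                       select("gene", strain = "strain",
                                              call = "call")) |>
        mutate(model = model, .before = 1)
      list(strains = strain_res, genes = gene_calls)
    })
    strains <- purrr::list_rbind(purrr::map(per_model, "strains"))
    gene_calls <- purrr::list_rbind(purrr::map(per_model, "genes"))
    readr::write_tsv(strains, file.path(out_dir, "modifier_strains.tsv"))
    jsonlite::write_json(gene_calls, file.path(out_dir, "modifier_genes.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    list(strains = strains, genes = gene_calls)
  })

  res$integrate <- stage("integrate", {
    profiles <- build_profiles(
      genes,
      res$histology,
      res$erg$calls,
      res$stress |> select("stressor", "gene", "confirmed"),
      res$climb$genes |> select("model", "gene", "high_confidence"),
      genes |> select("gene", "expression_category"))
    summary <- count_summary(profiles)
    clusters <- assign_snp_clusters(profiles, genes,
                                    erg_scope = config$integrate$erg_scope,
                                    dedup = config$integrate$dedup)
    readr::write_tsv(profiles, file.path(out_dir, "profiles.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "summary_counts.tsv"))
    jsonlite::write_json(clusters, file.path(out_dir, "cluster_snps.json"))
    list(profiles = profiles, summary = summary, clusters = clusters)
  })

  res$riskscore <- stage("riskscore", {
    clusters <- res$integrate$clusters[lengths(res$integrate$clusters) > 0]
    if (length(clusters) < 2) {
      warn("fewer than 2 non-empty phenotype clusters; risk scoring skipped.")
      return(NULL)
    }
    universe <- unique(unlist(clusters))
    cohort <- simulate_cohort(
      n_individuals = config$riskscore$n_individuals,
      cluster_snps = list(all = universe),
      base_freq = config$riskscore$base_freq,
      seed = config$seed)
    scores <- oligogenic_scores(cohort$genotypes, clusters,
                                component = min(config$riskscore$component,
                                                length(clusters)),
                                missing = config$riskscore$missing,
                                mode = config$riskscore$mode)
    write_cohort_vcf(cohort, file.path(out_dir, "cohort.vcf"))
    readr::write_tsv(scores$heatmap, file.path(out_dir, "risk_heatmap.tsv"))
    jsonlite::write_json(
      list(loadings = as.data.frame(scores$pca$loadings),
           variance_explained = scores$pca$variance_explained),
      file.path(out_dir, "pca_report.json"), digits = NA)
    scores
  })

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    parameters = unclass(config),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               sub(paste0(out_dir, "/?"), "", outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Write the fixture bundle
#'
#' Writes (1) the synthetic 100-gene screen-summary fixture, (2) a
#' worked-examples JSON holding the module threshold examples (vacuole
#' calls at the 15-vacuole rule, the 60% impairment cutoff, Holm
#' step-down arithmetic, area-between-curves rectangle/triangle cases), and
#' (3) a small demo synthetic screen plus cohort VCF.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the demo data.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- screen_summary_fixture()
  readr::write_tsv(fx, file.path(out_dir, "synthetic_screen_summary.tsv"))

  worked <- list(
    vacuole_rule = list(threshold = 15,
                        hit = list(counts = c(16, 18), call = TRUE),
                        control_range = list(counts = c(10, 9), call = FALSE),
                        inconsistent = list(counts = c(14, 16), call = FALSE)),
    stress_cutoff = list(cutoff = 0.6,
                         fractions = c(0, 0.6, 1),
                         candidate = c(FALSE, TRUE, TRUE)),
    holm = list(input = c(0.01, 0.04, 0.03),
                adjusted = holm_adjust(c(0.01, 0.04, 0.03))),
    area_between_curves = list(
      rectangle = area_between_curves(c(5, 18), c(8, 1.5), c(10, 3.5)),
      triangle = area_between_curves(c(5, 18), c(10, 1.5), c(10, 3.5))))
  jsonlite::write_json(worked, file.path(out_dir, "worked_examples.json"),
                       auto_unbox = TRUE, digits = NA)

  demo <- simulate_screen(sim_config(seed = seed, n_genes = 8L,
                                     n_flies_erg = 3L, n_traces_per_fly = 3L,
                                     sampling_rate_hz = 200))
  write_screen_dataset(demo, file.path(out_dir, "demo_screen"))
  cohort <- simulate_cohort(n_individuals = 40L, n_snps_per_cluster = 5L,
                            seed = seed)
  write_cohort_vcf(cohort, file.path(out_dir, "demo_cohort.vcf"))
  readr::write_tsv(cohort$snp_info, file.path(out_dir, "demo_cohort_snps.tsv"))
  invisible(list.files(out_dir, recursive = TRUE, full.names = TRUE))
}

#' Validate a fixture bundle against the expected layout
#'
#' Checks that every expected file exists and that the tables carry their
#' required columns.
#'
#' @param dir Bundle directory written by [make_fixtures()].
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_fixture_bundle <- function(dir) {
  need <- c("synthetic_screen_summary.tsv", "worked_examples.json",
            "demo_cohort.vcf", "demo_cohort_snps.tsv",
            file.path("demo_screen", c("vacuoles.tsv", "erg_traces.tsv",
                                       "stress_trials.tsv", "climbing.tsv",
                                       "genes.tsv", "truth.json")))
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    abort(sprintf("fixture bundle missing: %s", paste(missing, collapse = ", ")))
  }
  fx <- readr::read_tsv(file.path(dir, "synthetic_screen_summary.tsv"),
                        show_col_types = FALSE)
  assert_cols(fx, c("gene", "lead_snp", "risk_allele", "viability",
                    "structure", "erg_class", "function", "resilience_heat",
                    "resilience_bang", "abeta_modifier", "tau_modifier",
                    "expression_category"), "fixture")
  invisible(TRUE)
}
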