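# Brain-structure hit calling from vacuole counts and stress-resilience hit
# calling with the two-stage screen-then-replicate design.

#' Call structural degeneration from vacuole counts
#'
#' A genotype is annotated as structurally degenerating when it consistently
#' shows at least `threshold` vacuoles per brain; "consistently" is read
#' strictly as every examined head reaching the threshold (wildtype heads
#' can carry up to 10 vacuoles, so the default threshold of 15 sits above
#' the control range). A `"mean"` rule (mean count across heads >=
#' threshold) is available. At gene level, essential genes assayed with two
#' RNAi genotypes require both genotypes to satisfy the criterion.
#'
#' @param vacuoles Tibble with columns `gene`, `genotype`, `head_id`,
#'   `vacuole_count` (control rows may carry `gene = NA`).
#' @param genes Tibble with `gene`, `viability`.
#' @param threshold Vacuole threshold per head (default 15).
#' @param rule `"all_heads"` (default) or `"mean"`.
#' @return Tibble with one row per gene: `structure_hit`, plus per-genotype
#'   evidence nested in `evidence`.
#' @export
call_structure <- function(vacuoles, genes, threshold = 15,
                           rule = c("all_heads", "mean")) {
  rule <- match.arg(rule)
  assert_cols(vacuoles, c("gene", "genotype", "head_id", "vacuole_count"),
              "vacuoles")
  if (any(vacuoles$vacuole_count < 0)) abort("vacuole counts must be >= 0.")
  per_geno <- vacuoles |>
    filter(!is.na(.data$gene)) |>
    summarise(n_heads = dplyr::n(),
              min_count = min(.data$vacuole_count),
              mean_count = mean(.data$vacuole_count),
              .by = c("gene", "genotype"))
  if (any(per_geno$n_heads < 2)) {
    abort(sprintf("genotype(s) with < 2 heads: %s",
                  paste(per_geno$genotype[per_geno$n_heads < 2],
                        collapse = ", ")))
  }
  per_geno <- per_geno |>
    mutate(genotype_hit = if (rule == "all_heads") {
      .data$min_count >= threshold
    } else {
      .data$mean_count >= threshold
    })
  gene_call(per_geno, genes, "genotype_hit", "structure_hit")
}

# Essential (two-RNAi) genes require every genotype positive; others any.
gene_call <- function(per_geno, genes, flag_col, out_col) {
  assert_cols(genes, c("gene", "viability"), "genes")
  unknown <- setdiff(per_geno$gene, genes$gene)
  if (length(unknown)) {
    abort(sprintf("measurement(s) for undeclared gene(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  calls <- per_geno |>
    left_join(genes[, c("gene", "viability")], by = "gene") |>
    summarise(
      hit = if (dplyr::first(.data$viability) == "essential_rescuable") {
        all(.data[[flag_col]])
      } else {
        any(.data[[flag_col]])
      },
      .by = "gene")
  ev <- tidyr::nest(per_geno, evidence = -"gene")
  calls |>
    rename(!!out_col := "hit") |>
    left_join(ev, by = "gene")
}

#' Impairment fraction of a stress trial
#'
#' @param n_impaired,n_flies Counts of impaired flies (supine and/or
#'   seizure-like after the 10-second recovery) and flies tested.
#' @return `n_impaired / n_flies`.
#' @export
impairment_fraction <- function(n_impaired, n_flies) {
  if (any(n_flies <= 0)) abort("`n_flies` must be positive.")
  if (any(n_impaired < 0 | n_impaired > n_flies)) {
    abort("`n_impaired` must lie in [0, n_flies].")
  }
  n_impaired / n_flies
}

#' Primary stress screen: candidate genes at the 60% impairment cutoff
#'
#' A genotype is a candidate for a stressor when its primary-trial
#' impairment fraction reaches the cutoff (default 0.60, more than double
#' the control averages of 26% heat / 19% bang impairment). Essential genes
#' require both RNAi genotypes to reach the cutoff.
#'
#' @param trials Tibble with `gene`, `genotype`, `stressor`, `stage`,
#'   `n_flies`, `n_impaired`; only `stage == "primary"` rows are used (one
#'   per genotype per stressor).
#' @param genes Tibble with `gene`, `viability`.
#' @param cutoff Impairment fraction cutoff.
#' @return Tibble with one row per gene x stressor: `candidate` plus nested
#'   `evidence`.
#' @export
primary_stress_screen <- function(trials, genes, cutoff = 0.60) {
  assert_cols(trials, c("gene", "genotype", "stressor", "stage", "n_flies",
                        "n_impaired"), "trials")
  prim <- trials |>
    filter(.data$stage == "primary", !is.na(.data$gene))
  dup <- prim |> count(.data$gene, .data$genotype, .data$stressor) |>
    filter(.data$n > 1)
  if (nrow(dup)) abort("multiple primary trials for one genotype/stressor.")
  declared <- prim |> distinct(.data$gene, .data$genotype)
  per_geno <- prim |>
    mutate(fraction = impairment_fraction(.data$n_impaired, .data$n_flies),
           pass = .data$fraction >= cutoff)
  missing <- anti_join(
    tidyr::expand_grid(declared, stressor = unique(prim$stressor)),
    per_geno[, c("gene", "genotype", "stressor")],
    by = c("gene", "genotype", "stressor"))
  if (nrow(missing)) {
    abort(sprintf("missing primary trial for: %s",
                  paste(missing$genotype, missing$stressor, collapse = "; ")))
  }
  purrr::map(unique(per_geno$stressor), function(st) {
    gene_call(per_geno |> filter(.data$stressor == st) |>
                select("gene", "genotype", "fraction", "pass"),
              genes, "pass", "candidate") |>
      mutate(stressor = st, .before = 1)
  }) |> purrr::list_rbind()
}

#' Confirm stress candidates against controls on replicate trials
#'
#' Replicate-stage impairment fractions of each candidate genotype are
#' compared with control replicate fractions by Kruskal-Wallis plus Dunn's
#' test (adjusted p < `alpha` confirms). Candidates with fewer than
#' `min_replicates` replicates are reported as unconfirmable rather than
#' silently dropped. Essential genes require both RNAi genotypes confirmed.
#'
#' @param trials Replicate-stage trials (`stage == "replicate"`), including
#'   control genotype rows (`gene = NA`).
#' @param candidates Output of [primary_stress_screen()] (or a tibble with
#'   `gene`, `stressor`, `candidate`).
#' @param genes Tibble with `gene`, `viability`.
#' @param control_genotypes Character vector of control genotype names.
#' @param alpha Significance cutoff on the Dunn-adjusted p-value.
#' @param min_replicates Minimum replicates per genotype for inference.
#' @param p_adjust Passed to [dunn_vs_control()].
#' @return Tibble with one row per candidate gene x stressor: `confirmed`,
#'   `unconfirmable`, and per-genotype `p_adjusted` evidence.
#' @export
confirm_stress_hits <- function(trials, candidates, genes, control_genotypes,
                                alpha = 0.05, min_replicates = 3,
                                p_adjust = "holm") {
  assert_cols(trials, c("gene", "genotype", "stressor", "stage", "n_flies",
                        "n_impaired"), "trials")
  reps <- trials |>
    filter(.data$stage == "replicate") |>
    mutate(fraction = impairment_fraction(.data$n_impaired, .data$n_flies))
  cand <- candidates |> filter(.data$candidate)
  if (!nrow(cand)) {
    return(tibble(stressor = character(), gene = character(),
                  confirmed = logical(), unconfirmable = logical(),
                  evidence = list()))
  }
  purrr::map(unique(cand$stressor), function(st) {
    cand_genes <- cand$gene[cand$stressor == st]
    batch <- reps |>
      filter(.data$stressor == st,
             .data$gene %in% cand_genes |
               .data$genotype %in% control_genotypes)
    ctrl_rows <- batch$genotype %in% control_genotypes
    if (sum(ctrl_rows) < min_replicates) {
      abort(sprintf("fewer than %d control replicates for %s.",
                    min_replicates, st))
    }
    batch$group <- ifelse(ctrl_rows, "control", batch$genotype)
    counts <- batch |> count(.data$group)
    testable <- counts$group[counts$n >= min_replicates]
    test_batch <- batch |> filter(.data$group %in% testable)
    res <- if (length(unique(test_batch$group)) >= 2) {
      dunn_vs_control(test_batch, "fraction", "group", control = "control",
                      p_adjust = p_adjust)$comparisons
    } else {
      tibble(group = character(), p_adjusted = numeric(),
             direction = numeric())
    }
    per_geno <- batch |>
      filter(.data$group != "control") |>
      distinct(.data$gene, .data$genotype) |>
      left_join(res |> select(genotype = "group", "p_adjusted", "direction"),
                by = "genotype") |>
      mutate(tested = !is.na(.data$p_adjusted),
             pass = .data$tested & .data$p_adjusted < alpha &
               .data$direction > 0)
    out <- gene_call(per_geno, genes, "pass", "confirmed") |>
      mutate(stressor = st, .before = 1)
    unconf <- per_geno |>
      summarise(unconfirmable = any(!.data$tested), .by = "gene")
    out |> left_join(unconf, by = "gene")
  }) |> purrr::list_rbind()
}

#' Run the full two-stage stress-resilience pipeline
#'
#' Convenience wrapper: primary screen at the cutoff, then replicate-stage
#' confirmation against controls.
#'
#' @inheritParams primary_stress_screen
#' @inheritParams confirm_stress_hits
#' @return Tibble with one row per gene x stressor: `candidate`, `confirmed`.
#' @export
stress_pipeline <- function(trials, genes, control_genotypes, cutoff = 0.60,
                            alpha = 0.05, min_replicates = 3) {
  cands <- primary_stress_screen(trials, genes, cutoff)
  conf <- confirm_stress_hits(trials, cands, genes, control_genotypes,
                              alpha, min_replicates)
  cands |>
    select("stressor", "gene", "candidate") |>
    left_join(conf |> select("stressor", "gene", "confirmed",
                             "unconfirmable"),
              by = c("stressor", "gene")) |>
    mutate(confirmed = !is.na(.data$confirmed) & .data$confirmed,
           unconfirmable = !is.na(.data$unconfirmable) & .data$unconfirmable)
}
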