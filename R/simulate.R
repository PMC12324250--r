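#' Simulation configuration for a synthetic loss-of-function screen
#'
#' Bundles every tunable parameter of the synthetic-data generator. Defaults
#' encode the study conditions of the screen the package models: control
#' impairment probabilities of 26% (heat) and 19% (bang), climbing assessed
#' from day 5 to day 18 post-eclosion (6 timepoints for the tau model, 9 for
#' the amyloid-beta model, 4 vials of 10 females), at least 2 heads scored
#' per genotype for histology, and 5 flies x 5 averaged traces per genotype
#' for electroretinograms. Where the study reports no value (control vacuole
#' distribution, ERG noise), defaults are documented stand-ins: Poisson mean
#' 5 for normal heads vs 25 for degenerating heads, and Gaussian trace noise
#' of 0.5 mV.
#'
#' Phenotype prevalences default to the observed screen rates (18% structural
#' degeneration, 35% ERG phenotypes, 7% heat / 3% bang sensitive, tau and
#' amyloid-beta modifier rates summing to 22% and 9%).
#'
#' @param seed Integer root seed. Every table draws from a named substream of
#'   this seed, so any single table is reproducible in isolation.
#' @param n_genes Number of screened genes.
#' @param n_control_genotypes Number of control genotypes per assay batch.
#' @param vacuole_mean_normal,vacuole_mean_degenerating Poisson means for
#'   vacuole counts per head.
#' @param n_heads Heads examined per genotype (>= 2).
#' @param erg_baseline_mv,erg_plateau_mv,erg_on_mv,erg_off_mv ERG trace
#'   anatomy in mV. Depolarization is stored corneal-negative, so the
#'   plateau default is -10 mV; transient magnitudes are non-negative.
#' @param erg_noise_sd Gaussian noise SD (mV) added to simulated traces.
#' @param erg_effect Fractional change in trace components for genotypes with
#'   a true ERG phenotype (0.5 = 50% reduction for "decreased").
#' @param n_flies_erg Flies per genotype; `n_traces_per_fly` traces are
#'   averaged into one biological replicate per fly.
#' @param n_traces_per_fly Traces recorded per fly.
#' @param sampling_rate_hz,trace_end_s,stimulus_onset_s,stimulus_offset_s
#'   Trace grid and light-pulse window.
#' @param p_heat_control,p_bang_control Control impairment probabilities.
#' @param p_stress_sensitive Impairment probability for truly sensitive
#'   genotypes.
#' @param n_flies_stress Flies per stress trial (5-10 in practice).
#' @param n_stress_replicates Biological replicates in the replication stage.
#' @param climb_baseline,climb_decline Baseline speed (mm/s) at day 5 and
#'   decline per day for the disease control.
#' @param climb_shift,climb_slope Modifier effects: curve shift (mm/s) and
#'   slope change (mm/s/day); negative values worsen climbing (enhancer).
#' @param climb_vial_sd,climb_noise_sd Random vial intercept SD and residual
#'   SD (mm/s).
#' @param n_vials Vials per genotype.
#' @param ages_tau,ages_abeta Assessment ages (days post-eclosion).
#' @param age_transform Age transform g() of the decline term: "linear",
#'   "quadratic" or "log".
#' @param prevalence Named list of true-phenotype prevalences; see defaults.
#' @param n_individuals Cohort size for genotype simulation.
#' @param n_snps_per_cluster SNPs per phenotype cluster in the cohort.
#' @param base_freq Baseline risk-allele frequency in (0, 1).
#' @param enrichment_delta Added to `base_freq` at enriched-cluster SNPs for
#'   a subgroup (subtracted at depleted clusters).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       n_control_genotypes = 2L,
                       vacuole_mean_normal = 5,
                       vacuole_mean_degenerating = 25,
                       n_heads = 2L,
                       erg_baseline_mv = 0,
                       erg_plateau_mv = -10,
                       erg_on_mv = 3,
                       erg_off_mv = 4,
                       erg_noise_sd = 0.5,
                       erg_effect = 0.5,
                       n_flies_erg = 5L,
                       n_traces_per_fly = 5L,
                       sampling_rate_hz = 500,
                       trace_end_s = 0.9,
                       stimulus_onset_s = 0.2,
                       stimulus_offset_s = 0.7,
                       p_heat_control = 0.26,
                       p_bang_control = 0.19,
                       p_stress_sensitive = 0.9,
                       n_flies_stress = 10L,
                       n_stress_replicates = 5L,
                       climb_baseline = 10,
                       climb_decline = 0.5,
                       climb_shift = -1.5,
                       climb_slope = -0.05,
                       climb_vial_sd = 0.3,
                       climb_noise_sd = 0.5,
                       n_vials = 4L,
                       ages_tau = seq(5, 18, length.out = 6),
                       ages_abeta = seq(5, 18, length.out = 9),
                       age_transform = c("linear", "quadratic", "log"),
                       prevalence = list(structure = 0.18,
                                         erg_decreased = 0.30,
                                         erg_increased = 0.04,
                                         erg_mixed = 0.01,
                                         heat = 0.07,
                                         bang = 0.03,
                                         tau_enhancer = 0.15,
                                         tau_suppressor = 0.07,
                                         abeta_enhancer = 0.06,
                                         abeta_suppressor = 0.03,
                                         essential = 0.23,
                                         lethal = 0.09),
                       n_individuals = 100L,
                       n_snps_per_cluster = 10L,
                       base_freq = 0.3,
                       enrichment_delta = 0.2) {
  age_transform <- match.arg(age_transform)
  assert_count(n_genes, "n_genes")
  assert_count(n_control_genotypes, "n_control_genotypes")
  assert_count(n_heads, "n_heads")
  assert_prob(c(p_heat_control, p_bang_control, p_stress_sensitive),
              "stress probabilities")
  assert_prob(unlist(prevalence), "prevalence")
  if (base_freq <= 0 || base_freq >= 1) abort("`base_freq` must be in (0, 1).")
  if (erg_noise_sd < 0 || climb_noise_sd < 0 || climb_vial_sd < 0) {
    abort("noise SDs must be non-negative.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_genes, "genes |",
      x$n_individuals, "cohort individuals\n")
  invisible(x)
}

age_g <- function(age, transform) {
  a <- age - min(age)
  switch(transform,
         linear = a,
         quadratic = a + 0.02 * a^2,
         log = log1p(a) * max(a) / log1p(max(a)))
}

#' Simulate one electroretinogram trace
#'
#' Produces a voltage trace with the canonical anatomy of a fly ERG: a flat
#' pre-stimulus baseline, a sustained depolarization plateau during the light
#' pulse (the light-coincident receptor potential, stored corneal-negative),
#' a brief onset excursion of magnitude `on_mv` beyond the plateau, a brief
#' offset excursion of magnitude `off_mv` beyond baseline (opposite polarity
#' to the plateau), and additive Gaussian noise. Transients decay linearly
#' over 50 ms so that a noiseless trace round-trips exactly through
#' [extract_erg_features()].
#'
#' @param baseline_mv,plateau_mv,on_mv,off_mv Trace components (mV);
#'   `plateau_mv` is signed (depolarization negative), transients are
#'   magnitudes (>= 0).
#' @param noise_sd Gaussian noise SD in mV (>= 0).
#' @param stimulus_onset_s,stimulus_offset_s Light pulse window (s), strictly
#'   inside `[0, trace_end_s]`.
#' @param trace_end_s Trace duration (s).
#' @param sampling_rate_hz Sampling rate (> 0).
#'
#' @return A tibble of class `erg_trace` with columns `time_s`, `voltage_mv`
#'   and attributes `stimulus_onset`/`stimulus_offset`.
#' @export
#' @examples
#' tr <- simulate_erg_trace(plateau_mv = -10, noise_sd = 0)
#' extract_erg_features(tr)
simulate_erg_trace <- function(baseline_mv = 0, plateau_mv = -10,
                               on_mv = 3, off_mv = 4, noise_sd = 0,
                               stimulus_onset_s = 0.2,
                               stimulus_offset_s = 0.7,
                               trace_end_s = 0.9,
                               sampling_rate_hz = 500) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (sampling_rate_hz <= 0) abort("`sampling_rate_hz` must be positive.")
  if (!(0 < stimulus_onset_s && stimulus_onset_s < stimulus_offset_s &&
        stimulus_offset_s < trace_end_s)) {
    abort("stimulus window must satisfy 0 < onset < offset < trace end.")
  }
  if (on_mv < 0 || off_mv < 0) abort("transient magnitudes must be >= 0.")
  time_s <- seq(0, trace_end_s, by = 1 / sampling_rate_hz)
  s <- if (plateau_mv > 0) 1 else -1  # depolarization direction
  plateau_level <- baseline_mv + plateau_mv
  decay <- function(t0, tau = 0.05) pmax(0, 1 - (time_s - t0) / tau)
  in_stim <- time_s >= stimulus_onset_s & time_s < stimulus_offset_s
  post <- time_s >= stimulus_offset_s
  v <- rep(baseline_mv, length(time_s))
  v[in_stim] <- plateau_level + s * on_mv * decay(stimulus_onset_s)[in_stim]
  v[post] <- baseline_mv - s * off_mv * decay(stimulus_offset_s)[post]
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  new_erg_trace(tibble(time_s = time_s, voltage_mv = v),
                stimulus_onset_s, stimulus_offset_s)
}

new_erg_trace <- function(df, onset, offset) {
  structure(df, class = c("erg_trace", class(tibble())),
            stimulus_onset = onset, stimulus_offset = offset)
}

#' Simulate a full synthetic screen dataset
#'
#' Generates every assay table the pipeline consumes, under the study design
#' encoded in [sim_config()]: Poisson vacuole counts per head, ERG voltage
#' traces (5 flies x 5 traces per genotype), binomial heat/bang stress trials
#' (one primary trial plus replication-stage replicates per genotype), and
#' longitudinal climbing-speed series for the amyloid-beta and tau models
#' with a random vial intercept. True phenotype labels are drawn per gene
#' from the configured prevalences and recorded alongside the data.
#'
#' Gene viability triage mirrors the screen design: viable genes are assayed
#' as one deficiency trans-heterozygote genotype, essential-but-rescuable
#' genes as two RNAi genotypes (both of which must satisfy hit criteria
#' downstream), and genes lethal even with RNAi are excluded from
#' phenotyping.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `screen_dataset` with tibbles `genes`, `vacuoles`,
#'   `erg_traces`, `stress_trials`, `climbing`, and `truth`.
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- with_substream(config$seed, "genes", simulate_gene_truth(config))
  assayed <- genes[genes$viability != "essential_lethal", ]
  genotypes <- gene_genotypes(assayed)

  vac <- with_substream(config$seed, "vacuoles",
                        simulate_vacuoles(genotypes, genes, config))
  erg <- with_substream(config$seed, "erg",
                        simulate_erg_table(genotypes, genes, config))
  stress <- with_substream(config$seed, "stress",
                           simulate_stress(genotypes, genes, config))
  climb <- with_substream(config$seed, "climbing",
                          simulate_climbing_tables(genes, config))

  structure(list(genes = genes, vacuoles = vac, erg_traces = erg$traces,
                 erg_meta = erg$meta, stress_trials = stress,
                 climbing = climb, truth = genes, config = config),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("<screen_dataset>", nrow(x$genes), "genes;",
      nrow(x$vacuoles), "vacuole rows;",
      nrow(x$stress_trials), "stress trials;",
      nrow(x$climbing), "climbing rows\n")
  invisible(x)
}

simulate_gene_truth <- function(cfg) {
  p <- cfg$prevalence
  n <- cfg$n_genes
  gene_id <- sprintf("gene%03d", seq_len(n))
  viability <- sample(c("viable", "essential_rescuable", "essential_lethal"),
                      n, replace = TRUE,
                      prob = c(1 - p$essential - p$lethal, p$essential, p$lethal))
  erg_class <- sample(c("none", "decreased", "increased", "mixed"), n,
                      replace = TRUE,
                      prob = c(1 - p$erg_decreased - p$erg_increased - p$erg_mixed,
                               p$erg_decreased, p$erg_increased, p$erg_mixed))
  mod <- function(pe, ps) sample(c("none", "enhancer", "suppressor"), n,
                                 replace = TRUE, prob = c(1 - pe - ps, pe, ps))
  tibble(gene = gene_id,
         viability = viability,
         degenerating = stats::runif(n) < p$structure,
         erg_class = erg_class,
         heat_sensitive = stats::runif(n) < p$heat,
         bang_sensitive = stats::runif(n) < p$bang,
         tau_modifier = mod(p$tau_enhancer, p$tau_suppressor),
         abeta_modifier = mod(p$abeta_enhancer, p$abeta_suppressor),
         expression_category = sample(
           c("neuron", "glia", "both", "undetermined", "not_detected"), n,
           replace = TRUE, prob = c(0.24, 0.13, 0.46, 0.15, 0.02)),
         locus_id = sprintf("L%03d", seq_len(n)),
         lead_snp = sprintf("rs%06d", 13L * seq_len(n)),
         risk_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
         evidence_class = "functional_genomic")
}

# One genotype per viable gene (GAL4/deficiency), two RNAi genotypes per
# essential gene; lethal genes carry no assay genotypes.
gene_genotypes <- function(genes) {
  genes |>
    rowwise() |>
    reframe(gene = .data$gene, viability = .data$viability,
            genotype = if (.data$viability == "viable") {
              paste0(.data$gene, "_df")
            } else {
              paste0(.data$gene, c("_rnai1", "_rnai2"))
            })
}

control_ids <- function(cfg, prefix) sprintf("%s_ctrl%d", prefix,
                                             seq_len(cfg$n_control_genotypes))

simulate_vacuoles <- function(genotypes, genes, cfg) {
  gt <- genotypes |>
    left_join(genes[, c("gene", "degenerating")], by = "gene") |>
    mutate(mean = ifelse(.data$degenerating, cfg$vacuole_mean_degenerating,
                         cfg$vacuole_mean_normal))
  ctrl <- tibble(gene = NA_character_, genotype = control_ids(cfg, "vac"),
                 mean = cfg$vacuole_mean_normal)
  all <- bind_rows(gt[, c("gene", "genotype", "mean")], ctrl)
  all |>
    rowwise() |>
    reframe(gene = .data$gene, genotype = .data$genotype,
            head_id = seq_len(cfg$n_heads),
            vacuole_count = rpois(cfg$n_heads, .data$mean))
}

erg_effect_params <- function(class, cfg) {
  e <- cfg$erg_effect
  base <- c(plateau = cfg$erg_plateau_mv, on = cfg$erg_on_mv, off = cfg$erg_off_mv)
  switch(class,
         none = base,
         decreased = base * (1 - e),
         increased = base * (1 + e),
         mixed = c(plateau = base[["plateau"]] * (1 + e),
                   on = base[["on"]] * (1 + e),
                   off = base[["off"]] * (1 - e)))
}

simulate_erg_table <- function(genotypes, genes, cfg) {
  gt <- genotypes |>
    left_join(genes[, c("gene", "erg_class")], by = "gene")
  # deficiency genotypes carry mini-white (orange_red eyes); RNAi lines here
  # are modelled as white-eyed, each compared to eye-color-matched controls
  gt$eye_color <- ifelse(grepl("_df$", gt$genotype), "orange_red", "white")
  ctrl <- tidyr::expand_grid(gene = NA_character_,
                             eye_color = c("white", "orange_red"),
                             idx = seq_len(cfg$n_control_genotypes)) |>
    mutate(genotype = sprintf("erg_ctrl_%s%d", substr(.data$eye_color, 1, 1),
                              .data$idx),
           erg_class = "none") |>
    select("gene", "genotype", "erg_class", "eye_color")
  all <- bind_rows(gt[, c("gene", "genotype", "erg_class", "eye_color")], ctrl)

  traces <- purrr::pmap(all, function(gene, genotype, erg_class, eye_color) {
    par <- erg_effect_params(erg_class, cfg)
    tidyr::expand_grid(fly_id = seq_len(cfg$n_flies_erg),
                       trace_id = seq_len(cfg$n_traces_per_fly)) |>
      rowwise() |>
      reframe(fly_id = .data$fly_id, trace_id = .data$trace_id,
              simulate_erg_trace(cfg$erg_baseline_mv, par[["plateau"]],
                                 par[["on"]], par[["off"]], cfg$erg_noise_sd,
                                 cfg$stimulus_onset_s, cfg$stimulus_offset_s,
                                 cfg$trace_end_s, cfg$sampling_rate_hz)) |>
      mutate(genotype = genotype, eye_color = eye_color, .before = 1)
  }) |> purrr::list_rbind()
  list(traces = traces,
       meta = all |> mutate(is_control = is.na(.data$gene)))
}

simulate_stress <- function(genotypes, genes, cfg) {
  gt <- genotypes |>
    left_join(genes[, c("gene", "heat_sensitive", "bang_sensitive")],
              by = "gene")
  ctrl <- tibble(gene = NA_character_, genotype = control_ids(cfg, "stress"),
                 heat_sensitive = FALSE, bang_sensitive = FALSE)
  all <- bind_rows(gt[, names(ctrl)], ctrl)
  tidyr::expand_grid(all, stressor = c("heat", "bang"),
                     replicate_id = seq(0L, cfg$n_stress_replicates)) |>
    mutate(stage = ifelse(.data$replicate_id == 0L, "primary", "replicate"),
           sensitive = ifelse(.data$stressor == "heat", .data$heat_sensitive,
                              .data$bang_sensitive),
           p = dplyr::case_when(
             sensitive ~ cfg$p_stress_sensitive,
             .data$stressor == "heat" ~ cfg$p_heat_control,
             TRUE ~ cfg$p_bang_control),
           n_flies = cfg$n_flies_stress,
           n_impaired = rbinom(dplyr::n(), cfg$n_flies_stress, .data$p)) |>
    select("gene", "genotype", "stressor", "stage", "replicate_id",
           "n_flies", "n_impaired")
}

#' Simulate a climbing experiment for one genotype pair
#'
#' Generates longitudinal climbing-speed data (mean speed of the flies in
#' each vial at each age) for a disease control and one test strain. The
#' speed model is `baseline - decline * g(age) + shift + slope * (age -
#' min(age)) + vial intercept + noise`, truncated at zero.
#'
#' @param ages Assessment ages (days post-eclosion).
#' @param n_vials Vials per genotype.
#' @param baseline,decline Control curve parameters (mm/s, mm/s per day).
#' @param shift,slope Test-strain curve shift (mm/s) and slope change
#'   (mm/s/day); zero for a null strain.
#' @param vial_sd,noise_sd Random vial intercept SD and residual SD.
#' @param age_transform Age transform of the decline term.
#' @param genotypes Names for the control and test genotype.
#' @return Tibble with columns `genotype`, `vial_id`, `age_days`,
#'   `mean_speed`.
#' @export
simulate_climbing_pair <- function(ages = seq(5, 18, length.out = 6),
                                   n_vials = 4L, baseline = 10, decline = 0.5,
                                   shift = 0, slope = 0, vial_sd = 0.3,
                                   noise_sd = 0.5,
                                   age_transform = "linear",
                                   genotypes = c("control", "test")) {
  assert_count(n_vials, "n_vials")
  g <- age_g(ages, age_transform)
  per_geno <- function(geno, sh, sl) {
    vial_int <- rnorm(n_vials, 0, vial_sd)
    tidyr::expand_grid(vial_id = seq_len(n_vials), i = seq_along(ages)) |>
      mutate(genotype = geno, age_days = ages[.data$i],
             mean_speed = pmax(0, baseline - decline * g[.data$i] + sh +
                                 sl * (ages[.data$i] - min(ages)) +
                                 vial_int[.data$vial_id] +
                                 rnorm(dplyr::n(), 0, noise_sd))) |>
      mutate(vial_id = paste0(geno, "_v", .data$vial_id)) |>
      select("genotype", "vial_id", "age_days", "mean_speed")
  }
  bind_rows(per_geno(genotypes[1], 0, 0), per_geno(genotypes[2], shift, slope))
}

simulate_climbing_tables <- function(genes, cfg) {
  purrr::map(c(abeta = "abeta", tau = "tau"), function(model) {
    ages <- if (model == "tau") cfg$ages_tau else cfg$ages_abeta
    mods <- genes[[paste0(model, "_modifier")]]
    strain_tbl <- genes |>
      mutate(modifier = mods) |>
      rowwise() |>
      reframe(gene = .data$gene, modifier = .data$modifier,
              strain = paste0(.data$gene, "_s", 1:2))
    ctrl_name <- paste0("ctrl_", model)
    rows <- purrr::pmap(strain_tbl, function(gene, modifier, strain) {
      sh <- switch(modifier, none = 0, enhancer = cfg$climb_shift,
                   suppressor = -cfg$climb_shift)
      sl <- switch(modifier, none = 0, enhancer = cfg$climb_slope,
                   suppressor = -cfg$climb_slope)
      d <- simulate_climbing_pair(ages, cfg$n_vials, cfg$climb_baseline,
                                  cfg$climb_decline, sh, sl, cfg$climb_vial_sd,
                                  cfg$climb_noise_sd, cfg$age_transform,
                                  genotypes = c(ctrl_name, strain))
      d$gene <- gene
      d[d$genotype != ctrl_name, ]
    }) |> purrr::list_rbind()
    ctrl <- simulate_climbing_pair(ages, cfg$n_vials, cfg$climb_baseline,
                                   cfg$climb_decline, 0, 0, cfg$climb_vial_sd,
                                   cfg$climb_noise_sd, cfg$age_transform,
                                   genotypes = c(ctrl_name, "unused")) |>
      filter(.data$genotype == ctrl_name) |>
      mutate(gene = NA_character_)
    bind_rows(ctrl, rows) |> mutate(disease_model = model, .before = 1)
  }) |> purrr::list_rbind()
}

#' Simulate cohort genotypes from risk-allele frequencies
#'
#' Draws diploid risk-allele dosages (0/1/2) for each individual at each SNP
#' as Binomial(2, f). Optionally splits the cohort into subgroups with
#' enriched risk-allele frequencies at the SNPs of chosen phenotype clusters
#' (and depleted elsewhere is not assumed: only listed clusters move).
#'
#' @param n_individuals Cohort size.
#' @param cluster_snps Named list mapping cluster names to SNP id vectors; if
#'   `NULL`, `n_snps_per_cluster` SNPs per cluster are invented for the four
#'   canonical clusters (ERG, Structure, Bang, Heat).
#' @param base_freq Baseline risk-allele frequency, or a named vector of
#'   per-SNP frequencies.
#' @param subgroups Named list mapping subgroup name to the clusters it is
#'   enriched for, e.g. `list(g1 = c("ERG", "Structure"), g2 = c("Bang",
#'   "Heat"))`. Individuals are split evenly across subgroups.
#' @param enrichment_delta Frequency increment at enriched SNPs; resulting
#'   frequencies are clamped to `[0.001, 0.999]` and an error is raised if a
#'   requested frequency falls outside (0, 1) by more than the clamp.
#' @param n_snps_per_cluster SNPs per invented cluster.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim` with `genotypes` (a
#'   `cohort_genotypes` tibble: `individual_id` + one dosage column per SNP),
#'   `snp_info` (snp_id, cluster, ref, alt, risk_allele, frequency columns)
#'   and `subgroups` (individual_id, subgroup).
#' @export
simulate_cohort <- function(n_individuals = 100L, cluster_snps = NULL,
                            base_freq = 0.3, subgroups = NULL,
                            enrichment_delta = 0.2,
                            n_snps_per_cluster = 10L, seed = 1L) {
  assert_count(n_individuals, "n_individuals")
  if (is.null(cluster_snps)) {
    clusters <- c("ERG", "Structure", "Bang", "Heat")
    cluster_snps <- purrr::imap(setNames(clusters, clusters), function(cl, nm) {
      sprintf("rs%s%02d", tolower(nm), seq_len(n_snps_per_cluster))
    })
  }
  snp_info <- purrr::imap(cluster_snps, function(snps, cl) {
    tibble(snp_id = snps, cluster = cl)
  }) |> purrr::list_rbind()
  if (anyDuplicated(snp_info$snp_id)) abort("duplicate SNP ids across clusters.")
  n_snp <- nrow(snp_info)
  freq <- if (length(base_freq) == 1L) rep(base_freq, n_snp) else
    unname(base_freq[snp_info$snp_id])
  if (length(freq) != n_snp || anyNA(freq)) {
    abort("`base_freq` must be scalar or name every SNP.")
  }
  if (any(freq <= 0 | freq >= 1)) abort("frequencies must be in (0, 1).")

  ids <- sprintf("ind%03d", seq_len(n_individuals))
  sub_tbl <- if (is.null(subgroups)) {
    tibble(individual_id = ids, subgroup = "all")
  } else {
    tibble(individual_id = ids,
           subgroup = rep(names(subgroups), length.out = n_individuals) |>
             sort())
  }

  withr::with_seed(substream_seed(seed, "cohort"), {
    dosage <- matrix(NA_integer_, n_individuals, n_snp,
                     dimnames = list(ids, snp_info$snp_id))
    for (g in unique(sub_tbl$subgroup)) {
      rows <- sub_tbl$individual_id[sub_tbl$subgroup == g]
      f <- freq
      if (!is.null(subgroups) && g %in% names(subgroups)) {
        enr <- snp_info$cluster %in% subgroups[[g]]
        f[enr] <- f[enr] + enrichment_delta
      }
      if (any(f <= 0 | f >= 1)) {
        abort("enriched frequency outside (0, 1); adjust `enrichment_delta`.")
      }
      f <- pmin(pmax(f, 0.001), 0.999)
      dosage[rows, ] <- rbinom(length(rows) * n_snp, 2L, rep(f, each = length(rows)))
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snp, replace = TRUE)
    alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
  })
  snp_info <- snp_info |>
    mutate(ref = ref, alt = alt, risk_allele = alt, frequency = freq,
           chrom = "1", pos = 1000L * seq_len(n_snp))
  geno <- as_tibble(dosage) |> mutate(individual_id = ids, .before = 1)
  class(geno) <- c("cohort_genotypes", class(geno))
  structure(list(genotypes = geno, snp_info = snp_info, subgroups = sub_tbl),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>", nrow(x$genotypes), "individuals x",
      nrow(x$snp_info), "SNPs\n")
  invisible(x)
}

#' Write a screen dataset to TSV files plus a truth-label JSON
#'
#' @param dataset A `screen_dataset` from [simulate_screen()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_screen_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "screen_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vacuoles = file.path(dir, "vacuoles.tsv"),
    erg_traces = file.path(dir, "erg_traces.tsv"),
    stress_trials = file.path(dir, "stress_trials.tsv"),
    climbing = file.path(dir, "climbing.tsv"),
    genes = file.path(dir, "genes.tsv"),
    truth = file.path(dir, "truth.json"))
  for (nm in c("vacuoles", "erg_traces", "stress_trials", "climbing", "genes")) {
    readr::write_tsv(dataset[[nm]], paths[[nm]])
  }
  jsonlite::write_json(dataset$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write cohort genotypes as a minimal biallelic VCF (v4.2, GT only)
#'
#' @param cohort A `cohort_sim` from [simulate_cohort()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_sim"))
  geno <- cohort$genotypes
  info <- cohort$snp_info
  ids <- geno$individual_id
  gt_string <- function(d) c("0/0", "0/1", "1/1")[d + 1L]
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
  body <- purrr::pmap_chr(info, function(snp_id, cluster, ref, alt,
                                         risk_allele, frequency, chrom, pos) {
    # dosages are counts of the risk allele (= ALT here); GT encodes ALT count
    d <- geno[[snp_id]]
    gt <- ifelse(is.na(d), "./.", gt_string(ifelse(is.na(d), 0L, d)))
    paste(c(chrom, pos, snp_id, ref, alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  })
  writeLines(c(lines, body), path)
  invisible(path)
}
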