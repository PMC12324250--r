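test_that("average_fly_traces is the pointwise mean with grid checks", {
  tr <- simulate_erg_trace(noise_sd = 0)
  expect_equal(average_fly_traces(list(tr))$voltage_mv, tr$voltage_mv)
  neg <- tr; neg$voltage_mv <- -tr$voltage_mv
  expect_equal(average_fly_traces(list(tr, neg))$voltage_mv,
               rep(0, nrow(tr)))
  expect_equal(average_fly_traces(rep(list(tr), 5))$voltage_mv,
               tr$voltage_mv)
  short <- simulate_erg_trace(noise_sd = 0, sampling_rate_hz = 100)
  expect_error(average_fly_traces(list(tr, short)), "mismatched")
})

test_that("feature extraction recovers configured components and their invariances", {
  # flat null trace
  flat <- simulate_erg_trace(baseline_mv = 0, plateau_mv = 0, on_mv = 0,
                             off_mv = 0, noise_sd = 0)
  expect_equal(unlist(extract_erg_features(flat)),
               c(lcrp_amplitude = 0, on_transient = 0, off_transient = 0))

  # generator/extractor round trip: plateau -10, on 3, off 4 -> (10, 3, 4)
  tr <- simulate_erg_trace(plateau_mv = -10, on_mv = 3, off_mv = 4,
                           noise_sd = 0)
  f <- extract_erg_features(tr)
  expect_equal(f$lcrp_amplitude, 10)
  expect_equal(f$on_transient, 3)
  expect_equal(f$off_transient, 4)

  # additive offset invariance
  shifted <- tr; shifted$voltage_mv <- tr$voltage_mv + 12.5
  expect_equal(extract_erg_features(shifted), f)

  # time-shift invariance when the stimulus window moves consistently
  moved <- simulate_erg_trace(plateau_mv = -10, on_mv = 3, off_mv = 4,
                              noise_sd = 0, stimulus_onset_s = 0.3,
                              stimulus_offset_s = 0.8, trace_end_s = 1.0)
  expect_equal(extract_erg_features(moved), f)

  # windows outside the trace error
  expect_error(extract_erg_features(tr, erg_windows(off_s = 5)), "outside")
})

test_that("genotype comparisons behave on exchangeable and separated groups", {
  feats <- dplyr::bind_rows(
    tibble::tibble(genotype = "ctrl", fly_id = 1:5, eye_color = "white",
                   lcrp_amplitude = c(5, 6, 5, 6, 5), on_transient = 1,
                   off_transient = 1),
    tibble::tibble(genotype = "mut", fly_id = 1:5, eye_color = "white",
                   lcrp_amplitude = c(50, 51, 50, 51, 50), on_transient = 1,
                   off_transient = 1))
  res <- compare_erg_genotypes(feats, c(white = "ctrl"))
  amp <- res[res$component == "lcrp_amplitude", ]
  expect_lt(amp$p_adjusted, 0.05)
  expect_equal(amp$direction, 1)
  expect_equal(amp$control_ratio, mean(c(50, 51, 50, 51, 50)) / 5.4)
  # identical replicates: tied components flagged, not significant
  tied <- res[res$component == "on_transient", ]
  expect_false(tied$significant)
  # adjustment monotonicity
  expect_true(all(res$p_adjusted >= res$p_value))
})

test_that("mutants are only compared to eye-color-matched controls", {
  feats <- dplyr::bind_rows(
    fly_features("ctrl_w", 3, -10, noise_sd = 0.1, eye = "white"),
    fly_features("mut_o", 3, -5, noise_sd = 0.1, eye = "orange_red"))
  expect_error(compare_erg_genotypes(feats, c(white = "ctrl_w")),
               "orange_red")
})

test_that("gene classification applies the direction and essential-gene rules", {
  mk <- function(gene, genotype, comp, dir, p) {
    tibble::tibble(gene = gene, genotype = genotype, component = comp,
                   direction = dir, p_adjusted = p)
  }
  genes <- tibble::tibble(gene = c("gA", "gB", "gC"),
                          viability = c("viable", "essential_rescuable",
                                        "viable"))
  # mixed: amplitude and on increased, off decreased
  cmp <- dplyr::bind_rows(
    mk("gA", "gA_df", "lcrp_amplitude", 1, 0.01),
    mk("gA", "gA_df", "on_transient", 1, 0.02),
    mk("gA", "gA_df", "off_transient", -1, 0.03))
  expect_equal(classify_erg_gene(cmp, genes)$erg_class, "mixed")

  # essential gene: one RNAi significant, the other not -> none
  cmp_b <- dplyr::bind_rows(
    mk("gB", "gB_rnai1", "lcrp_amplitude", -1, 0.001),
    mk("gB", "gB_rnai2", "lcrp_amplitude", -1, 0.40),
    mk("gB", "gB_rnai1", "on_transient", -1, 0.9),
    mk("gB", "gB_rnai2", "on_transient", -1, 0.9))
  expect_equal(classify_erg_gene(cmp_b, genes)$erg_class, "none")

  # nothing significant -> none
  cmp_c <- mk("gC", "gC_df", "lcrp_amplitude", 1, 0.8)
  expect_equal(classify_erg_gene(cmp_c, genes)$erg_class, "none")

  # essential gene with a single strain is a structural error
  expect_error(classify_erg_gene(mk("gB", "gB_rnai1", "lcrp_amplitude",
                                    -1, 0.01), genes), "< 2 RNAi")
})

test_that("per-component type-I rate is controlled on null simulations", {
  n_geno <- 1000
  calls <- withr::with_seed(2024, purrr::map_lgl(seq_len(n_geno), function(i) {
    feats <- dplyr::bind_rows(fly_features("ctrl", 5, -10, noise_sd = 0.5),
                              fly_features("mut", 5, -10, noise_sd = 0.5))
    res <- compare_erg_genotypes(feats, c(white = "ctrl"),
                                 components = "lcrp_amplitude")
    res$significant
  }))
  expect_lte(mean(calls), 0.07)
})

test_that("halved amplitude with modest noise is detected with correct direction", {
  n_geno <- 200
  ok <- withr::with_seed(77, purrr::map_lgl(seq_len(n_geno), function(i) {
    feats <- dplyr::bind_rows(fly_features("ctrl", 5, -10, noise_sd = 1),
                              fly_features("mut", 5, -5, noise_sd = 1))
    res <- compare_erg_genotypes(feats, c(white = "ctrl"),
                                 components = "lcrp_amplitude")
    res$significant && res$direction == -1
  }))
  expect_gte(mean(ok), 0.95)
})

test_that("erg_feature_table averages each fly's traces before extraction", {
  cfg <- sim_config(seed = 21, n_genes = 2, n_flies_erg = 2,
                    n_traces_per_fly = 3, sampling_rate_hz = 200,
                    erg_noise_sd = 0)
  ds <- simulate_screen(cfg)
  ft <- erg_feature_table(ds$erg_traces, cfg$stimulus_onset_s,
                          cfg$stimulus_offset_s)
  expect_equal(nrow(ft), dplyr::n_distinct(ds$erg_traces$genotype) * 2)
  # noiseless: every unaffected genotype shows the configured components
  none_genos <- ds$erg_meta$genotype[ds$erg_meta$erg_class == "none"]
  sub <- ft[ft$genotype %in% none_genos, ]
  expect_equal(sub$lcrp_amplitude, rep(10, nrow(sub)))
  expect_equal(sub$on_transient, rep(3, nrow(sub)))
})
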