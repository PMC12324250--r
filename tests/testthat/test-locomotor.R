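ages6 <- seq(5, 18, length.out = 6)

test_that("noiseless fits recover the generating coefficients exactly", {
  # identical curves: all genotype terms zero, p-values 1
  d0 <- withr::with_seed(1, simulate_climbing_pair(ages6, 4, vial_sd = 0,
                                                   noise_sd = 0))
  f0 <- fit_longitudinal(d0, "control")
  co0 <- tidy(f0)
  expect_equal(co0$estimate[grepl("genotype", co0$term)],
               rep(0, 3), tolerance = 1e-10)
  expect_equal(test_effects(f0)$p_value, rep(1, 3))

  # constant -2 mm/s offset (least-squares oracle: exact recovery)
  d1 <- withr::with_seed(1, simulate_climbing_pair(ages6, 4, shift = -2,
                                                   vial_sd = 0, noise_sd = 0))
  f1 <- fit_longitudinal(d1, "control")
  co1 <- tidy(f1)
  expect_equal(co1$estimate[co1$term == "genotypetest"], -2,
               tolerance = 1e-8)
  expect_equal(co1$estimate[co1$term == "age_c:genotypetest"], 0,
               tolerance = 1e-8)
  # perfect separation reports a floor p-value
  expect_lt(test_effects(f1)$p_value[2], 1e-12)

  # extra slope -0.1 mm/s/day lands on the interaction coefficient
  d2 <- withr::with_seed(2, simulate_climbing_pair(ages6, 4, slope = -0.1,
                                                   vial_sd = 0, noise_sd = 0))
  co2 <- tidy(fit_longitudinal(d2, "control"))
  expect_equal(co2$estimate[co2$term == "age_c:genotypetest"], -0.1,
               tolerance = 1e-8)
})

test_that("fits validate their design requirements", {
  d <- withr::with_seed(3, simulate_climbing_pair(ages6, 4))
  expect_error(fit_longitudinal(d[d$genotype == "control", ], "control"),
               "two genotypes")
  two_tp <- d[d$age_days %in% ages6[1:2], ]
  expect_error(fit_longitudinal(two_tp, "control"), "3 shared timepoints")
  one_vial <- d[d$vial_id %in% c("control_v1", "test_v1"), ]
  expect_error(fit_longitudinal(one_vial, "control"), "2 vials")
})

test_that("null effect-test p-values are uniform (simulation calibration)", {
  ps <- withr::with_seed(123, purrr::map(1:1000, function(i) {
    d <- simulate_climbing_pair(ages6, 4, vial_sd = 0.3, noise_sd = 0.5)
    test_effects(fit_longitudinal(d, "control"))$p_value
  }))
  P <- do.call(rbind, ps)
  for (j in 1:3) {
    ks <- suppressWarnings(stats::ks.test(P[, j], "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("area between curves matches analytic cases and is antisymmetric", {
  grid <- c(5, 18)
  ctrl <- c(10, 3.5)
  expect_equal(area_between_curves(grid, ctrl, ctrl), 0)
  expect_equal(area_between_curves(grid, ctrl - 2, ctrl), -26)
  expect_equal(area_between_curves(grid, c(10, 1.5), ctrl), -13)
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- sort(stats::runif(6, 0, 20))
      f <- stats::rnorm(6); g <- stats::rnorm(6)
      expect_equal(area_between_curves(a, f, g),
                   -area_between_curves(a, g, f))
    }
  })
  # exact additivity under grid refinement for piecewise-linear curves
  coarse <- c(5, 18)
  fine <- seq(5, 18, length.out = 27)
  lin <- function(x, y0, y1) y0 + (y1 - y0) * (x - 5) / 13
  expect_equal(
    area_between_curves(fine, lin(fine, 8, 1.5), lin(fine, 10, 3.5)),
    area_between_curves(coarse, c(8, 1.5), c(10, 3.5)))
  expect_error(area_between_curves(c(5, 4), 1:2, 1:2), "increasing")
})

test_that("strain classification gates on significance and effect size", {
  tests <- tibble::tibble(effect = c("genotype", "additive", "interactive"),
                          p_adjusted = c(0.2, 0.3, 0.4))
  expect_equal(classify_strain(tests, area = -30), "none")
  tests$p_adjusted <- c(0.001, 0.01, 0.2)
  expect_equal(classify_strain(tests, area = -30), "enhancer")
  expect_equal(classify_strain(tests, area = +30), "suppressor")
  # the codified visual-inspection floor suppresses tiny effects
  expect_equal(classify_strain(tests, area = -3, min_area = 10), "none")
  # interaction-only gating
  expect_equal(classify_strain(tests, area = -30, gate = "interaction"),
               "none")
})

test_that("gene consolidation requires two consistent strains", {
  calls <- function(...) tibble::tibble(gene = "g", strain = paste0("s", seq_along(c(...))),
                                        call = c(...))
  expect_true(consolidate_gene(calls("enhancer", "enhancer", "none"))$high_confidence)
  expect_equal(consolidate_gene(calls("enhancer", "enhancer", "none"))$direction,
               "enhancer")
  expect_false(consolidate_gene(calls("enhancer"))$high_confidence)
  conf <- consolidate_gene(calls("enhancer", "suppressor"))
  expect_false(conf$high_confidence)
  expect_true(conf$conflict)
})

test_that("analyze_strain ties the pieces together on a strong enhancer", {
  d <- withr::with_seed(9, simulate_climbing_pair(ages6, 4, shift = -1.5,
                                                  noise_sd = 0.5))
  res <- analyze_strain(d, "control")
  expect_equal(res$call, "enhancer")
  expect_lt(res$area, 0)
  expect_true(all(c(res$p_genotype_adj, res$p_additive_adj) >=
                    c(res$p_genotype, res$p_additive)))
})

test_that("Monte-Carlo power matches its operating limits", {
  # size equals level at zero effect
  p0 <- estimate_power(shift = 0, n_sims = 150, seed = 4,
                       ddf = "Satterthwaite")
  expect_lt(abs(p0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 0.01)
  # overwhelming effect with tiny noise
  p1 <- estimate_power(shift = -4, n_sims = 100, noise_sd = 0.01,
                       vial_sd = 0.01, seed = 5, ddf = "Satterthwaite")
  expect_equal(p1$power, 1)
  # self-consistency against a doubled-replicate rerun
  pa <- estimate_power(shift = -1, n_sims = 150, seed = 6,
                       ddf = "Satterthwaite")
  pb <- estimate_power(shift = -1, n_sims = 300, seed = 7,
                       ddf = "Satterthwaite")
  expect_lt(abs(pa$power - pb$power),
            3 * sqrt(pa$se^2 + pb$se^2) + 1e-9)
  expect_error(estimate_power(shift = 0, n_sims = 50), ">= 100")
})
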