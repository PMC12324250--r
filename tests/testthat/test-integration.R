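test_that("viability triage follows the cross-outcome scheme", {
  crosses <- tibble::tibble(
    gene = c("gA", "gB", "gC"),
    deficiency_viable = c(TRUE, FALSE, FALSE),
    rnai_viable = c(NA, TRUE, FALSE))
  v <- classify_viability(crosses)
  expect_equal(v$viability, c("viable", "essential_rescuable",
                              "essential_lethal"))
  expect_equal(v$eligible, c(TRUE, TRUE, FALSE))
  expect_equal(v$scheme, c("gal4_over_deficiency", "two_rnai", "excluded"))
  crosses$rnai_viable[2] <- NA
  expect_error(classify_viability(crosses), "missing RNAi")
})

test_that("profiles compose single-assay calls and enforce completeness", {
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          viability = c("viable", "viable",
                                        "essential_lethal"))
  strct <- tibble::tibble(gene = c("g1", "g2"),
                          structure_hit = c(FALSE, TRUE))
  erg <- tibble::tibble(gene = c("g1", "g2"),
                        erg_class = c("decreased", "none"))
  stress <- tidyr::expand_grid(stressor = c("heat", "bang"),
                               gene = c("g1", "g2")) |>
    dplyr::mutate(confirmed = .data$gene == "g2" & .data$stressor == "heat")
  prof <- build_profiles(genes, strct, erg, stress)
  g1 <- prof[prof$gene == "g1", ]
  expect_false(g1$structure); expect_true(g1$`function`)
  expect_false(g1$resilience_heat); expect_false(g1$resilience_bang)
  g2 <- prof[prof$gene == "g2", ]
  expect_true(g2$structure); expect_false(g2$`function`)
  expect_true(g2$resilience_heat)
  # excluded gene carries NA phenotypes
  expect_true(all(is.na(prof[prof$gene == "g3",
                             c("structure", "function", "resilience_heat")])))
  # a phenotyped gene missing from an assay errors
  expect_error(build_profiles(genes, strct[1, ], erg, stress), "missing")
  # unknown gene errors
  bad <- dplyr::bind_rows(strct, tibble::tibble(gene = "gX",
                                                structure_hit = TRUE))
  expect_error(build_profiles(genes, bad, erg, stress), "unknown")
})

test_that("summary counts reproduce the published screen arithmetic on the fixture", {
  fx <- screen_summary_fixture()
  s <- count_summary(fx)
  val <- function(m) s$value[s$metric == m]
  expect_equal(val("structure_total"), 18)
  expect_equal(val("function_total"), 35)
  expect_equal(val("erg_decreased"), 30)
  expect_equal(val("erg_increased"), 4)
  expect_equal(val("erg_mixed"), 1)
  expect_equal(val("structure_and_erg_decreased"), 5)
  expect_equal(val("heat_total"), 7)
  expect_equal(val("bang_total"), 3)
  expect_equal(val("heat_only"), 5)
  expect_equal(val("bang_only"), 1)
  expect_equal(val("heat_and_bang"), 2)
  expect_equal(val("resilience_union"), 8)
  expect_equal(val("cns_union"), 50)
  expect_equal(val("abeta_modifiers"), 9)
  expect_equal(val("tau_modifiers"), 22)
  expect_equal(val("modifier_both"), 3)
  expect_equal(val("modifier_union"), 28)
  # viability bookkeeping
  expect_equal(sum(fx$viability != "viable"), 32)
  expect_equal(sum(fx$viability == "essential_lethal"), 9)
  # excluded genes never appear among phenotype positives
  yes <- function(x) !is.na(x) & x
  pos <- fx$gene[yes(fx$structure) | yes(fx$`function`) |
                   yes(fx$resilience_heat) | yes(fx$resilience_bang)]
  expect_length(intersect(pos, fx$gene[fx$viability == "essential_lethal"]),
                0)
})

test_that("empty profiles give all-zero counts", {
  empty <- tibble::tibble(gene = character(), structure = logical(),
                          `function` = logical(),
                          resilience_heat = logical(),
                          resilience_bang = logical())
  expect_true(all(count_summary(empty)$value == 0))
})

test_that("inclusion-exclusion matches direct unions on random call sets", {
  withr::with_seed(66, {
    for (i in 1:20) {
      n <- 30
      prof <- tibble::tibble(
        gene = paste0("g", 1:n),
        structure = sample(c(TRUE, FALSE), n, replace = TRUE),
        `function` = sample(c(TRUE, FALSE), n, replace = TRUE),
        resilience_heat = sample(c(TRUE, FALSE), n, replace = TRUE),
        resilience_bang = sample(c(TRUE, FALSE), n, replace = TRUE))
      s <- count_summary(prof)  # aborts internally if the identity fails
      direct <- sum(prof$structure | prof$`function` |
                      prof$resilience_heat | prof$resilience_bang)
      expect_equal(s$value[s$metric == "cns_union"], direct)
    }
  })
})

test_that("expression tallies report categories and both percent summaries", {
  fx <- screen_summary_fixture()
  tl <- tally_expression(fx)
  expect_equal(tl$counts$n[match(c("neuron", "glia", "both", "undetermined",
                                   "not_detected"), tl$counts$category)],
               c(24, 13, 46, 15, 2))
  expect_equal(sum(tl$counts$n), 100)
  expect_equal(tl$percent_expressed, 98)
  expect_equal(tl$percent_colocalized, 83)
  all_nd <- tibble::tibble(gene = c("a", "b"),
                           expression_category = "not_detected")
  expect_equal(tally_expression(all_nd)$percent_expressed, 0)
  expect_error(tally_expression(tibble::tibble(gene = "a",
                                               expression_category = "soma")),
               "unknown")
})

test_that("cluster-SNP maps deduplicate loci and track exclusions", {
  fx <- screen_summary_fixture()
  cl <- assign_snp_clusters(fx, fx)
  # genes g008/g009 share one locus SNP; it appears once in Structure
  expect_equal(anyDuplicated(cl$Structure), 0)
  expect_equal(length(cl$Structure), 18 - 1 - 1)  # shared locus + rare-variant
  # default ERG scope is decreased-only; one rare-variant gene and the
  # shared-locus duplicate drop out
  expect_equal(length(cl$ERG), 30 - 1 - 1)
  expect_gt(length(assign_snp_clusters(fx, fx, erg_scope = "all")$ERG),
            length(cl$ERG))
  # a gene positive for heat and bang lands in both clusters
  tace_snp <- fx$lead_snp[fx$gene == "Tace"]
  expect_true(tace_snp %in% cl$Heat && tace_snp %in% cl$Bang)
  # rare-variant exclusions are logged
  excl <- attr(cl, "excluded")
  expect_true(all(c("g020", "g044") %in% excl$gene))
  # per-gene counting keeps the duplicate
  cl2 <- assign_snp_clusters(fx, fx, dedup = FALSE)
  expect_equal(length(cl2$Structure), 18 - 1)
  # empty cluster warns
  none <- fx
  none$resilience_bang <- FALSE
  expect_warning(assign_snp_clusters(none, none), "Bang")
})

test_that("profiles survive a TSV round trip with identical summaries", {
  fx <- screen_summary_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(fx, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(count_summary(back), count_summary(fx))
  expect_equal(tally_expression(back)$counts, tally_expression(fx)$counts)
})
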