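mk_geno <- function(M, ids = sprintf("i%02d", seq_len(nrow(M)))) {
  g <- tibble::as_tibble(M)
  dplyr::mutate(g, individual_id = ids, .before = 1)
}

test_that("risk-allele counting tabulates dosages per cluster", {
  M <- matrix(0L, 4, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  g <- mk_geno(M)
  counts <- count_risk_alleles(g, list(A = c("s1", "s2"), B = "s3"))
  expect_true(all(counts$A == 0) && all(counts$B == 0))

  M2 <- matrix(c(2L, 1L, 0L), 1, 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  g2 <- mk_geno(M2, "only")
  expect_equal(count_risk_alleles(g2, list(A = c("s1", "s2", "s3")))$A, 3)

  # disjoint clusters conserve each individual's total dosage
  withr::with_seed(12, {
    M3 <- matrix(sample(0:2, 60, replace = TRUE), 10, 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
  })
  g3 <- mk_geno(M3)
  cc <- count_risk_alleles(g3, list(A = paste0("s", 1:3),
                                    B = paste0("s", 4:6)))
  expect_equal(cc$A + cc$B, unname(rowSums(M3)))

  # carrier mode counts presence, not dosage
  expect_equal(count_risk_alleles(g2, list(A = c("s1", "s2", "s3")),
                                  mode = "carrier")$A, 2)
  expect_error(count_risk_alleles(g3, list(A = "missing_snp")), "absent")
  g3$s1[1] <- 5L
  expect_error(count_risk_alleles(g3, list(A = "s1")), "\\{0, 1, 2\\}")
})

test_that("missing dosages are mean-imputed or rejected in strict mode", {
  M <- matrix(c(0L, 2L, NA, 1L, 1L, 1L), 3, 2,
              dimnames = list(NULL, c("s1", "s2")))
  g <- mk_geno(M)
  counts <- count_risk_alleles(g, list(A = c("s1", "s2")))
  expect_equal(counts$A[3], mean(c(0, 2)) + 1)
  expect_equal(attr(counts, "missingness")$missing_frac, c(1 / 3, 0))
  expect_error(count_risk_alleles(g, list(A = c("s1", "s2")),
                                  missing = "strict"), "missing genotypes")
})

test_that("standardization matches the hand-computed z-scores", {
  counts <- tibble::tibble(individual_id = c("a", "b"), A = c(1, 3))
  z <- standardize_scores(counts)
  expect_equal(z$A, c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_error(standardize_scores(tibble::tibble(individual_id = c("a", "b"),
                                                 A = c(2, 2))),
               "zero variance")
  withr::with_seed(3, {
    counts2 <- tibble::tibble(individual_id = sprintf("i%d", 1:30),
                              A = rpois(30, 5), B = rpois(30, 3) + 0.0)
  })
  z2 <- standardize_scores(counts2)
  expect_equal(mean(z2$A), 0, tolerance = 1e-10)
  expect_equal(sd(z2$A), 1, tolerance = 1e-10)
})

test_that("PCA matches a brute-force eigensolver and its spectral identities", {
  z <- tibble::tibble(individual_id = c("a", "b", "c"),
                      ERG = c(1, -1, 0), Structure = c(-1, 1, 0))
  pca <- run_pca(z)
  expect_equal(abs(pca$loadings[, 1]), c(ERG = 1, Structure = 1) / sqrt(2),
               tolerance = 1e-10)
  expect_gte(pca$loadings["ERG", 1], 0)  # sign convention
  expect_equal(pca$variance_explained, c(1, 0), tolerance = 1e-12)

  # one informative column -> that axis explains everything
  z1 <- tibble::tibble(individual_id = letters[1:5],
                       A = c(-2, -1, 0, 1, 2), B = rep(0, 5))
  expect_equal(run_pca(z1)$variance_explained[1], 1)

  withr::with_seed(21, {
    for (i in 1:5) {
      Z <- matrix(rnorm(200), 50, 4,
                  dimnames = list(NULL, c("ERG", "Structure", "Bang",
                                          "Heat")))
      zt <- mk_geno(Z, sprintf("i%02d", 1:50))
      p <- run_pca(zt)
      # orthonormal loadings
      expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-8,
                   ignore_attr = TRUE)
      # variance fractions sum to one
      expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
      # eigenvalues agree with brute force eigen() on the covariance
      bf <- brute_pca(Z)
      expect_equal(sort(p$variance_explained, decreasing = TRUE),
                   bf$values / sum(bf$values), tolerance = 1e-8)
      # reconstruction: scores %*% t(loadings) recovers the matrix
      S <- as.matrix(p$scores[, -1])
      expect_lt(max(abs(S %*% t(p$loadings) - Z)), 1e-8)
    }
  })
})

test_that("projection and ordering follow the chosen component", {
  z <- tibble::tibble(individual_id = c("a", "b", "c"),
                      ERG = c(1, -1, 0), Structure = c(-1, 1, 0))
  pca <- run_pca(z)
  proj <- project_component(pca, 1)
  # axis projection: score = Z . loading
  expect_equal(proj$score,
               as.numeric(as.matrix(z[, -1]) %*% pca$loadings[, 1]))
  # flipping the sign reverses the order exactly
  flipped <- pca
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$scores[["PC1"]] <- -flipped$scores[["PC1"]]
  p2 <- project_component(flipped, 1)
  expect_equal(order(-p2$score), rev(order(-proj$score)))
  expect_error(project_component(pca, 5), "component")
})

test_that("row centering zeroes every row and applies the sort order", {
  z <- tibble::tibble(individual_id = c("a", "b"),
                      A = c(1, 2), B = c(1, 0), C = c(1, 0), D = c(1, 0))
  hm <- center_rows(z)
  expect_equal(unlist(hm[1, -1], use.names = FALSE), rep(0, 4))
  expect_equal(unlist(hm[2, -1], use.names = FALSE),
               c(1.5, -0.5, -0.5, -0.5))
  expect_equal(rowSums(as.matrix(hm[, -1])), c(0, 0), tolerance = 1e-10)
  ordered <- center_rows(z, order = c("b", "a"))
  expect_equal(ordered$individual_id, c("b", "a"))
  expect_error(center_rows(z, order = c("b", "x")), "permutation")
})

test_that("VCF dosages respect the risk-allele complement rule", {
  co <- simulate_cohort(6, list(X = c("rsx01", "rsx02")), base_freq = 0.5,
                        seed = 2)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(co, path)
  # risk = ALT: dosage equals ALT count (round trip checked elsewhere);
  # risk = REF: dosage complements
  info_ref <- co$snp_info
  info_ref$risk_allele <- info_ref$ref
  flipped <- load_cohort_vcf(path, info_ref)
  straight <- load_cohort_vcf(path, co$snp_info)
  for (s in co$snp_info$snp_id) {
    expect_equal(flipped[[s]], 2 - straight[[s]])
  }
  # risk allele matching neither REF nor ALT errors
  info_bad <- co$snp_info
  bases <- c("A", "C", "G", "T")
  info_bad$risk_allele[1] <- setdiff(bases, c(info_bad$ref[1],
                                              info_bad$alt[1]))[1]
  expect_error(load_cohort_vcf(path, info_bad), "neither REF nor ALT")
  # missing genotypes become NA and are imputed at counting time
  lines <- readLines(path)
  lines[length(lines)] <- sub("\t[01]/[01]$", "\t./.",
                              lines[length(lines)])
  writeLines(lines, path)
  with_na <- load_cohort_vcf(path, co$snp_info)
  expect_true(anyNA(with_na[[co$snp_info$snp_id[2]]]))
  cc <- count_risk_alleles(with_na, list(X = co$snp_info$snp_id))
  expect_false(anyNA(cc$X))
})

test_that("the scoring pipeline is deterministic end to end", {
  co <- simulate_cohort(40, n_snps_per_cluster = 4, seed = 14)
  cl <- split(co$snp_info$snp_id, co$snp_info$cluster)
  a <- oligogenic_scores(co$genotypes, cl)
  b <- oligogenic_scores(co$genotypes, cl)
  expect_identical(a$heatmap, b$heatmap)
  expect_identical(a$pca$loadings, b$pca$loadings)
})
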