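# Oligogenic risk scoring: per-cluster risk-allele counts, standardization,
# PCA, projection ordering, and the row-centered heatmap matrix.

#' Tabulate risk-allele counts per individual per phenotype cluster
#'
#' For each phenotype cluster, sums the risk-allele dosage (0/1/2) of the
#' cluster's SNPs for every individual. Missing dosages are imputed with the
#' per-SNP mean dosage over non-missing individuals (strict mode errors on
#' any missingness instead); a per-SNP missingness report is attached.
#' Carrier mode counts a SNP once per individual when at least one risk
#' allele is present.
#'
#' @param genotypes A `cohort_genotypes` tibble: `individual_id` plus one
#'   dosage column per SNP (integers 0/1/2 or `NA`).
#' @param cluster_snps Named list of SNP-id vectors per cluster (see
#'   [assign_snp_clusters()]); every SNP must be present in `genotypes`.
#' @param missing `"impute_mean"` (default) or `"strict"`.
#' @param mode `"dosage"` (default) or `"carrier"`.
#' @return Tibble `individual_id` + one count column per cluster, with
#'   attribute `missingness` (per-SNP missing fraction).
#' @export
count_risk_alleles <- function(genotypes, cluster_snps,
                               missing = c("impute_mean", "strict"),
                               mode = c("dosage", "carrier")) {
  missing <- match.arg(missing)
  mode <- match.arg(mode)
  assert_cols(genotypes, "individual_id", "genotypes")
  cluster_snps <- cluster_snps[lengths(cluster_snps) > 0]
  snps <- unique(unlist(cluster_snps))
  absent <- setdiff(snps, names(genotypes))
  if (length(absent)) {
    abort(sprintf("cluster SNP(s) absent from genotypes: %s",
                  paste(absent, collapse = ", ")))
  }
  M <- as.matrix(genotypes[, snps, drop = FALSE])
  storage.mode(M) <- "double"
  rng <- range(M, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2 ||
      any(M[!is.na(M)] != floor(M[!is.na(M)]))) {
    abort("dosages must be integers in {0, 1, 2}.")
  }
  miss_frac <- colMeans(is.na(M))
  if (any(miss_frac > 0)) {
    if (missing == "strict") {
      abort(sprintf("missing genotypes at SNP(s): %s",
                    paste(snps[miss_frac > 0], collapse = ", ")))
    }
    for (j in which(miss_frac > 0)) {
      M[is.na(M[, j]), j] <- mean(M[, j], na.rm = TRUE)
    }
  }
  if (mode == "carrier") M <- (M > 0) * 1
  counts <- purrr::imap(cluster_snps, function(cl_snps, cl) {
    rowSums(M[, cl_snps, drop = FALSE])
  })
  out <- tibble(individual_id = genotypes$individual_id, !!!counts)
  attr(out, "missingness") <- tibble(snp_id = snps,
                                     missing_frac = unname(miss_frac))
  out
}

#' Standardize cluster score columns to z-scores
#'
#' Subtracts each cluster's mean risk-allele count and divides by its
#' standard deviation (sample SD, n-1 denominator, by default). A
#' zero-variance cluster is an error naming the degenerate column.
#'
#' @param counts Output of [count_risk_alleles()].
#' @param denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return Tibble of the same shape with standardized columns.
#' @export
standardize_scores <- function(counts, denominator = c("sample",
                                                       "population")) {
  denominator <- match.arg(denominator)
  assert_cols(counts, "individual_id", "counts")
  if (nrow(counts) < 2) abort("need >= 2 individuals to standardize.")
  num_cols <- setdiff(names(counts), "individual_id")
  out <- counts
  for (cl in num_cols) {
    x <- counts[[cl]]
    s <- sd(x)
    if (denominator == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (!is.finite(s) || s == 0) {
      abort(sprintf("cluster '%s' has zero variance; cannot standardize.", cl))
    }
    out[[cl]] <- (x - mean(x)) / s
  }
  out
}

#' Principal component analysis of standardized cluster scores
#'
#' Eigen-decomposes the covariance of the standardized score matrix (via
#' `prcomp`), orders components by decreasing eigenvalue, and applies a
#' deterministic sign convention: each loading vector is flipped so its ERG
#' entry (first cluster column otherwise) is non-negative, with ties broken
#' by the next cluster. Rank-deficient input yields trailing zero
#' eigenvalues rather than an error.
#'
#' @param z Output of [standardize_scores()] (or any individuals x clusters
#'   tibble with an `individual_id` column).
#' @return Object of class `risk_pca`: list with `loadings` (clusters x
#'   components), `variance_explained`, `scores` (individuals x components
#'   tibble), `clusters`.
#' @export
run_pca <- function(z) {
  assert_cols(z, "individual_id", "z")
  clusters <- setdiff(names(z), "individual_id")
  Z <- as.matrix(z[, clusters, drop = FALSE])
  if (nrow(Z) <= length(clusters)) {
    abort("need more individuals than clusters for PCA.")
  }
  if (any(!is.finite(Z))) abort("standardized scores must be finite.")
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  ev <- pc$sdev^2
  # deterministic eigensign: first (preferably ERG) loading >= 0
  ref_rows <- order(match(clusters, c("ERG", "Structure", "Bang", "Heat"),
                          nomatch = length(clusters) + 1L))
  for (j in seq_len(ncol(load))) {
    for (i in ref_rows) {
      v <- load[i, j]
      if (abs(v) > 1e-12) {
        if (v < 0) load[, j] <- -load[, j]
        break
      }
    }
  }
  scores <- Z %*% load
  structure(list(
    loadings = load,
    variance_explained = ev / sum(ev),
    scores = tibble(individual_id = z$individual_id) |>
      bind_cols(as_tibble(scores)),
    clusters = clusters), class = "risk_pca")
}

#' @export
print.risk_pca <- function(x, ...) {
  cat("<risk_pca>", length(x$clusters), "clusters;",
      "variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Project individuals onto a principal component and derive a sort order
#'
#' Scores are the product of the standardized matrix with the chosen
#' component's loading vector. The sort order is decreasing in score with
#' ties broken by individual id (stable).
#'
#' @param pca A `risk_pca` from [run_pca()].
#' @param component Component index (default 2, the component observed to
#'   separate phenotype-cluster score profiles in the study this models).
#' @return Tibble `individual_id`, `score`, `rank`.
#' @export
project_component <- function(pca, component = 2) {
  stopifnot(inherits(pca, "risk_pca"))
  k <- ncol(pca$loadings)
  if (component < 1 || component > k) {
    abort(sprintf("component must be in 1..%d.", k))
  }
  sc <- pca$scores[[paste0("PC", component)]]
  ids <- pca$scores$individual_id
  ord <- order(-sc, ids)
  tibble(individual_id = ids, score = sc,
         rank = match(seq_along(ids), ord))
}

#' Report which component best separates given subgroup labels
#'
#' Computes the point-biserial correlation between each component's
#' projection and a binary subgroup label, returning per-component |r|.
#'
#' @param pca A `risk_pca`.
#' @param subgroups Tibble `individual_id`, `subgroup` (two levels).
#' @return Tibble `component`, `r`, `abs_r`, sorted by `abs_r` descending.
#' @export
component_separation <- function(pca, subgroups) {
  stopifnot(inherits(pca, "risk_pca"))
  assert_cols(subgroups, c("individual_id", "subgroup"), "subgroups")
  lab <- subgroups$subgroup[match(pca$scores$individual_id,
                                  subgroups$individual_id)]
  lv <- unique(lab)
  if (length(lv) != 2) abort("`subgroups` must have exactly two levels.")
  y <- as.numeric(lab == lv[1])
  purrr::map(seq_along(pca$clusters), function(j) {
    r <- suppressWarnings(cor(pca$scores[[paste0("PC", j)]], y))
    tibble(component = j, r = r, abs_r = abs(r))
  }) |> purrr::list_rbind() |> arrange(dplyr::desc(.data$abs_r))
}

#' Row-center standardized scores and order rows for heatmap rendering
#'
#' Subtracts each individual's own mean standardized score from their row
#' (so every row sums to zero) and permutes rows into the supplied order
#' (typically the projection sort from [project_component()]).
#'
#' @param z Standardized score tibble.
#' @param order Tibble with `individual_id` and `rank` (as returned by
#'   [project_component()]), or a character vector of individual ids in the
#'   desired order.
#' @return Tibble of row-centered scores in heatmap row order.
#' @export
center_rows <- function(z, order = NULL) {
  assert_cols(z, "individual_id", "z")
  clusters <- setdiff(names(z), "individual_id")
  M <- as.matrix(z[, clusters, drop = FALSE])
  M <- M - rowMeans(M)
  out <- tibble(individual_id = z$individual_id) |>
    bind_cols(as_tibble(M))
  if (!is.null(order)) {
    ids <- if (is.data.frame(order)) {
      assert_cols(order, c("individual_id", "rank"), "order")
      order$individual_id[base::order(order$rank)]
    } else {
      order
    }
    if (!setequal(ids, out$individual_id) ||
        length(ids) != nrow(out)) {
      abort("`order` must be a permutation of the individual ids.")
    }
    out <- out[match(ids, out$individual_id), ]
  }
  out
}

#' Load cohort genotypes from a biallelic VCF
#'
#' Reads GT fields from a VCF (v4.2) and converts them to risk-allele
#' dosages: the ALT count when the risk allele is ALT, `2 - ALT count` when
#' it is REF. Multiallelic records used by a cluster and risk alleles
#' matching neither REF nor ALT are errors; missing genotypes (`./.`) are
#' recorded as `NA` in the dosage table (imputed later at counting time).
#'
#' @param path VCF file path.
#' @param snp_info Tibble with `snp_id` and `risk_allele` for the SNPs to
#'   load (others are ignored).
#' @return A `cohort_genotypes` tibble (`individual_id` + dosage columns).
#' @export
load_cohort_vcf <- function(path, snp_info) {
  assert_cols(snp_info, c("snp_id", "risk_allele"), "snp_info")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- fix$ID %in% snp_info$snp_id
  if (!any(keep)) abort("none of the requested SNPs found in the VCF.")
  absent <- setdiff(snp_info$snp_id, fix$ID)
  if (length(absent)) {
    abort(sprintf("SNP(s) missing from VCF: %s",
                  paste(absent, collapse = ", ")))
  }
  multi <- keep & grepl(",", fix$ALT)
  if (any(multi)) {
    abort(sprintf("multiallelic record(s) for: %s",
                  paste(fix$ID[multi], collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  dosages <- purrr::map(which(keep), function(i) {
    ra <- snp_info$risk_allele[match(fix$ID[i], snp_info$snp_id)]
    if (!ra %in% c(fix$REF[i], fix$ALT[i])) {
      abort(sprintf("risk allele '%s' at %s matches neither REF nor ALT.",
                    ra, fix$ID[i]))
    }
    g <- gt[i, ]
    alt_count <- stringr::str_count(g, "1")
    alt_count[is.na(g) | grepl("\\.", g)] <- NA_integer_
    if (ra == fix$ALT[i]) alt_count else 2L - alt_count
  })
  names(dosages) <- fix$ID[keep]
  out <- tibble(individual_id = ids, !!!dosages)
  class(out) <- c("cohort_genotypes", class(out))
  out
}

#' End-to-end oligogenic risk scoring
#'
#' Convenience wrapper: counts risk alleles per cluster, standardizes, runs
#' PCA, projects onto the chosen component, and builds the row-centered
#' heatmap matrix.
#'
#' @inheritParams count_risk_alleles
#' @param component Component used for the sort order.
#' @param subgroups Optional subgroup labels; if given, the per-component
#'   separation report is included.
#' @return List with `counts`, `z`, `pca`, `projection`, `heatmap`, and
#'   optionally `separation`.
#' @export
oligogenic_scores <- function(genotypes, cluster_snps, component = 2,
                              missing = "impute_mean", mode = "dosage",
                              subgroups = NULL) {
  counts <- count_risk_alleles(genotypes, cluster_snps, missing, mode)
  z <- standardize_scores(counts)
  pca <- run_pca(z)
  proj <- project_component(pca, component)
  hm <- center_rows(z, proj)
  out <- list(counts = counts, z = z, pca = pca, projection = proj,
              heatmap = hm)
  if (!is.null(subgroups)) {
    out$separation <- component_separation(pca, subgroups)
  }
  out
}
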