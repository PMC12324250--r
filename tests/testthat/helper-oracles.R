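# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# All permutations of 1..n as a list of index vectors.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- combinat_perms(n - 1)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

# Brute-force step-down adjustment straight from the definition.
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Exact two-group permutation test on the difference of group mean ranks
# (two-sided). Enumerates all assignments of the pooled sample.
perm_rank_test <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- abs(mean(r[seq_along(x)]) - mean(r[-seq_along(x)]))
  idx <- utils::combn(n, length(x))
  stats <- apply(idx, 2, function(ii) {
    abs(mean(r[ii]) - mean(r[-ii]))
  })
  mean(stats >= obs - 1e-12)
}

# Dunn z for two chosen groups, recomputed from scratch (mid-ranks via
# explicit sorting, tie correction from the tabulated values).
brute_dunn_z <- function(values, groups, g1, g2) {
  n <- length(values)
  ord <- order(values)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1]] == values[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  tie <- table(values)
  sigma2 <- n * (n + 1) / 12 - sum(tie^3 - tie) / (12 * (n - 1))
  m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (m1 - m2) / sqrt(sigma2 * (1 / n1 + 1 / n2))
}

# Brute-force PCA of a score matrix via eigen() on the covariance.
brute_pca <- function(Z) {
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  e <- eigen(stats::cov(Zc), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

null_erg_batch <- function(n_flies = 5, noise_sd = 0.5, plateau = -10) {
  purrr::map(seq_len(2 * n_flies), function(i) {
    simulate_erg_trace(plateau_mv = plateau, noise_sd = noise_sd)
  })
}

# Per-fly features for one genotype, one trace per fly (keeps null
# simulations cheap while exercising the real trace pipeline).
fly_features <- function(genotype, n_flies, plateau, on = 3, off = 4,
                         noise_sd = 0.5, eye = "white") {
  purrr::map(seq_len(n_flies), function(f) {
    tr <- simulate_erg_trace(plateau_mv = plateau, on_mv = on, off_mv = off,
                             noise_sd = noise_sd)
    extract_erg_features(tr) |>
      dplyr::mutate(genotype = genotype, fly_id = f, eye_color = eye,
                    .before = 1)
  }) |> purrr::list_rbind()
}
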