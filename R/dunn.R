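#' Kruskal-Wallis test with Dunn's post-hoc comparisons against a control
#'
#' Runs the non-parametric one-way ANOVA (Kruskal-Wallis, tie-corrected)
#' across all groups, then Dunn's z tests of each non-control group against
#' the control, using mid-ranks of the pooled sample and the tie-corrected
#' rank variance. Two-sided p-values are adjusted across the control
#' comparisons with the step-down Holm procedure by default (Bonferroni
#' available).
#'
#' The Dunn z statistic for groups i, j is
#' `(Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`,
#' where `T = sum(t^3 - t)` over tie groups. When all observations are tied
#' the rank variance is zero; the comparison is flagged degenerate and
#' reported with z = 0, p = 1.
#'
#' @param data Data frame with one row per observation.
#' @param value,group Column names (strings) of the measurement and the group
#'   label.
#' @param control Group label used as the reference; all other groups are
#'   compared against it.
#' @param p_adjust `"holm"` or `"bonferroni"`.
#' @return A list with `omnibus` (the `kruskal.test` result) and
#'   `comparisons`, a tibble with columns `group`, `n`, `mean_value`,
#'   `direction` (sign of group mean minus control mean), `z`, `p_value`,
#'   `p_adjusted`, `degenerate`.
#' @export
#' @examples
#' d <- data.frame(g = rep(c("ctrl", "mut"), each = 5),
#'                 y = c(5, 6, 5, 6, 5, 50, 51, 50, 51, 50))
#' dunn_vs_control(d, "y", "g", control = "ctrl")$comparisons
dunn_vs_control <- function(data, value, group, control,
                            p_adjust = c("holm", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  assert_cols(data, c(value, group), "data")
  y <- data[[value]]
  g <- as.character(data[[group]])
  if (!control %in% g) abort(sprintf("control group '%s' not found.", control))
  groups <- unique(g)
  if (length(groups) < 2) abort("need at least 2 groups including control.")
  n_per <- table(g)
  if (any(n_per < 2)) abort("need >= 2 replicates per group.")

  N <- length(y)
  r <- rank(y)  # mid-ranks
  ties <- table(y)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  mu <- tapply(y, g, mean)

  omnibus <- if (sigma2 > 0) kruskal.test(y, factor(g)) else NULL

  others <- setdiff(groups, control)
  z <- if (sigma2 > 0) {
    as.numeric((rbar[others] - rbar[[control]]) /
                 sqrt(sigma2 * (1 / n_per[others] + 1 / n_per[[control]])))
  } else {
    rep(0, length(others))
  }
  cmp <- tibble(
    group = others,
    n = as.integer(n_per[others]),
    mean_value = as.numeric(mu[others]),
    direction = sign(as.numeric(mu[others]) - mu[[control]]),
    degenerate = sigma2 <= 0,
    z = z,
    p_value = if (sigma2 > 0) 2 * pnorm(-abs(z)) else rep(1, length(others)))
  cmp$p_adjusted <- holm_adjust(cmp$p_value, method = p_adjust)
  list(omnibus = omnibus, comparisons = cmp)
}

#' Step-down Holm adjustment of p-values
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotone non-decreasing adjusted values, caps at 1,
#' and restores the original order. With `method = "bonferroni"` every
#' p-value is multiplied by `m` instead.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"holm"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_adjust <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, p * m))
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}
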