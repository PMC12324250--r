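# broom-style tidiers for fitted objects.

#' Tidy a longitudinal climbing fit
#'
#' @param x A `fly_lmm` from [fit_longitudinal()].
#' @param ... Unused.
#' @return Tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std_error`.
#' @export
tidy.fly_lmm <- function(x, ...) {
  beta <- coef_fixed(x)
  se <- if (x$engine == "lmer") {
    sqrt(diag(as.matrix(stats::vcov(x$model))))
  } else {
    # a perfect (noiseless) fit makes summary.lm warn; its zero SEs are fine
    suppressWarnings(sqrt(diag(stats::vcov(x$model))))
  }
  tibble(term = names(beta), estimate = unname(beta), std_error = unname(se))
}

#' Glance at a longitudinal climbing fit
#'
#' @param x A `fly_lmm`.
#' @param ... Unused.
#' @return One-row tibble: `engine`, `basis`, `sigma`, `n_obs`, `n_vials`.
#' @export
glance.fly_lmm <- function(x, ...) {
  tibble(engine = x$engine, basis = x$basis,
         sigma = stats::sigma(x$model),
         n_obs = nrow(x$data),
         n_vials = dplyr::n_distinct(x$data$vial_id))
}

#' Tidy a risk-score PCA
#'
#' @param x A `risk_pca` from [run_pca()].
#' @param ... Unused.
#' @return Tibble with one row per cluster x component: `cluster`,
#'   `component`, `loading`.
#' @export
tidy.risk_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "component",
                        values_to = "loading") |>
    mutate(component = as.integer(sub("PC", "", .data$component)))
}

#' Glance at a risk-score PCA
#'
#' @param x A `risk_pca`.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`,
#'   `variance_explained`.
#' @export
glance.risk_pca <- function(x, ...) {
  tibble(component = seq_along(x$variance_explained),
         variance_explained = x$variance_explained)
}
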