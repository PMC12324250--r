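# Longitudinal locomotor modifier analysis: mixed-effects fits of climbing
# speed over age, nested effect tests, Holm adjustment, area between curves,
# and strain -> gene consolidation.

climb_basis <- function(basis = c("quadratic", "linear", "log")) {
  match.arg(basis)
}

basis_terms <- function(basis) {
  switch(basis,
         quadratic = c("age_c", "age_c2"),
         linear = "age_c",
         log = "age_l")
}

add_basis_cols <- function(data, basis) {
  a0 <- min(data$age_days)
  data$age_c <- data$age_days - a0
  data$age_c2 <- data$age_c^2
  data$age_l <- log1p(data$age_c)
  data
}

#' Fit the longitudinal climbing model for one strain vs its disease control
#'
#' Models the mean climbing speed per vial and timepoint as a polynomial in
#' age (quadratic by default, the package's choice of curve for the
#' "nonlinear" decline; linear and log-age available), a genotype indicator
#' (the curve shift, i.e. additive effect), genotype-by-age interaction
#' terms (the slope change, i.e. interactive effect), and a random intercept
#' per vial. Estimation uses REML via `lmer`; when the fit degenerates
#' (zero residual variance, as in noiseless oracles, or convergence
#' failure) the model falls back to ordinary least squares, recorded in the
#' result.
#'
#' @param data Tibble with columns `genotype`, `vial_id`, `age_days`,
#'   `mean_speed` for exactly two genotypes sharing >= 3 timepoints.
#' @param control Genotype name of the disease control (reference level).
#' @param basis `"quadratic"`, `"linear"` or `"log"` age basis.
#' @return Object of class `fly_lmm`: list with the fitted model, data,
#'   term bookkeeping, and `engine` ("lmer" or "lm").
#' @export
fit_longitudinal <- function(data, control, basis = "quadratic") {
  basis <- climb_basis(basis)
  assert_cols(data, c("genotype", "vial_id", "age_days", "mean_speed"),
              "data")
  genos <- unique(data$genotype)
  if (length(genos) != 2 || !control %in% genos) {
    abort("`data` must contain exactly two genotypes including `control`.")
  }
  shared_ages <- intersect(data$age_days[data$genotype == control],
                           data$age_days[data$genotype != control])
  if (length(unique(shared_ages)) < 3) {
    abort("need >= 3 shared timepoints across genotypes.")
  }
  vials_per_geno <- rowSums(table(data$genotype, data$vial_id) > 0)
  if (min(vials_per_geno) < 2) {
    abort("need >= 2 vials per genotype.")
  }
  data <- add_basis_cols(data, basis)
  data$genotype <- stats::relevel(factor(data$genotype), ref = control)
  bt <- basis_terms(basis)
  fml <- stats::as.formula(paste(
    "mean_speed ~", paste(bt, collapse = " + "),
    "+ genotype +", paste(paste0("genotype:", bt), collapse = " + ")))
  fixed_only <- fml
  fml_re <- stats::update(fml, . ~ . + (1 | vial_id))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(fml_re, data = data, REML = TRUE))),
    error = function(e) NULL)
  engine <- "lmer"
  if (is.null(fit) || stats::sigma(fit) < 1e-8) {
    fit <- lm(fixed_only, data = data)
    engine <- "lm"
  }
  structure(list(model = fit, data = data, basis = basis, control = control,
                 test_genotype = setdiff(as.character(genos), control),
                 formula = fml, engine = engine),
            class = "fly_lmm")
}

#' @export
print.fly_lmm <- function(x, ...) {
  cat("<fly_lmm>", x$test_genotype, "vs", x$control,
      sprintf("(%s basis, %s fit)\n", x$basis, x$engine))
  print(coef_fixed(x))
  invisible(x)
}

coef_fixed <- function(fit) {
  if (fit$engine == "lmer") lme4::fixef(fit$model) else coef(fit$model)
}

genotype_term_groups <- function(fit) {
  cn <- names(coef_fixed(fit))
  main <- grep("^genotype[^:]*$", cn)
  inter <- grep(":", cn)[grepl("genotype", grep(":", cn, value = TRUE))]
  list(genotype = c(main, inter), additive = main, interactive = inter)
}

#' Test the genotype, additive and interactive effects of a climbing fit
#'
#' Returns p-values for dropping (a) every genotype term (overall genotype
#' effect), (b) the genotype shift alone (additive effect: a vertical shift
#' of the decline curve), and (c) the genotype-by-age interaction terms
#' (interactive effect: a change in the curve's slope). For mixed fits the
#' tests are joint F tests with Satterthwaite denominator degrees of
#' freedom; for the least-squares fallback they are exact F tests. A fit
#' with (numerically) zero residual variance reports p = 0 for effects with
#' non-zero coefficients, p = 1 otherwise.
#'
#' @param fit A `fly_lmm` from [fit_longitudinal()].
#' @param ddf Denominator degrees-of-freedom method for mixed fits:
#'   `"Kenward-Roger"` (default; better calibrated for joint tests with few
#'   vials) or `"Satterthwaite"` (faster).
#' @return Tibble with columns `effect`, `statistic`, `df`, `p_value`.
#' @export
test_effects <- function(fit, ddf = c("Kenward-Roger", "Satterthwaite")) {
  ddf <- match.arg(ddf)
  stopifnot(inherits(fit, "fly_lmm"))
  groups <- genotype_term_groups(fit)
  beta <- coef_fixed(fit)
  p_ncoef <- length(beta)
  resid_sd <- stats::sigma(fit$model)
  one <- function(idx, name) {
    if (resid_sd < 1e-10) {
      p <- if (max(abs(beta[idx])) < 1e-8) 1 else 0
      return(tibble(effect = name, statistic = NA_real_,
                    df = length(idx), p_value = p))
    }
    if (fit$engine == "lmer") {
      L <- diag(p_ncoef)[idx, , drop = FALSE]
      ct <- lmerTest::contest(fit$model, L, joint = TRUE, ddf = ddf)
      tibble(effect = name, statistic = ct[["F value"]],
             df = ct[["NumDF"]], p_value = ct[["Pr(>F)"]])
    } else {
      X <- stats::model.matrix(fit$model)
      reduced <- lm(fit$data$mean_speed ~ X[, -idx, drop = FALSE] - 1)
      a <- anova(reduced, fit$model)
      tibble(effect = name, statistic = a$F[2], df = a$Df[2],
             p_value = a$`Pr(>F)`[2])
    }
  }
  bind_rows(one(groups$genotype, "genotype"),
            one(groups$additive, "additive"),
            one(groups$interactive, "interactive"))
}

#' Area between two fitted speed-over-age curves
#'
#' Trapezoidal integral of `test - control` over the shared age span, in
#' mm/s x day. Positive values mean the test strain climbs faster than the
#' disease control (suppressor direction); negative values mean worse
#' climbing (enhancer direction). Antisymmetric in its curve arguments and
#' exact for piecewise-linear curves under grid refinement.
#'
#' @param age Shared, increasing age grid (days).
#' @param test,control Curve values (mm/s) on `age`.
#' @return Signed scalar (mm/s x day).
#' @export
#' @examples
#' area_between_curves(c(5, 18), c(8, 1.5), c(10, 3.5))  # constant -2 -> -26
area_between_curves <- function(age, test, control) {
  if (length(age) < 2 || is.unsorted(age, strictly = TRUE)) {
    abort("`age` must be an increasing grid of length >= 2.")
  }
  if (length(test) != length(age) || length(control) != length(age)) {
    abort("curves must be evaluated on the shared `age` grid.")
  }
  d <- test - control
  sum(diff(age) * (head(d, -1) + d[-1]) / 2)
}

#' Fitted mean curves and area between curves for a climbing fit
#'
#' Evaluates the fixed-effect mean curve of each genotype on the observed
#' age grid and integrates their difference (test minus disease control).
#'
#' @param fit A `fly_lmm`.
#' @return List with `grid` (tibble of fitted means) and `area`.
#' @export
fitted_curves <- function(fit) {
  stopifnot(inherits(fit, "fly_lmm"))
  ages <- sort(unique(fit$data$age_days))
  newd <- tidyr::expand_grid(
    genotype = factor(c(fit$control, fit$test_genotype),
                      levels = levels(fit$data$genotype)),
    age_days = ages) |>
    add_basis_cols(fit$basis)
  pred <- if (fit$engine == "lmer") {
    stats::predict(fit$model, newdata = newd, re.form = NA)
  } else {
    stats::predict(fit$model, newdata = newd)
  }
  grid <- newd |> mutate(speed = pred) |>
    select("genotype", "age_days", "speed")
  wide <- grid |> tidyr::pivot_wider(names_from = "genotype",
                                     values_from = "speed")
  area <- area_between_curves(wide$age_days, wide[[fit$test_genotype]],
                              wide[[fit$control]])
  list(grid = grid, area = area)
}

#' Analyze one strain: fit, effect tests, Holm adjustment, area, call
#'
#' Runs the whole per-strain analysis: longitudinal fit, the three nested
#' effect tests with step-down Holm adjustment (the per-strain family),
#' area between the fitted curves, and the enhancer/suppressor call.
#'
#' @inheritParams fit_longitudinal
#' @inheritParams classify_strain
#' @return One-row tibble: `strain`, raw and adjusted p-values, `area`,
#'   `call`, `engine`.
#' @export
analyze_strain <- function(data, control, basis = "quadratic", alpha = 0.05,
                           min_area = NULL, gate = c("any", "interaction"),
                           ddf = "Kenward-Roger") {
  fit <- fit_longitudinal(data, control, basis)
  tests <- test_effects(fit, ddf = ddf)
  tests$p_adjusted <- holm_adjust(tests$p_value)
  fc <- fitted_curves(fit)
  if (is.null(min_area)) {
    ctrl_curve <- fc$grid |> filter(.data$genotype == control)
    min_area <- 0.1 * abs(area_between_curves(
      ctrl_curve$age_days, ctrl_curve$speed, rep(0, nrow(ctrl_curve))))
  }
  call <- classify_strain(tests, fc$area, alpha = alpha, min_area = min_area,
                          gate = gate)
  tibble(strain = fit$test_genotype,
         p_genotype = tests$p_value[1], p_additive = tests$p_value[2],
         p_interactive = tests$p_value[3],
         p_genotype_adj = tests$p_adjusted[1],
         p_additive_adj = tests$p_adjusted[2],
         p_interactive_adj = tests$p_adjusted[3],
         area = fc$area, call = call, engine = fit$engine)
}

#' Classify a strain as enhancer, suppressor or none
#'
#' A strain is a modifier when at least one Holm-adjusted effect p-value is
#' below `alpha` (configurable to interaction-only) and the absolute area
#' between curves clears `min_area` - the codified stand-in for the study's
#' visual plausibility check. Direction follows the sign of the area:
#' negative (worse climbing than the disease control) is an enhancer,
#' positive a suppressor.
#'
#' @param tests Output of [test_effects()] with a `p_adjusted` column.
#' @param area Signed area between curves (mm/s x day).
#' @param alpha Significance level.
#' @param min_area Minimum absolute area for a call (mm/s x day).
#' @param gate `"any"`: any of the three adjusted p-values may gate the
#'   call; `"interaction"`: only the interactive effect.
#' @return `"enhancer"`, `"suppressor"` or `"none"`.
#' @export
classify_strain <- function(tests, area, alpha = 0.05, min_area = 0,
                            gate = c("any", "interaction")) {
  gate <- match.arg(gate)
  assert_cols(tests, c("effect", "p_adjusted"), "tests")
  ps <- if (gate == "any") tests$p_adjusted else
    tests$p_adjusted[tests$effect == "interactive"]
  if (!any(ps < alpha) || abs(area) < min_area) return("none")
  if (area < 0) "enhancer" else "suppressor"
}

#' Consolidate strain-level calls into a gene-level modifier call
#'
#' A gene is a high-confidence modifier when at least `min_strains`
#' independent strains are called with the same direction; strains called in
#' conflicting directions block high confidence and set a flag.
#'
#' @param strain_calls Tibble with columns `gene`, `strain`, `call`
#'   (`"enhancer"`, `"suppressor"`, `"none"`).
#' @param min_strains Minimum consistent strains (default 2).
#' @return Tibble per gene: `high_confidence`, `direction`, `n_support`,
#'   `conflict`.
#' @export
consolidate_gene <- function(strain_calls, min_strains = 2) {
  assert_cols(strain_calls, c("gene", "strain", "call"), "strain_calls")
  strain_calls |>
    summarise(
      n_enh = sum(.data$call == "enhancer"),
      n_sup = sum(.data$call == "suppressor"),
      .by = "gene") |>
    mutate(
      conflict = .data$n_enh > 0 & .data$n_sup > 0,
      n_support = pmax(.data$n_enh, .data$n_sup),
      direction = dplyr::case_when(
        conflict ~ "conflict",
        n_enh > 0 ~ "enhancer",
        n_sup > 0 ~ "suppressor",
        TRUE ~ "none"),
      high_confidence = !.data$conflict & .data$n_support >= min_strains) |>
    select("gene", "high_confidence", "direction", "n_support", "conflict")
}

#' Monte-Carlo power of the climbing modifier analysis
#'
#' Simulates climbing experiments with the given effect, analyzes each with
#' [analyze_strain()], and reports the fraction with some Holm-adjusted
#' p-value below `alpha`, with its binomial standard error.
#'
#' @param shift,slope Effect sizes (mm/s shift; mm/s/day slope change).
#' @param n_vials Vials per genotype.
#' @param ages Assessment age grid.
#' @param n_sims Simulated experiments (>= 100).
#' @param alpha Significance level.
#' @param noise_sd,vial_sd Residual and vial-intercept SDs.
#' @param basis Age basis for the fitted model.
#' @param seed Integer seed.
#' @return One-row tibble: `power`, `se`, `n_sims`.
#' @export
estimate_power <- function(shift, slope = 0, n_vials = 4,
                           ages = seq(5, 18, length.out = 6), n_sims = 200,
                           alpha = 0.05, noise_sd = 0.5, vial_sd = 0.3,
                           basis = "quadratic", seed = 1L,
                           ddf = "Kenward-Roger") {
  if (n_sims < 100) abort("`n_sims` must be >= 100.")
  hits <- withr::with_seed(substream_seed(seed, "power"), {
    purrr::map_lgl(seq_len(n_sims), function(i) {
      d <- simulate_climbing_pair(ages, n_vials, shift = shift, slope = slope,
                                  vial_sd = vial_sd, noise_sd = noise_sd)
      fit <- fit_longitudinal(d, control = "control", basis = basis)
      tests <- test_effects(fit, ddf = ddf)
      any(holm_adjust(tests$p_value) < alpha)
    })
  })
  p <- mean(hits)
  tibble(power = p, se = sqrt(p * (1 - p) / n_sims), n_sims = n_sims)
}
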