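# Electroretinogram analysis: trace averaging, feature extraction, mutant vs
# eye-color-matched control comparison, gene-level classification.

#' Average replicate ERG traces from one fly
#'
#' Pointwise mean of the voltage traces recorded from a single fly (5 light
#' pulses in the standard protocol); the average serves as one biological
#' replicate. All traces must share the time grid and stimulus window.
#'
#' @param traces List of `erg_trace` objects.
#' @return One `erg_trace`.
#' @export
average_fly_traces <- function(traces) {
  if (length(traces) < 1) abort("need at least one trace.")
  ref <- traces[[1]]
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr$time_s, ref$time_s)) ||
        !identical(attr(tr, "stimulus_onset"), attr(ref, "stimulus_onset")) ||
        !identical(attr(tr, "stimulus_offset"), attr(ref, "stimulus_offset"))) {
      abort("traces have mismatched time grids or stimulus windows.")
    }
  }
  v <- rowMeans(do.call(cbind, purrr::map(traces, "voltage_mv")))
  new_erg_trace(tibble(time_s = ref$time_s, voltage_mv = v),
                attr(ref, "stimulus_onset"), attr(ref, "stimulus_offset"))
}

#' Feature-window configuration for ERG component extraction
#'
#' Window lengths in seconds, relative to the stimulus: baseline = mean over
#' `baseline_s` before onset, on transient searched over `on_s` after onset,
#' plateau = last `plateau_frac` of the stimulus, off transient searched over
#' `off_s` after offset. The protocol this models never states windows, so
#' they are explicit configuration.
#'
#' @param baseline_s,on_s,off_s Window lengths (s).
#' @param plateau_frac Fraction of the stimulus (from its end) used as the
#'   plateau window.
#' @param amplitude `"plateau_mean"` (default) or `"peak"`: how the
#'   light-coincident receptor potential amplitude is measured.
#' @return List of class `erg_windows`.
#' @export
erg_windows <- function(baseline_s = 0.2, on_s = 0.1, off_s = 0.2,
                        plateau_frac = 0.5,
                        amplitude = c("plateau_mean", "peak")) {
  amplitude <- match.arg(amplitude)
  stopifnot(baseline_s > 0, on_s > 0, off_s > 0,
            plateau_frac > 0, plateau_frac <= 1)
  structure(list(baseline_s = baseline_s, on_s = on_s, off_s = off_s,
                 plateau_frac = plateau_frac, amplitude = amplitude),
            class = "erg_windows")
}

#' Extract the three ERG components from a voltage trace
#'
#' Computes, relative to the pre-stimulus baseline (mean voltage over the
#' baseline window):
#' * `lcrp_amplitude` - magnitude of the sustained depolarization, i.e.
#'   `|mean plateau-window voltage - baseline|` (or the peak excursion if the
#'   window config selects `"peak"`);
#' * `on_transient` - maximal excursion beyond the plateau level, in the
#'   depolarizing direction, within the on window;
#' * `off_transient` - maximal excursion beyond baseline, opposite to the
#'   depolarizing direction, within the off window.
#'
#' All features are non-negative magnitudes and are invariant to adding a
#' constant voltage offset to the whole trace.
#'
#' @param trace An `erg_trace` (tibble with `time_s`, `voltage_mv` and
#'   stimulus attributes, as produced by [simulate_erg_trace()] or
#'   [read_erg_traces()]).
#' @param windows An [erg_windows()] configuration.
#' @return A one-row tibble with `lcrp_amplitude`, `on_transient`,
#'   `off_transient` (mV, >= 0).
#' @export
extract_erg_features <- function(trace, windows = erg_windows()) {
  onset <- attr(trace, "stimulus_onset")
  offset <- attr(trace, "stimulus_offset")
  if (is.null(onset) || is.null(offset)) {
    abort("trace lacks stimulus_onset/stimulus_offset attributes.")
  }
  t <- trace$time_s
  v <- trace$voltage_mv
  if (onset - windows$baseline_s < min(t) - 1e-9 ||
      offset + windows$off_s > max(t) + 1e-9) {
    abort("feature windows fall outside the trace span.")
  }
  sel <- function(from, to) t >= from - 1e-9 & t < to - 1e-9
  base_w <- sel(onset - windows$baseline_s, onset)
  stim_len <- offset - onset
  plat_w <- sel(offset - windows$plateau_frac * stim_len, offset)
  on_w <- sel(onset, onset + windows$on_s)
  off_w <- t >= offset - 1e-9 & t <= offset + windows$off_s + 1e-9
  if (!any(base_w) || !any(plat_w) || !any(on_w) || !any(off_w)) {
    abort("a feature window contains no samples.")
  }
  baseline <- mean(v[base_w])
  plat_mean <- mean(v[plat_w])
  s <- if (plat_mean - baseline > 0) 1 else -1  # depolarization direction
  amp <- if (windows$amplitude == "plateau_mean") {
    abs(plat_mean - baseline)
  } else {
    max(s * (v[plat_w] - baseline), 0)
  }
  plateau_level <- baseline + s * amp
  on_tr <- max(s * (v[on_w] - plateau_level), 0)
  off_tr <- max(-s * (v[off_w] - baseline), 0)
  tibble(lcrp_amplitude = amp, on_transient = on_tr, off_transient = off_tr)
}

#' Extract per-fly ERG features for a whole trace table
#'
#' Averages the traces of each fly ([average_fly_traces()]) and extracts the
#' three components from the per-fly average, yielding one biological
#' replicate per fly.
#'
#' @param traces Long tibble with columns `genotype`, `fly_id`, `trace_id`,
#'   `time_s`, `voltage_mv`, and optionally `eye_color`; plus stimulus
#'   window attributes or explicit `stimulus_onset`/`stimulus_offset`
#'   arguments.
#' @param stimulus_onset,stimulus_offset Stimulus window (s); defaults to
#'   the table's attributes when present.
#' @param windows An [erg_windows()] configuration.
#' @return Tibble with one row per genotype x fly: feature columns plus
#'   `eye_color` if supplied.
#' @export
erg_feature_table <- function(traces, stimulus_onset = NULL,
                              stimulus_offset = NULL,
                              windows = erg_windows()) {
  assert_cols(traces, c("genotype", "fly_id", "trace_id", "time_s",
                        "voltage_mv"), "traces")
  onset <- stimulus_onset %||% attr(traces, "stimulus_onset") %||% 0.2
  offset <- stimulus_offset %||% attr(traces, "stimulus_offset") %||% 0.7
  has_eye <- "eye_color" %in% names(traces)
  keys <- c("genotype", "fly_id", if (has_eye) "eye_color")
  traces |>
    summarise(voltage_mv = mean(.data$voltage_mv),
              .by = dplyr::all_of(c(keys, "time_s"))) |>
    tidyr::nest(.by = dplyr::all_of(keys), .key = "trace") |>
    mutate(feats = purrr::map(.data$trace, function(tr) {
      extract_erg_features(new_erg_trace(tr[order(tr$time_s), ],
                                         onset, offset), windows)
    })) |>
    select(-"trace") |>
    tidyr::unnest("feats")
}

#' Compare mutant ERG features to eye-color-matched controls
#'
#' For each ERG component, runs a Kruskal-Wallis test across the genotypes
#' that share an eye color (mutants plus their matched control) followed by
#' Dunn's z tests of each mutant against the control, with Holm (or
#' Bonferroni) adjustment over the mutant comparisons of that batch.
#' Matching is structural: a mutant is only ever compared with the control
#' genotype registered for its eye color, mirroring the protocol in which
#' each mutant is compared to controls with matching eye color.
#'
#' @param features Per-fly feature table from [erg_feature_table()]; must
#'   contain `genotype`, `eye_color` and the component columns.
#' @param controls Named character vector mapping eye color to its control
#'   genotype, e.g. `c(white = "erg_ctrl_w1", orange_red = "erg_ctrl_o1")`.
#' @param components Feature columns to test.
#' @param p_adjust Passed to [dunn_vs_control()].
#' @return Tibble with one row per genotype x component: `control_ratio`
#'   (mutant mean / control mean), `direction`, `p_value`, `p_adjusted`,
#'   `significant` (adjusted p < 0.05).
#' @export
compare_erg_genotypes <- function(features, controls,
                                  components = c("lcrp_amplitude",
                                                 "on_transient",
                                                 "off_transient"),
                                  p_adjust = "holm") {
  assert_cols(features, c("genotype", "eye_color", components), "features")
  if (is.null(names(controls)) || any(!nzchar(names(controls)))) {
    abort("`controls` must be a named vector keyed by eye color.")
  }
  eye_colors <- unique(features$eye_color[
    !features$genotype %in% unname(controls)])
  missing_ctrl <- setdiff(eye_colors, names(controls))
  if (length(missing_ctrl)) {
    abort(sprintf("no control registered for eye color(s): %s",
                  paste(missing_ctrl, collapse = ", ")))
  }
  out <- purrr::map(intersect(names(controls), unique(features$eye_color)),
                    function(ec) {
    ctrl <- controls[[ec]]
    batch <- features |>
      filter(.data$eye_color == ec,
             .data$genotype == ctrl | !.data$genotype %in% unname(controls))
    if (!ctrl %in% batch$genotype) {
      abort(sprintf("control '%s' has no rows with eye color '%s'.", ctrl, ec))
    }
    if (length(unique(batch$genotype)) < 2) return(NULL)
    purrr::map(components, function(comp) {
      res <- dunn_vs_control(batch, comp, "genotype", control = ctrl,
                             p_adjust = p_adjust)
      ctrl_mean <- mean(batch[[comp]][batch$genotype == ctrl])
      res$comparisons |>
        mutate(component = comp, eye_color = ec,
               control_genotype = ctrl,
               control_ratio = .data$mean_value / ctrl_mean,
               omnibus_p = res$omnibus$p.value %||% 1,
               significant = .data$p_adjusted < 0.05, .before = 1) |>
        rename(genotype = "group")
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out
}

#' Classify each gene's ERG phenotype from strain-level comparisons
#'
#' A component counts as significant for a gene if it is significant
#' (adjusted p < 0.05) in its genotype; for essential genes assayed with two
#' RNAi strains, the component must be significant in both strains with the
#' same direction. The gene class is then: `decreased` if all significant
#' components decreased, `increased` if all increased, `mixed` if both
#' directions occur, `none` if nothing is significant.
#'
#' @param comparisons Output of [compare_erg_genotypes()] augmented with a
#'   `gene` column (join on genotype).
#' @param genes Tibble with `gene` and `viability` columns; essential genes
#'   (`viability == "essential_rescuable"`) require both RNAi strains.
#' @return Tibble with one row per gene x component (significance, direction)
#'   nested in `components`, plus `erg_class`.
#' @export
classify_erg_gene <- function(comparisons, genes) {
  assert_cols(comparisons, c("gene", "genotype", "component", "direction",
                             "p_adjusted"), "comparisons")
  assert_cols(genes, c("gene", "viability"), "genes")
  ess <- genes$gene[genes$viability == "essential_rescuable"]
  n_strains <- comparisons |>
    distinct(.data$gene, .data$genotype) |>
    count(.data$gene, name = "n_strains")
  bad <- n_strains$gene[n_strains$gene %in% ess & n_strains$n_strains < 2]
  if (length(bad)) {
    abort(sprintf("essential gene(s) with < 2 RNAi strains: %s",
                  paste(bad, collapse = ", ")))
  }
  comp_calls <- comparisons |>
    mutate(sig = .data$p_adjusted < 0.05) |>
    summarise(
      all_sig = all(.data$sig),
      any_sig = any(.data$sig),
      same_dir = dplyr::n_distinct(.data$direction[.data$sig]) <= 1,
      direction = if (any(.data$sig)) .data$direction[.data$sig][1] else 0,
      .by = c("gene", "component")) |>
    left_join(genes[, c("gene", "viability")], by = "gene") |>
    mutate(significant = ifelse(.data$viability == "essential_rescuable",
                                .data$all_sig & .data$same_dir,
                                .data$any_sig))
  comp_calls |>
    summarise(
      n_sig = sum(.data$significant),
      dirs = list(unique(.data$direction[.data$significant])),
      .by = "gene") |>
    mutate(erg_class = purrr::map2_chr(.data$n_sig, .data$dirs, function(k, d) {
      if (k == 0) return("none")
      if (all(d > 0)) return("increased")
      if (all(d < 0)) return("decreased")
      "mixed"
    })) |>
    select("gene", "erg_class", "n_sig") |>
    left_join(tidyr::nest(comp_calls, components = -"gene"), by = "gene")
}

#' Read ERG traces from a TSV file
#'
#' Expects columns `genotype`, `fly_id`, `trace_id`, `time_s`, `voltage_mv`
#' and optionally `eye_color`; the stimulus window is supplied explicitly.
#'
#' @param path TSV path.
#' @param stimulus_onset,stimulus_offset Stimulus window (s).
#' @return Tibble with stimulus attributes set.
#' @export
read_erg_traces <- function(path, stimulus_onset = 0.2,
                            stimulus_offset = 0.7) {
  tr <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(tr, c("genotype", "fly_id", "trace_id", "time_s", "voltage_mv"),
              "traces")
  attr(tr, "stimulus_onset") <- stimulus_onset
  attr(tr, "stimulus_offset") <- stimulus_offset
  tr
}
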