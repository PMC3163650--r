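#' Relative expression by the 2^-ddCt method
#'
#' Computes per-sample relative expression of a target gene from a
#' crossing-point (Cp) plate: technical replicates are averaged on the Cp
#' scale, the housekeeping reference is the Cp of one housekeeping gene or
#' the arithmetic-mean Cp of a chosen pair (the geometric mean on the
#' expression scale), and
#' \deqn{\Delta Ct = Cp_{gene} - Cp_{hk}, \qquad
#'       \mathrm{rel} = 2^{-\Delta Ct}.}
#' Calibration to a reference group (the ddCt step) happens in
#' [fold_regulation()]. The model assumes a doubling of template per cycle.
#'
#' @param plate Tibble `gene`, `sample`, `group`, `replicate`, `Cp`
#'   (e.g. from [synth_qpcr_plate()] or [read_cp_csv()]).
#' @param gene Target gene label.
#' @param hk One housekeeping gene label, or a character vector of two to
#'   combine.
#' @return Tibble `sample`, `group`, `delta_ct`, `rel_expr`. Samples
#'   missing a housekeeping well are dropped with a warning.
#' @examples
#' cfg <- synth_config(seed = 1, cp_sd = 0)
#' plate <- synth_qpcr_plate(cfg, "Ctsb", c(HAB = 1, LAB = 2))
#' ddct_quantify(plate, "Ctsb", c("Gapdh", "Hprt1"))
#' @export
ddct_quantify <- function(plate, gene, hk) {
  assert_cols(plate, c("gene", "sample", "group", "replicate", "Cp"))
  if (any(!is.finite(plate$Cp)) || any(plate$Cp <= 0)) {
    abort("Cp values must be positive and finite")
  }
  if (!length(hk) %in% 1:2) abort("`hk` must be one gene or a pair")
  if (!gene %in% plate$gene) abort(sprintf("gene '%s' not on plate", gene))
  miss_hk <- setdiff(hk, plate$gene)
  if (length(miss_hk) > 0) {
    abort(paste("housekeeping gene(s) not on plate:", paste(miss_hk, collapse = ", ")))
  }
  cp <- plate |>
    dplyr::filter(.data$gene %in% c(!!gene, !!hk)) |>
    dplyr::group_by(.data$gene, .data$sample, .data$group) |>
    dplyr::summarise(Cp = mean(.data$Cp), .groups = "drop")
  wide <- cp |>
    tidyr::pivot_wider(names_from = "gene", values_from = "Cp")
  have_all <- complete.cases(wide[, c(gene, hk)])
  if (any(!have_all)) {
    warn(sprintf("%d sample(s) dropped: missing target or housekeeping wells",
                 sum(!have_all)))
    wide <- wide[have_all, , drop = FALSE]
  }
  ref <- rowMeans(as.matrix(wide[, hk, drop = FALSE]))
  wide |>
    dplyr::transmute(.data$sample, .data$group,
                     delta_ct = .data[[gene]] - ref,
                     rel_expr = 2^(-.data$delta_ct))
}

#' Fold regulation relative to the lowest-expressing group
#'
#' Converts per-sample relative expressions into group fold-regulation
#' values: the reference is the group with the smallest mean relative
#' expression, whose fold is exactly 1; every other group's fold is the
#' ratio of its mean to the reference mean (the ddCt calibration step).
#' Dispersion is reported as the SEM of per-sample folds.
#'
#' @param expr Tibble `sample`, `group`, `rel_expr` from [ddct_quantify()].
#' @return A `fold_table` tibble: `group`, `n`, `fold`, `sem`,
#'   `reference` (logical). Ties in the lowest mean are broken by group
#'   label order, with a message.
#' @export
fold_regulation <- function(expr) {
  assert_cols(expr, c("sample", "group", "rel_expr"))
  if (nrow(expr) == 0) abort("empty expression table")
  means <- expr |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_expr = mean(.data$rel_expr), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$group)
  lowest <- means$mean_expr == min(means$mean_expr)
  if (sum(lowest) > 1) {
    inform("tie in lowest-expressing group; first by label order used as reference")
  }
  ref_group <- means$group[which(lowest)[1]]
  ref_mean <- means$mean_expr[which(lowest)[1]]
  per_sample <- expr |>
    dplyr::mutate(sample_fold = .data$rel_expr / ref_mean)
  out <- per_sample |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      fold = mean(.data$sample_fold),
      sem = sd(.data$sample_fold) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(reference = .data$group == ref_group)
  structure(out, class = c("fold_table", class(out)), reference_group = ref_group)
}

#' In situ hybridization signal arithmetic
#'
#' Per-section expression is the hybridization signal of the region of
#' interest minus the background signal of a nearby structure that does not
#' express the gene; the reported value for an individual is the maximum
#' over its sections. Individuals contributed three to six usable sections
#' in the emulated protocol; outside that range a warning is raised. A
#' non-positive result (background at or above signal everywhere) is
#' returned but flagged.
#'
#' @param readings Tibble `section`, `region_signal`, `background_signal`
#'   for one individual; signals must be >= 0, missing sections are
#'   dropped.
#' @return One-row tibble `expression`, `n_sections`, `nonpositive`.
#' @export
ish_quantify <- function(readings) {
  assert_cols(readings, c("section", "region_signal", "background_signal"))
  ok <- complete.cases(readings[, c("region_signal", "background_signal")])
  readings <- readings[ok, , drop = FALSE]
  if (nrow(readings) == 0) abort("all sections missing")
  if (any(readings$region_signal < 0) || any(readings$background_signal < 0)) {
    abort("signals must be >= 0")
  }
  if (!nrow(readings) %in% 3:6) {
    warn("individuals are expected to contribute 3-6 sections")
  }
  vals <- readings$region_signal - readings$background_signal
  tibble::tibble(expression = max(vals),
                 n_sections = nrow(readings),
                 nonpositive = max(vals) <= 0)
}
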