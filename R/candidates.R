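#' Cross-region candidate selection rules
#'
#' The two printed selection rules of the emulated study, both expressed on
#' percent regulation (see Details):
#' * `strictA`: at least 40% greater regulation in one region and at least
#'   30% greater regulation in all other regions, with adjusted
#'   p-value < 0.05 (the p requirement applies to every region, which makes
#'   rule A strictly stronger than rule B at a matched p threshold);
#' * `strictB`: at least 30% greater regulation with adjusted p-value < 0.10
#'   in all, or at least three, analysed regions.
#'
#' Percent regulation of an oriented fold ratio (`2^mean_M`, written r
#' below) is `100 * (max(r, 1/r) - 1)`: the magnitude ratio between the
#' higher- and lower-expressing line, so a 6-fold difference is 500%
#' regulation whichever line is higher. Because regulation is computed from
#' the oriented log ratio, thresholding it at X% is identical to
#' thresholding `|mean_M|` at `log2(1 + X/100)`: the ratio and log scales
#' coincide here.
#'
#' @param rule_id `"strictA"` or `"strictB"`.
#' @param primary_threshold Percent regulation required in at least one
#'   region (rule A).
#' @param secondary_threshold Percent regulation required in the remaining
#'   (rule A) or all qualifying (rule B) regions.
#' @param p_threshold Adjusted p-value cutoff.
#' @param region_coverage `"all"` or `"at_least_3"`.
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(rule_id = c("strictA", "strictB"),
                           primary_threshold = NULL,
                           secondary_threshold = NULL,
                           p_threshold = NULL,
                           region_coverage = NULL) {
  rule_id <- match.arg(rule_id)
  defaults <- if (rule_id == "strictA") {
    list(primary_threshold = 40, secondary_threshold = 30,
         p_threshold = 0.05, region_coverage = "all")
  } else {
    list(primary_threshold = 30, secondary_threshold = 30,
         p_threshold = 0.10, region_coverage = "at_least_3")
  }
  out <- list(
    rule_id = rule_id,
    primary_threshold = primary_threshold %||% defaults$primary_threshold,
    secondary_threshold = secondary_threshold %||% defaults$secondary_threshold,
    p_threshold = p_threshold %||% defaults$p_threshold,
    region_coverage = region_coverage %||% defaults$region_coverage
  )
  if (out$primary_threshold <= 0 || out$secondary_threshold <= 0) {
    abort("thresholds must be positive")
  }
  if (!out$region_coverage %in% c("all", "at_least_3")) {
    abort("`region_coverage` must be 'all' or 'at_least_3'")
  }
  structure(out, class = "selection_rule")
}

# Percent regulation of an oriented mean log2 ratio.
regulation_pct <- function(mean_M) 100 * (2^abs(mean_M) - 1)

check_bundle <- function(bundle) {
  if (is.list(bundle) && !is.data.frame(bundle)) {
    bundle <- dplyr::bind_rows(bundle, .id = "region")
  }
  assert_cols(bundle, c("region", "probe_id", "mean_M", "p_adj"), "bundle")
  dup <- bundle |>
    dplyr::count(.data$region, .data$probe_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("bundle has duplicate (region, probe) rows")
  bundle
}

#' Select cross-region differential-expression candidates
#'
#' Applies a [selection_rule()] to per-region differential-expression
#' tables. Regulation must point in the same direction (the same line
#' higher) in every region where the probe was measured; probes regulated
#' oppositely across regions are excluded and reported in the
#' `"flagged_direction"` attribute (see [direction_report()] for the
#' region-specific candidate track). Probes missing from a region's table
#' are treated as failing that region.
#'
#' @param bundle Long tibble with columns `region`, `probe_id`, `mean_M`,
#'   `p_adj` (e.g. row-bound [tidy()] outputs of [de_permutation()]), or a
#'   named list of per-region tables.
#' @param rule A [selection_rule()].
#' @return Tibble of selected probes, sorted by maximal regulation: columns
#'   `probe_id`, `direction` (+1 higher in HAB), `n_regions`,
#'   `regions_passed`, `max_regulation`, `min_regulation`, `min_p_adj`, and
#'   one `reg_<region>` / `p_<region>` column pair per region. Attribute
#'   `"flagged_direction"` lists the direction-inconsistent probes.
#' @export
select_candidates <- function(bundle, rule = selection_rule("strictA")) {
  stopifnot(inherits(rule, "selection_rule"))
  bundle <- check_bundle(bundle)
  if (nrow(bundle) == 0) abort("empty bundle")
  all_regions <- sort(unique(bundle$region))
  per <- bundle |>
    dplyr::mutate(regulation = regulation_pct(.data$mean_M),
                  direction = sign(.data$mean_M))
  by_probe <- per |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      n_regions = dplyr::n(),
      mixed = dplyr::n_distinct(.data$direction[.data$regulation > 0]) > 1,
      direction = .data$direction[which.max(.data$regulation)][1],
      max_regulation = max(.data$regulation),
      min_regulation = min(.data$regulation),
      min_p_adj = min(.data$p_adj),
      primary_hit = any(.data$regulation >= rule$primary_threshold),
      all_p = all(.data$p_adj < rule$p_threshold),
      n_pass = sum(.data$regulation >= rule$secondary_threshold &
                     .data$p_adj < rule$p_threshold),
      all_secondary = all(.data$regulation >= rule$secondary_threshold),
      .groups = "drop"
    )
  flagged <- dplyr::filter(by_probe, .data$mixed)
  ok <- dplyr::filter(by_probe, !.data$mixed)
  n_total <- length(all_regions)
  selected <- if (rule$rule_id == "strictA") {
    dplyr::filter(ok, .data$n_regions == n_total, .data$all_p,
                  .data$primary_hit, .data$all_secondary)
  } else {
    # "all, or at least three, analysed regions": passing all implies >= 3
    need <- if (rule$region_coverage == "all") n_total else min(3L, n_total)
    dplyr::filter(ok, .data$n_pass >= need)
  }
  wide <- per |>
    dplyr::mutate(region = factor(.data$region, levels = all_regions)) |>
    dplyr::arrange(.data$region) |>
    dplyr::select("probe_id", "region", "regulation", "p_adj") |>
    tidyr::pivot_wider(names_from = "region",
                       values_from = c("regulation", "p_adj"),
                       names_glue = "{.value}_{region}") |>
    dplyr::rename_with(~ sub("^regulation_", "reg_", .x))
  out <- selected |>
    dplyr::select("probe_id", "direction", "n_regions", regions_passed = "n_pass",
                  "max_regulation", "min_regulation", "min_p_adj") |>
    dplyr::left_join(wide, by = "probe_id") |>
    dplyr::arrange(dplyr::desc(.data$max_regulation))
  attr(out, "flagged_direction") <- flagged$probe_id
  attr(out, "rule") <- rule
  out
}

#' Report probes regulated oppositely across regions
#'
#' Lists probes whose oriented mean log ratio changes sign between two
#' regions in which both adjusted p-values fall below the threshold: the
#' region-specific candidate pattern (higher in one line in one region,
#' higher in the other line elsewhere).
#'
#' @inheritParams select_candidates
#' @param p_threshold Adjusted p-value both regions must fall below.
#' @return Tibble `probe_id`, `region_up`, `region_down`, `mean_M_up`,
#'   `mean_M_down` with one row per probe (most extreme region pair).
#' @export
direction_report <- function(bundle, p_threshold = 0.05) {
  bundle <- check_bundle(bundle)
  if (dplyr::n_distinct(bundle$region) < 2) abort("need >= 2 regions")
  sig <- bundle |>
    dplyr::filter(.data$p_adj < p_threshold, .data$mean_M != 0)
  if (nrow(sig) == 0) {
    return(tibble::tibble(probe_id = character(), region_up = character(),
                          region_down = character(), mean_M_up = numeric(),
                          mean_M_down = numeric()))
  }
  sig |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      opposed = any(.data$mean_M > 0) & any(.data$mean_M < 0),
      region_up = .data$region[which.max(.data$mean_M)],
      region_down = .data$region[which.min(.data$mean_M)],
      mean_M_up = max(.data$mean_M),
      mean_M_down = min(.data$mean_M),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$opposed) |>
    dplyr::select(-"opposed")
}
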