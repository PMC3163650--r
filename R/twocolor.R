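#' MA transform of two-colour spot intensities
#'
#' Computes, for every spot, the log ratio `M = log2(R/G)` and the mean log
#' intensity `A = log2(sqrt(R * G))` of the Cy5 (R) and Cy3 (G) channels.
#' Spots with a non-positive intensity in either channel have no defined log
#' ratio; they are flagged and carry missing M/A through the whole pipeline,
#' excluded from every median and fit.
#'
#' @param arrays Tibble of spots with columns `array_id`, `orientation`,
#'   `probe_id`, `block`, `R`, `G` (as produced by [synth_twocolor()] or
#'   [read_intensity_tsv()]).
#' @return The same tibble with columns `M`, `A`, `flagged` and `state`
#'   (`"raw"`) added. Dye orientation is recorded but not applied;
#'   see [orient_and_stack()].
#' @examples
#' spots <- tibble::tibble(array_id = "a1", orientation = "HAB_Cy5",
#'                         probe_id = c("p1", "p2"), block = 1L,
#'                         R = c(1024, 100), G = c(256, 100))
#' ma_transform(spots)[, c("M", "A")]
#' @export
ma_transform <- function(arrays) {
  assert_cols(arrays, c("array_id", "orientation", "probe_id", "block", "R", "G"))
  if (any(!is.finite(arrays$R)) || any(!is.finite(arrays$G)) ||
      any(arrays$R < 0) || any(arrays$G < 0)) {
    abort("intensities must be finite and >= 0")
  }
  out <- arrays |>
    dplyr::mutate(
      flagged = .data$R <= 0 | .data$G <= 0,
      # log2 R - log2 G (not log2(R/G)) so a channel swap negates M bit-exactly
      M = ifelse(.data$flagged, NA_real_, log2(.data$R) - log2(.data$G)),
      A = ifelse(.data$flagged, NA_real_, 0.5 * log2(.data$R * .data$G)),
      state = "raw"
    )
  bad <- out |>
    dplyr::group_by(.data$array_id) |>
    dplyr::summarise(ok = sum(!.data$flagged), .groups = "drop") |>
    dplyr::filter(.data$ok == 0)
  if (nrow(bad) > 0) {
    abort(paste("no usable spots on array(s):", paste(bad$array_id, collapse = ", ")))
  }
  out
}

check_state <- function(ma, expected, op) {
  assert_cols(ma, c("array_id", "probe_id", "M", "A", "state"))
  st <- unique(ma$state)
  if (length(st) != 1 || st != expected) {
    abort(sprintf("%s requires normalization state '%s', found '%s'",
                  op, expected, paste(st, collapse = "/")))
  }
  invisible(ma)
}

#' Global median normalization
#'
#' Subtracts from each array's M values the constant `c` = median of its
#' usable M values, implementing the assumption that the two channels
#' correlate so the bulk of spots have true ratio 1. After this step the
#' median usable M of every array is 0 (to floating precision).
#'
#' @param ma An MA tibble at state `"raw"` (from [ma_transform()]).
#' @return The tibble at state `"global"`, with the fitted constants stored
#'   in attribute `"correction"` (tibble `array_id`, `c_global`).
#' @export
normalize_global <- function(ma) {
  check_state(ma, "raw", "normalize_global")
  out <- ma |>
    dplyr::group_by(.data$array_id) |>
    dplyr::mutate(.c = median(.data$M, na.rm = TRUE),
                  M = .data$M - .c) |>
    dplyr::ungroup()
  corr <- out |>
    dplyr::distinct(.data$array_id, c_global = .data$.c)
  out <- dplyr::select(out, -".c") |>
    dplyr::mutate(state = "global")
  attr(out, "correction") <- corr
  out
}

#' Intensity-dependent loess normalization
#'
#' Fits, per array, a locally weighted linear regression (tricube weights,
#' robustified) of M on A using a neighbourhood containing `span` of the
#' usable spots, and subtracts the fitted curve `c(A)`. This removes smooth
#' intensity-dependent dye bias visible as curvature of the MA-plot. The
#' default span uses 40% of the spots.
#'
#' @param ma An MA tibble at state `"global"`.
#' @param span Fraction of usable spots in each local neighbourhood,
#'   in (0, 1].
#' @param grid_n Number of points at which the fitted curve is tabulated.
#' @return The tibble at state `"loess"`, with the fitted curves stored in
#'   attribute `"curve"` (tibble `array_id`, `A`, `c_hat`).
#' @export
normalize_loess <- function(ma, span = 0.40, grid_n = 101L) {
  check_state(ma, "global", "normalize_loess")
  if (!is_scalar_number(span) || span <= 0 || span > 1) {
    abort("`span` must be a fraction in (0, 1]")
  }
  pieces <- ma |>
    dplyr::group_by(.data$array_id) |>
    dplyr::group_split()
  fitted <- purrr::map(pieces, function(d) {
    ok <- !is.na(d$M) & !is.na(d$A)
    if (sum(ok) < 10) {
      abort(sprintf("array '%s' has fewer than 10 usable spots; loess fit unidentifiable",
                    d$array_id[1]))
    }
    # fit the smoother to M and to -M and antisymmetrize: the curve is then
    # exactly odd under a global channel swap (M -> -M), so the pipeline is
    # bit-identically equivariant; statistically the two fits coincide
    fit_p <- lowess(d$A[ok], d$M[ok], f = span, iter = 3)
    fit_m <- lowess(d$A[ok], -d$M[ok], f = span, iter = 3)
    eval_at <- function(x) {
      (approx(fit_p$x, fit_p$y, xout = x, rule = 2, ties = mean)$y -
         approx(fit_m$x, fit_m$y, xout = x, rule = 2, ties = mean)$y) / 2
    }
    c_hat <- rep(NA_real_, nrow(d))
    c_hat[ok] <- eval_at(d$A[ok])
    grid_A <- seq(min(d$A[ok]), max(d$A[ok]), length.out = grid_n)
    curve <- tibble::tibble(array_id = d$array_id[1], A = grid_A,
                            c_hat = eval_at(grid_A))
    d$M <- d$M - c_hat
    list(d = d, curve = curve)
  })
  out <- dplyr::bind_rows(purrr::map(fitted, "d")) |>
    dplyr::mutate(state = "loess")
  attr(out, "correction") <- attr(ma, "correction")
  attr(out, "curve") <- dplyr::bind_rows(purrr::map(fitted, "curve"))
  out
}

#' Sub-array (print-block) balancing
#'
#' Subtracts, within each array, the median usable M of every sub-array
#' block, removing offsets caused by unequal probe distribution across print
#' blocks or locally unbalanced fluorescence. Blocks without usable spots
#' are left unchanged with a warning. The step is idempotent: a second pass
#' subtracts zero.
#'
#' @param ma An MA tibble at state `"loess"` with a `block` column.
#' @return The tibble at state `"subarray"`.
#' @export
normalize_subarray <- function(ma) {
  check_state(ma, "loess", "normalize_subarray")
  assert_cols(ma, "block")
  out <- ma |>
    dplyr::group_by(.data$array_id, .data$block) |>
    dplyr::mutate(.c = median(.data$M, na.rm = TRUE)) |>
    dplyr::ungroup()
  empty <- is.na(out$.c)
  if (any(empty)) {
    warn(sprintf("%d block(s) without usable spots left unchanged",
                 nrow(dplyr::distinct(out[empty, ], .data$array_id, .data$block))))
    out$.c[empty] <- 0
  }
  out <- out |>
    dplyr::mutate(M = .data$M - .data$.c, state = "subarray") |>
    dplyr::select(-".c")
  attr(out, "correction") <- attr(ma, "correction")
  attr(out, "curve") <- attr(ma, "curve")
  out
}

#' Orient dye-swapped arrays and stack them probe-by-array
#'
#' Flips the sign of M on arrays that carried the low-anxiety line on Cy5,
#' so that every column measures log2(HAB/LAB), then aligns probes by id
#' into a wide probe-by-array table. Probes absent (or flagged) on some
#' arrays keep missing cells.
#'
#' @param ma An MA tibble at state `"subarray"` (or the state named in
#'   `require_state`) with an `orientation` column containing `"HAB_Cy5"`
#'   or `"LAB_Cy5"`.
#' @param require_state Normalization state the input must carry.
#' @return A wide tibble: `probe_id` plus one oriented-M column per
#'   `array_id`.
#' @export
orient_and_stack <- function(ma, require_state = "subarray") {
  check_state(ma, require_state, "orient_and_stack")
  assert_cols(ma, "orientation")
  bad <- setdiff(unique(ma$orientation), c("HAB_Cy5", "LAB_Cy5"))
  if (length(bad) > 0) {
    abort(paste("unknown orientation value(s):", paste(bad, collapse = ", ")))
  }
  ma |>
    dplyr::mutate(M = ifelse(.data$orientation == "LAB_Cy5", -.data$M, .data$M)) |>
    dplyr::select("probe_id", "array_id", "M") |>
    tidyr::pivot_wider(names_from = "array_id", values_from = "M")
}

#' Run the full two-colour normalization chain
#'
#' Convenience wrapper: [ma_transform()], [normalize_global()],
#' [normalize_loess()], [normalize_subarray()], then [orient_and_stack()].
#'
#' @inheritParams ma_transform
#' @inheritParams normalize_loess
#' @param skip_subarray If `TRUE`, omit the sub-array balancing step and
#'   stack directly after the loess step.
#' @return A wide oriented M matrix as a tibble (see [orient_and_stack()]).
#' @export
normalize_twocolor <- function(arrays, span = 0.40, skip_subarray = FALSE) {
  ma <- arrays |> ma_transform() |> normalize_global() |> normalize_loess(span = span)
  if (skip_subarray) {
    orient_and_stack(ma, require_state = "loess")
  } else {
    orient_and_stack(normalize_subarray(ma))
  }
}
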