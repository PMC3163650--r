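#' Read and write the pipeline's plain-text table dialects
#'
#' Tab-delimited spot intensity tables (`probe_id`, `block`, `row`, `col`,
#' `R`, `G` plus `array_id` / `orientation` metadata columns), probe-by-
#' sample expression matrices (TSV), qPCR crossing-point tables (CSV:
#' `gene`, `sample`, `group`, `replicate`, `Cp`), variant tables (TSV
#' mirroring the supplementary-table dialect) and behavioural endpoint
#' tables (CSV).
#'
#' @param x Tibble to write.
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_intensity_tsv <- function(x, path) {
  assert_cols(x, c("array_id", "orientation", "probe_id", "block", "R", "G"))
  per_block <- x |>
    dplyr::group_by(.data$array_id, .data$block) |>
    dplyr::mutate(.i = dplyr::row_number(),
                  row = (.data$.i - 1L) %/% 24L + 1L,
                  col = (.data$.i - 1L) %% 24L + 1L) |>
    dplyr::ungroup() |>
    dplyr::select("array_id", "orientation", "probe_id", "block",
                  "row", "col", "R", "G")
  readr::write_tsv(per_block, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_intensity_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(out, c("array_id", "orientation", "probe_id", "block", "R", "G"),
              "intensity table")
  out
}

#' @rdname pipeline_io
#' @export
write_ma_tsv <- function(x, path) {
  assert_cols(x, c("array_id", "probe_id", "block", "M", "A", "state"))
  readr::write_tsv(dplyr::select(x, "array_id", "probe_id", "block",
                                 "M", "A", "state"), path)
  invisible(path)
}

#' Write the fitted loess correction curves as a grid file
#' @rdname pipeline_io
#' @export
write_curve_tsv <- function(x, path) {
  curve <- attr(x, "curve") %||% x
  assert_cols(curve, c("array_id", "A", "c_hat"), "curve")
  readr::write_tsv(curve, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_matrix_tsv <- function(x, path) {
  assert_cols(x, "probe_id")
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_matrix_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(out, "probe_id", "expression matrix")
  out
}

#' @rdname pipeline_io
#' @export
write_cp_csv <- function(x, path) {
  assert_cols(x, c("gene", "sample", "group", "replicate", "Cp"))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cp_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(out, c("gene", "sample", "group", "replicate", "Cp"), "Cp table")
  out
}

#' @rdname pipeline_io
#' @export
write_variant_tsv <- function(x, path) {
  assert_cols(x, c("type", "genomic_position", "hab_allele", "lab_allele"))
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a variant table, preserving its own labels
#'
#' The reader keeps the table's `type` and `location` labels as printed
#' (insertion/deletion orientation conventions are a property of the
#' source table, not re-derived).
#' @rdname pipeline_io
#' @export
read_variant_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           hab_allele = readr::col_character(),
                           lab_allele = readr::col_character(),
                           .default = readr::col_guess()))
  assert_cols(out, c("type", "genomic_position", "hab_allele", "lab_allele"),
              "variant table")
  out$hab_allele[is.na(out$hab_allele)] <- ""
  out$lab_allele[is.na(out$lab_allele)] <- ""
  out
}

#' @rdname pipeline_io
#' @export
write_behavior_csv <- function(x, path) {
  assert_cols(x, c("subject", "genotype", "sex", "endpoint", "value"))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_behavior_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(out, c("subject", "genotype", "sex", "endpoint", "value"),
              "behaviour table")
  out
}
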