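#' Generate a qPCR crossing-point plate
#'
#' Emulates duplicate qPCR measurements of one target gene plus the
#' configured housekeeping genes across sample groups. The crossing point of
#' a well is
#' \deqn{Cp = \mathrm{intercept} - \log_2(\mathrm{relative\ expression})
#'       + L_s + \epsilon,}
#' with a per-sample loading offset \eqn{L_s} shared by target and
#' housekeeping wells (it cancels under housekeeping normalization) and
#' independent Gaussian well noise. Housekeeping genes have fold 1 in every
#' group.
#'
#' @param cfg A [synth_config()].
#' @param gene Target gene label.
#' @param true_fold_by_group Named numeric vector of true expression folds,
#'   one entry per group in `cfg$qpcr_groups$group`.
#' @param n_replicates Technical replicates per (gene, sample); the emulated
#'   protocol ran duplicates.
#' @return A tibble with columns `gene`, `sample`, `group`, `replicate`,
#'   `Cp`, carrying the housekeeping gene set as attribute `"hk_genes"`.
#' @examples
#' cfg <- synth_config(seed = 1, cp_sd = 0)
#' plate <- synth_qpcr_plate(cfg, "Ctsb", c(HAB = 1, LAB = 2))
#' head(plate)
#' @export
synth_qpcr_plate <- function(cfg, gene, true_fold_by_group, n_replicates = 2L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(cfg$hk_genes) == 0) abort("`hk_genes` must be non-empty")
  groups <- cfg$qpcr_groups
  missing <- setdiff(groups$group, names(true_fold_by_group))
  if (length(missing) > 0) {
    abort(paste("`true_fold_by_group` lacks group(s):", paste(missing, collapse = ", ")))
  }
  if (any(true_fold_by_group <= 0)) abort("true folds must be > 0")
  samples <- tidyr::uncount(groups, .data$n, .id = "idx") |>
    dplyr::mutate(sample = sprintf("%s_%02d", .data$group, .data$idx)) |>
    dplyr::select("sample", "group")
  genes <- c(gene, cfg$hk_genes)
  with_seed(derive_seed(cfg$seed, paste0("qpcr-", gene)), {
    samples$loading <- rnorm(nrow(samples), 0, cfg$sample_shift_sd)
    wells <- tidyr::expand_grid(gene = genes, samples,
                                replicate = seq_len(n_replicates))
    rel <- ifelse(wells$gene == gene,
                  true_fold_by_group[wells$group], 1)
    wells$Cp <- cfg$cp_intercept - log2(rel) + wells$loading +
      rnorm(nrow(wells), 0, cfg$cp_sd)
    out <- dplyr::select(wells, "gene", "sample", "group", "replicate", "Cp")
    attr(out, "hk_genes") <- cfg$hk_genes
    out
  })
}
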