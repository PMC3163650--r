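#' Tidy the per-probe table of a permutation DE result
#'
#' @param x A `de_result` from [de_permutation()].
#' @param ... Unused.
#' @return Tibble `probe_id`, `n_arrays`, `mean_M`, `t_raw`, `fold_pct`,
#'   `regulation_pct`, `p_adj` (one row per probe).
#' @export
tidy.de_result <- function(x, ...) {
  x$table
}

#' One-row summary of a permutation DE result
#'
#' @inheritParams tidy.de_result
#' @return Tibble `region`, `n_probes`, `n_arrays`, `n_perm`,
#'   `enumerated`, `n_sig_05`, `n_sig_10`.
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(region = x$region, n_probes = nrow(x$table),
                 n_arrays = x$n_arrays, n_perm = x$n_perm,
                 enumerated = x$enumerated,
                 n_sig_05 = sum(x$table$p_adj < 0.05),
                 n_sig_10 = sum(x$table$p_adj < 0.10))
}

#' Tidy the per-probe table of a moderated-t fit
#'
#' @param x A `modt_fit` from [moderated_t()].
#' @param ... Unused.
#' @return Tibble `probe_id`, `log_ratio`, `s2`, `t_mod`, `p_mod`.
#' @export
tidy.modt_fit <- function(x, ...) {
  x$table
}

#' Hyperparameters of a moderated-t fit
#'
#' @inheritParams tidy.modt_fit
#' @return Tibble `d0`, `s0_sq`, `df_residual`, `n_probes`.
#' @export
glance.modt_fit <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, df_residual = x$df_residual,
                 n_probes = nrow(x$table))
}

#' Pairwise table of a gated group comparison
#'
#' @param x A `group_comparison` from [group_compare()].
#' @param ... Unused.
#' @return The pairwise Mann-Whitney/Holm tibble (zero rows when the
#'   omnibus gate was not passed).
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' Omnibus row of a gated group comparison
#'
#' @inheritParams tidy.group_comparison
#' @return The Kruskal-Wallis tibble with the gate settings appended.
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus, gate_p = x$gate_p, alpha = x$alpha)
}
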