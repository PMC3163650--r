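#' Generate a behavioural endpoint table
#'
#' Emulates a knock-out behavioural battery: three genotype groups (WT, HET,
#' KO) by two sexes, with endpoint values drawn from Gaussian distributions
#' shifted per genotype according to `cfg$behavior_effect`. A shift of 0
#' everywhere gives a null table for type-I-error calibration.
#'
#' @param cfg A [synth_config()]. `cfg$behavior_effect` is a named list
#'   `endpoint -> c(genotype = shift, ...)` with shifts in units of
#'   `cfg$behavior_sd`; an empty list produces the single null endpoint
#'   `"endpoint1"`.
#' @param genotypes Genotype labels.
#' @param sexes Sex labels.
#' @return Tibble with columns `subject`, `genotype`, `sex`, `endpoint`,
#'   `value`.
#' @examples
#' cfg <- synth_config(seed = 1, behavior_n = 5,
#'                     behavior_effect = list(floating = c(KO = 2)))
#' table(synth_behavior(cfg)$genotype)
#' @export
synth_behavior <- function(cfg, genotypes = c("WT", "HET", "KO"),
                           sexes = c("m", "f")) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$behavior_n <= 0) abort("`behavior_n` must be a positive group size")
  effects <- cfg$behavior_effect
  if (length(effects) == 0) effects <- list(endpoint1 = c())
  layout <- tidyr::expand_grid(genotype = genotypes, sex = sexes,
                               idx = seq_len(cfg$behavior_n)) |>
    dplyr::mutate(subject = sprintf("%s_%s_%02d", .data$genotype, .data$sex, .data$idx))
  with_seed(derive_seed(cfg$seed, "behavior"), {
    purrr::imap_dfr(effects, function(shifts, endpoint) {
      sh <- rep(0, nrow(layout))
      if (length(shifts) > 0) {
        hit <- layout$genotype %in% names(shifts)
        sh[hit] <- shifts[layout$genotype[hit]] * cfg$behavior_sd
      }
      tibble::tibble(
        subject = layout$subject, genotype = layout$genotype,
        sex = layout$sex, endpoint = endpoint,
        value = sh + rnorm(nrow(layout), 0, cfg$behavior_sd)
      )
    })
  })
}
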