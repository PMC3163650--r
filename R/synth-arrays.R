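#' Generate dye-swapped two-colour arrays for one brain region
#'
#' Emulates replicate two-colour hybridizations of pooled line samples for a
#' single brain region: half of the slides carry the high-anxiety (HAB) line
#' on Cy5, half are dye-swapped. The spot model on the log2 scale is
#' \deqn{M = s \cdot r_p + b(A_p) + o_{block} + \epsilon,}
#' where \eqn{r_p} is the planted line log2 ratio (HAB over LAB), \eqn{s} is
#' +1 when HAB is on Cy5 and -1 on dye-swapped slides, \eqn{b(A)} is a smooth
#' dye bias, \eqn{o_{block}} a per-sub-array offset and \eqn{\epsilon}
#' Gaussian noise. Channel intensities are reconstructed as
#' \eqn{R = 2^{A + M/2}}, \eqn{G = 2^{A - M/2}}.
#'
#' @param cfg A [synth_config()].
#' @param region A region label from `cfg$regions`.
#' @return A list with
#'   * `arrays`: long tibble of spots with columns `array_id`, `region`,
#'     `orientation` (`"HAB_Cy5"` / `"LAB_Cy5"`), `probe_id`, `block`,
#'     `R`, `G`;
#'   * `truth`: tibble `probe_id`, `block`, `baseline_A`, `log2_ratio`,
#'     `fold` marking exactly `cfg$n_de_probes` probes with non-unit fold.
#' @examples
#' cfg <- synth_config(seed = 1, n_probes = 96, n_subarrays = 4,
#'                     n_de_probes = 5, n_arrays_per_region = 4)
#' tc <- synth_twocolor(cfg, "PVN")
#' dplyr::count(tc$arrays, array_id, orientation)
#' @export
synth_twocolor <- function(cfg, region) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!region %in% cfg$regions) {
    abort(sprintf("unknown region label '%s'", region))
  }
  truth <- probe_truth(cfg)
  arrays <- spot_tables(cfg, truth, region = region,
                        ratio = truth$log2_ratio,
                        seed_tag = paste0("twocolor-", region))
  list(arrays = arrays, truth = truth)
}

#' Generate null self-hybridization arrays
#'
#' The negative control of the two-colour pipeline: the same pooled sample is
#' hybridized against itself in both dye orientations, so the true ratio is 1
#' for every probe while dye bias, sub-array offsets and noise still apply.
#'
#' @inheritParams synth_twocolor
#' @return As [synth_twocolor()]; the truth table has fold 1 everywhere.
#' @export
synth_selfhyb <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- probe_truth(cfg)
  truth$log2_ratio <- 0
  truth$fold <- 1
  arrays <- spot_tables(cfg, truth, region = "selfhyb",
                        ratio = rep(0, cfg$n_probes), seed_tag = "selfhyb")
  list(arrays = arrays, truth = truth)
}

# Shared spot-level generator for the two-colour emulations.
spot_tables <- function(cfg, truth, region, ratio, seed_tag) {
  n_arr <- cfg$n_arrays_per_region
  orientations <- rep(c("HAB_Cy5", "LAB_Cy5"), length.out = n_arr)
  with_seed(derive_seed(cfg$seed, seed_tag), {
    purrr::map_dfr(seq_len(n_arr), function(k) {
      s <- if (orientations[k] == "HAB_Cy5") 1 else -1
      block_off <- rnorm(cfg$n_subarrays, 0, cfg$subarray_sd)
      M <- s * ratio +
        dye_bias_curve(truth$baseline_A, cfg$dye_bias_amplitude, cfg$a_range) +
        block_off[truth$block] +
        rnorm(cfg$n_probes, 0, cfg$noise_sd)
      tibble::tibble(
        array_id = sprintf("%s_a%02d", region, k),
        region = region,
        orientation = orientations[k],
        probe_id = truth$probe_id,
        block = truth$block,
        R = 2^(truth$baseline_A + M / 2),
        G = 2^(truth$baseline_A - M / 2)
      )
    })
  })
}

#' Generate a single-channel probe-by-sample expression matrix
#'
#' Emulates one bead-array batch: up to six mice per line hybridized
#' one-sample-per-array, with planted per-sample scale factors (so that
#' between-array normalization is non-trivial) and the same planted line
#' ratios as the two-colour truth.
#'
#' @inheritParams synth_twocolor
#' @return A list with
#'   * `exprs`: tibble `probe_id` plus one positive-intensity column per
#'     sample;
#'   * `samples`: tibble `sample`, `group`, `log2_scale` (planted scale
#'     factor);
#'   * `truth`: the probe truth table (see [synth_twocolor()]).
#' @export
synth_singlechannel <- function(cfg, region) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!region %in% cfg$regions) {
    abort(sprintf("unknown region label '%s'", region))
  }
  if (cfg$n_samples_per_group > 6) {
    warn("more than six samples per line in one batch; the emulated design caps batches at six")
  }
  truth <- probe_truth(cfg)
  n <- cfg$n_samples_per_group
  samples <- tibble::tibble(
    sample = c(sprintf("HAB_%02d", seq_len(n)), sprintf("LAB_%02d", seq_len(n))),
    group = rep(c("HAB", "LAB"), each = n)
  )
  with_seed(derive_seed(cfg$seed, paste0("singlechannel-", region)), {
    samples$log2_scale <- rnorm(nrow(samples), 0, cfg$sc_scale_sd)
    cols <- purrr::map(seq_len(nrow(samples)), function(j) {
      half <- if (samples$group[j] == "HAB") 0.5 else -0.5
      2^(truth$baseline_A + half * truth$log2_ratio +
           samples$log2_scale[j] + rnorm(cfg$n_probes, 0, cfg$sc_noise_sd))
    })
    exprs <- tibble::as_tibble(setNames(cols, samples$sample))
    exprs <- dplyr::bind_cols(tibble::tibble(probe_id = truth$probe_id), exprs)
    list(exprs = exprs, samples = samples, truth = truth)
  })
}
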