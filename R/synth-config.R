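#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic study emulation: a dye-swapped
#' two-colour array experiment over seven limbic brain regions with technical
#' replicate slides, a single-channel bead-array style expression matrix,
#' qPCR crossing-point plates with housekeeping genes, and group-structured
#' behavioural endpoint tables. The defaults reproduce the emulated study
#' design: 24,192 probes per array, ten replicate slides per region (half of
#' them dye-swapped), seven brain regions, 300 probes with a planted
#' line-expression ratio of at least 1.4-fold.
#'
#' All generators are deterministic functions of this configuration:
#' identical configurations (including `seed`) give bit-identical output.
#'
#' @param seed Master integer seed; every generator derives its own stream
#'   from it.
#' @param n_probes Number of probes (spots) per array.
#' @param n_arrays_per_region Replicate slides per brain region; half carry
#'   the high-anxiety line on Cy5, half are dye-swapped.
#' @param regions Character vector of brain-region labels.
#' @param n_de_probes Number of probes with a planted non-unit line ratio.
#' @param de_fold_range Length-2 numeric, the range of planted fold ratios
#'   (magnitudes; direction is drawn symmetrically).
#' @param dye_bias_amplitude Amplitude (log2 units) of the smooth
#'   intensity-dependent dye bias added to every two-colour array.
#' @param subarray_sd SD (log2 units) of per-block (sub-array) offsets.
#' @param noise_sd SD (log2 units) of additive spot noise.
#' @param n_subarrays Number of print blocks per slide; must divide
#'   `n_probes`.
#' @param a_range Range of baseline mean log2 intensities (the A axis).
#' @param n_samples_per_group Mice per line per batch on the single-channel
#'   path (at most six per batch in the emulated design).
#' @param sc_noise_sd SD (log2) of single-channel measurement noise.
#' @param sc_scale_sd SD (log2) of planted per-sample scale factors.
#' @param qpcr_groups Tibble with columns `group`, `n`: qPCR group layout.
#' @param hk_genes Housekeeping gene labels measured on every plate.
#' @param cp_sd SD (cycles) of per-well crossing-point noise.
#' @param cp_intercept Baseline crossing point (cycles) of a unit-expression
#'   target.
#' @param sample_shift_sd SD (cycles) of per-sample loading offsets, shared
#'   between target and housekeeping wells so that housekeeping
#'   normalization is non-trivial.
#' @param behavior_n Animals per genotype per sex in behaviour tables.
#' @param behavior_sd Within-group SD of behavioural endpoint values.
#' @param behavior_effect Named list: endpoint -> named numeric vector of
#'   location shifts per genotype (in units of `behavior_sd`); genotypes
#'   absent from the vector get shift 0.
#'
#' @return An object of class `synth_config` (a named list).
#' @examples
#' cfg <- synth_config(seed = 1, n_probes = 200, n_de_probes = 10)
#' cfg$regions
#' @export
synth_config <- function(seed = 1L,
                         n_probes = 24192L,
                         n_arrays_per_region = 10L,
                         regions = c("Cg", "NAc", "PVN", "SON", "BLA", "CeA", "DG"),
                         n_de_probes = 300L,
                         de_fold_range = c(1.4, 3),
                         dye_bias_amplitude = 0.3,
                         subarray_sd = 0.1,
                         noise_sd = 0.15,
                         n_subarrays = 48L,
                         a_range = c(6, 14),
                         n_samples_per_group = 6L,
                         sc_noise_sd = 0.2,
                         sc_scale_sd = 0.3,
                         qpcr_groups = tibble::tibble(group = c("HAB", "LAB"),
                                                      n = c(8L, 8L)),
                         hk_genes = c("Gapdh", "Hprt1", "Atp2b1", "Rpl13a", "Polr2b"),
                         cp_sd = 0.1,
                         cp_intercept = 24,
                         sample_shift_sd = 0.5,
                         behavior_n = 15L,
                         behavior_sd = 1,
                         behavior_effect = list()) {
  if (!is_scalar_number(seed)) abort("`seed` must be a single finite number")
  if (n_de_probes > n_probes) abort("`n_de_probes` must not exceed `n_probes`")
  sds <- c(dye_bias_amplitude, subarray_sd, noise_sd, sc_noise_sd,
           sc_scale_sd, cp_sd, sample_shift_sd, behavior_sd)
  if (any(sds < 0)) abort("all SD / amplitude parameters must be >= 0")
  if (any(de_fold_range <= 0) || length(de_fold_range) != 2) {
    abort("`de_fold_range` must be two positive ratios")
  }
  if (n_probes %% n_subarrays != 0) {
    abort("`n_subarrays` must divide `n_probes`")
  }
  if (length(regions) < 1 || anyDuplicated(regions)) {
    abort("`regions` must be a non-empty set of unique labels")
  }
  assert_cols(qpcr_groups, c("group", "n"), "qpcr_groups")
  if (any(qpcr_groups$n < 0)) abort("qPCR group sizes must be >= 0")
  structure(list(
    seed = as.integer(seed), n_probes = as.integer(n_probes),
    n_arrays_per_region = as.integer(n_arrays_per_region),
    regions = regions, n_de_probes = as.integer(n_de_probes),
    de_fold_range = sort(as.numeric(de_fold_range)),
    dye_bias_amplitude = dye_bias_amplitude, subarray_sd = subarray_sd,
    noise_sd = noise_sd, n_subarrays = as.integer(n_subarrays),
    a_range = as.numeric(a_range),
    n_samples_per_group = as.integer(n_samples_per_group),
    sc_noise_sd = sc_noise_sd, sc_scale_sd = sc_scale_sd,
    qpcr_groups = qpcr_groups, hk_genes = hk_genes,
    cp_sd = cp_sd, cp_intercept = cp_intercept,
    sample_shift_sd = sample_shift_sd,
    behavior_n = as.integer(behavior_n), behavior_sd = behavior_sd,
    behavior_effect = behavior_effect
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  probes:", x$n_probes, " arrays/region:", x$n_arrays_per_region,
      " regions:", paste(x$regions, collapse = ","), "\n")
  cat("  planted DE probes:", x$n_de_probes, " fold range:",
      paste(signif(x$de_fold_range, 3), collapse = "-"), "\n")
  cat("  noise_sd:", x$noise_sd, " dye bias:", x$dye_bias_amplitude,
      " subarray_sd:", x$subarray_sd, " seed:", x$seed, "\n")
  invisible(x)
}

# Probe-level properties shared by every array of a configuration:
# baseline A values, block layout, and the planted truth table.
probe_truth <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "probe-truth"), {
    probe_id <- sprintf("P%05d", seq_len(cfg$n_probes))
    baseline_A <- runif(cfg$n_probes, cfg$a_range[1], cfg$a_range[2])
    log2_ratio <- rep(0, cfg$n_probes)
    if (cfg$n_de_probes > 0) {
      de_idx <- sort(sample.int(cfg$n_probes, cfg$n_de_probes))
      folds <- runif(cfg$n_de_probes, cfg$de_fold_range[1], cfg$de_fold_range[2])
      signs <- sample(c(-1, 1), cfg$n_de_probes, replace = TRUE)
      log2_ratio[de_idx] <- signs * log2(folds)
    }
    tibble::tibble(
      probe_id = probe_id,
      block = rep(seq_len(cfg$n_subarrays), each = cfg$n_probes / cfg$n_subarrays),
      baseline_A = baseline_A,
      log2_ratio = log2_ratio,
      fold = 2^log2_ratio
    )
  })
}

# Smooth intensity-dependent dye bias: one full sine period scaled to the
# baseline A range, so its array-wide median is ~0 and loess can remove it.
dye_bias_curve <- function(A, amplitude, a_range) {
  u <- (A - a_range[1]) / diff(a_range)
  amplitude * sin(2 * pi * u)
}
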