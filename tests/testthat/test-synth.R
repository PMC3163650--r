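test_that("identical configurations give bit-identical outputs", {
  cfg <- cfg_small(seed = 42)
  a1 <- synth_twocolor(cfg, "PVN")
  a2 <- synth_twocolor(cfg_small(seed = 42), "PVN")
  expect_identical(a1, a2)
  expect_identical(synth_qpcr_plate(cfg, "Ctsb", c(HAB = 1, LAB = 2)),
                   synth_qpcr_plate(cfg, "Ctsb", c(HAB = 1, LAB = 2)))
  expect_identical(synth_behavior(cfg), synth_behavior(cfg))
  # different seed changes the data
  expect_false(identical(a1$arrays$R,
                         synth_twocolor(cfg_small(seed = 43), "PVN")$arrays$R))
})

test_that("truth table plants exactly n_de_probes probes", {
  cfg <- cfg_small()
  tc <- synth_twocolor(cfg, "BLA")
  expect_equal(sum(tc$truth$fold != 1), 20)
  expect_true(all(abs(tc$truth$log2_ratio[tc$truth$fold != 1]) >= log2(1.4) - 1e-12))
  # same truth in every region (cross-region consistency of planted effects)
  expect_identical(tc$truth, synth_twocolor(cfg, "DG")$truth)
})

test_that("with all effects off every spot has R = G (M = 0 exactly)", {
  tc <- synth_twocolor(cfg_clean(), "Cg")
  expect_equal(tc$arrays$R, tc$arrays$G)
})

test_that("a planted fold of 2 gives dye-corrected M = 1 on every array", {
  cfg <- cfg_clean(n_probes = 96)
  cfg$n_de_probes <- 1L
  cfg$de_fold_range <- c(2, 2)
  tc <- synth_twocolor(cfg, "Cg")
  de_probe <- tc$truth$probe_id[tc$truth$fold != 1]
  spots <- dplyr::filter(tc$arrays, .data$probe_id == de_probe)
  m <- log2(spots$R / spots$G)
  oriented <- ifelse(spots$orientation == "LAB_Cy5", -m, m)
  expect_equal(oriented, rep(sign(tc$truth$log2_ratio[tc$truth$fold != 1]) *
                               abs(tc$truth$log2_ratio[tc$truth$fold != 1]),
                             nrow(spots)))
  expect_equal(abs(oriented), rep(1, nrow(spots)))
})

test_that("unknown region labels are rejected", {
  expect_error(synth_twocolor(cfg_small(), "cortex"), "unknown region")
  expect_error(synth_singlechannel(cfg_small(), "cortex"), "unknown region")
})

test_that("self-hybridization arrays carry no planted effect", {
  cfg <- cfg_small(seed = 5)
  sh <- synth_selfhyb(cfg)
  expect_true(all(sh$truth$fold == 1))
  # noiseless self-hyb: M exactly 0
  sh0 <- synth_selfhyb(cfg_clean())
  expect_equal(sh0$arrays$R, sh0$arrays$G)
  # dye-swapped pair averages to ~0 per probe (law of large numbers bound)
  m <- log2(sh$arrays$R / sh$arrays$G)
  oriented <- ifelse(sh$arrays$orientation == "LAB_Cy5", -m, m)
  pair_mean <- tapply(oriented, sh$arrays$probe_id, mean)
  expect_lt(mean(abs(pair_mean)), 4 * cfg$noise_sd / sqrt(2))
})

test_that("planted oriented M recovers the planted ratio at generator scale", {
  cfg <- synth_config(seed = 1, n_probes = 2400, n_subarrays = 4,
                      n_de_probes = 30, dye_bias_amplitude = 0,
                      subarray_sd = 0, noise_sd = 0.15)
  tc <- synth_twocolor(cfg, "SON")
  m <- log2(tc$arrays$R / tc$arrays$G)
  oriented <- ifelse(tc$arrays$orientation == "LAB_Cy5", -m, m)
  per_probe <- tapply(oriented, tc$arrays$probe_id, mean)
  planted <- tc$truth[tc$truth$fold != 1, ]
  err <- per_probe[planted$probe_id] - planted$log2_ratio
  n_arr <- cfg$n_arrays_per_region
  # pooled error over planted probes
  expect_lt(abs(mean(err)), 3 * cfg$noise_sd / sqrt(nrow(planted) * n_arr))
  # and nearly all individual probes inside the per-probe 4-sigma band
  expect_gte(mean(abs(err) < 4 * cfg$noise_sd / sqrt(n_arr)), 0.99)
})

test_that("single-channel generator plants scale factors and group ratios", {
  cfg0 <- cfg_clean()
  sc0 <- synth_singlechannel(cfg0, "Cg")
  cols <- as.matrix(dplyr::select(sc0$exprs, -"probe_id"))
  expect_true(all(apply(cols, 1, function(r) max(r) - min(r)) < 1e-12))
  # planted per-sample scale factors shift pre-normalization column medians
  # (read back exactly at zero measurement noise)
  cfg <- synth_config(seed = 9, n_probes = 480, n_subarrays = 4,
                      n_de_probes = 0, sc_noise_sd = 0, sc_scale_sd = 0.3)
  sc <- synth_singlechannel(cfg, "Cg")
  lm2 <- log2(as.matrix(dplyr::select(sc$exprs, -"probe_id")))
  med <- apply(lm2, 2, median)
  expect_equal(unname(med - med[1]),
               sc$samples$log2_scale - sc$samples$log2_scale[1],
               tolerance = 1e-12)
  # planted fold 2, no noise: group log2 difference equals 1
  cfg2 <- cfg_clean()
  cfg2$n_de_probes <- 1L
  cfg2$de_fold_range <- c(2, 2)
  sc2 <- synth_singlechannel(cfg2, "Cg")
  de_probe <- which(sc2$truth$fold != 1)
  lm2 <- log2(as.matrix(dplyr::select(sc2$exprs, -"probe_id")))
  diffs <- mean(lm2[de_probe, sc2$samples$group == "HAB"]) -
    mean(lm2[de_probe, sc2$samples$group == "LAB"])
  expect_equal(abs(diffs), 1, tolerance = 1e-12)
})

test_that("qPCR plate generator follows the Cp model", {
  cfg <- cfg_clean()
  plate <- synth_qpcr_plate(cfg, "Ctsb", c(HAB = 1, LAB = 1))
  expr <- ddct_quantify(plate, "Ctsb", cfg$hk_genes[1])
  expect_equal(expr$delta_ct, rep(0, nrow(expr)))
  # fold 2 in LAB: housekeeping-normalized expression ratio is exactly 2
  plate2 <- synth_qpcr_plate(cfg, "Ctsb", c(HAB = 1, LAB = 2))
  expr2 <- ddct_quantify(plate2, "Ctsb", "Gapdh")
  by_group <- tapply(expr2$rel_expr, expr2$group, mean)
  expect_equal(unname(by_group["LAB"] / by_group["HAB"]), 2, tolerance = 1e-12)
})

test_that("behaviour generator applies genotype shifts and validates sizes", {
  cfg <- synth_config(seed = 3, behavior_n = 10,
                      behavior_effect = list(floating = c(KO = 3)))
  b <- synth_behavior(cfg)
  expect_equal(nrow(b), 10 * 3 * 2)
  mn <- tapply(b$value, b$genotype, mean)
  expect_gt(mn["KO"] - mn["WT"], 1.5)
  cfg0 <- synth_config(seed = 3, behavior_n = 0)
  expect_error(synth_behavior(cfg0), "positive group size")
})

test_that("large genotype shifts are detected by the rank-test chain", {
  cfg <- function(s) synth_config(seed = s, behavior_n = 15,
                                  behavior_effect = list(e = c(KO = 3)))
  hits <- vapply(1:50, function(s) {
    b <- synth_behavior(cfg(s))
    kruskal_wallis(b, "value", "genotype")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_probes = 10, n_de_probes = 20), "exceed")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(de_fold_range = c(-1, 2)), "positive")
  expect_error(synth_config(n_probes = 100, n_de_probes = 0, n_subarrays = 7),
               "divide")
})
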