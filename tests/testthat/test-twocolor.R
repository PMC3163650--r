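spot_tbl <- function(R, G, block = 1L, orientation = "HAB_Cy5",
                     array_id = "a1") {
  tibble::tibble(array_id = array_id, orientation = orientation,
                 probe_id = sprintf("p%03d", seq_along(R)),
                 block = block, R = R, G = G)
}

test_that("ma_transform computes M and A and flags zero intensities", {
  ma <- ma_transform(spot_tbl(R = c(100, 1024, 0), G = c(100, 256, 50)))
  expect_equal(ma$M[1:2], c(0, 2))
  expect_equal(ma$A[1:2], c(log2(100), 9))
  expect_true(ma$flagged[3])
  expect_true(is.na(ma$M[3]) && is.na(ma$A[3]))
  expect_equal(unique(ma$state), "raw")
  expect_error(ma_transform(spot_tbl(R = c(0, 0), G = c(1, 1))),
               "no usable spots")
  expect_error(ma_transform(spot_tbl(R = -1, G = 1)), "finite and >= 0")
})

test_that("global normalization zeroes the median and records c", {
  ma <- ma_transform(spot_tbl(R = 2 * c(8, 8, 8), G = c(8, 8, 8)))
  g <- normalize_global(ma)
  expect_equal(g$M, c(0, 0, 0))
  expect_equal(attr(g, "correction")$c_global, 1)
  # symmetric M about 0 is unchanged
  ma2 <- ma_transform(spot_tbl(R = c(512, 128, 256), G = c(256, 256, 256)))
  g2 <- normalize_global(ma2)
  expect_equal(g2$M, ma2$M)
  # state machine: refuses wrong input state
  expect_error(normalize_global(g), "state 'raw'")
  expect_error(normalize_loess(ma), "state 'global'")
  expect_error(normalize_subarray(g), "state 'loess'")
})

test_that("global normalization recovers a planted constant bias exactly", {
  cfg <- cfg_clean(n_probes = 200)
  tc <- synth_twocolor(cfg, "Cg")
  arrays <- dplyr::mutate(tc$arrays, R = .data$R * 2^0.3)
  g <- normalize_global(ma_transform(arrays))
  expect_equal(attr(g, "correction")$c_global,
               rep(0.3, cfg$n_arrays_per_region), tolerance = 1e-12)
  expect_equal(median(g$M[g$array_id == "Cg_a01"]), 0, tolerance = 1e-12)
})

test_that("loess normalization removes a planted smooth dye bias", {
  set.seed(11)
  n <- 24192
  A <- runif(n, 6, 14)
  bias <- 0.5 * sin(A * pi / max(A))
  arrays <- tibble::tibble(array_id = "a1", orientation = "HAB_Cy5",
                           probe_id = sprintf("p%05d", 1:n), block = 1L,
                           R = 2^(A + bias / 2), G = 2^(A - bias / 2))
  out <- arrays |> ma_transform() |> normalize_global() |> normalize_loess()
  expect_lt(max(abs(out$M)), 0.02)
  curve <- attr(out, "curve")
  expect_true(all(c("array_id", "A", "c_hat") %in% names(curve)))
  # identically-zero M stays zero with a ~zero fitted curve
  flat <- arrays |> dplyr::mutate(R = G) |> ma_transform() |>
    normalize_global() |> normalize_loess()
  expect_equal(flat$M, rep(0, n))
  expect_lt(max(abs(attr(flat, "curve")$c_hat)), 1e-12)
})

test_that("loess on constant-bias data agrees with global normalization", {
  set.seed(3)
  n <- 600
  A <- runif(n, 6, 14)
  arrays <- tibble::tibble(array_id = "a1", orientation = "HAB_Cy5",
                           probe_id = sprintf("p%04d", 1:n), block = 1L,
                           R = 2^(A + 0.15), G = 2^(A - 0.15))
  g <- arrays |> ma_transform() |> normalize_global()
  l <- normalize_loess(g, span = 1)
  expect_lt(max(abs(l$M - g$M)), 1e-6)
})

test_that("loess fit requires at least 10 usable spots", {
  arrays <- spot_tbl(R = 2^runif(5, 5, 8), G = 2^runif(5, 5, 8))
  expect_error(arrays |> ma_transform() |> normalize_global() |>
                 normalize_loess(), "fewer than 10 usable spots")
  expect_error(normalize_loess(
    ma_transform(spot_tbl(R = rep(2, 20), G = rep(1, 20))) |> normalize_global(),
    span = 2), "fraction")
})

test_that("sub-array balancing removes planted block offsets exactly", {
  # constructed at state loess so the step is tested in isolation
  off <- c(0.2, -0.2, 0.1, -0.1)
  ma <- tibble::tibble(array_id = "a1", orientation = "HAB_Cy5",
                       probe_id = sprintf("p%03d", 1:80),
                       block = rep(1:4, each = 20),
                       A = 8, flagged = FALSE,
                       M = off[rep(1:4, each = 20)], state = "loess")
  out <- normalize_subarray(ma)
  expect_identical(out$M, rep(0, 80))
  # idempotence: a second pass subtracts zero
  again <- out
  again$state <- "loess"
  expect_identical(normalize_subarray(again)$M, out$M)
  # a block without usable spots is left unchanged, with a warning
  ma$M[ma$block == 2] <- NA
  expect_warning(out2 <- normalize_subarray(ma), "without usable spots")
  expect_true(all(is.na(out2$M[out2$block == 2])))
  expect_identical(out2$M[out2$block == 1], rep(0, 20))
})

test_that("single-block balancing equals overall median subtraction", {
  set.seed(8)
  arrays <- spot_tbl(R = 2^runif(40, 5, 10), G = 2^runif(40, 5, 10))
  l <- arrays |> ma_transform() |> normalize_global() |> normalize_loess(span = 1)
  s <- normalize_subarray(l)
  expect_equal(s$M, l$M - median(l$M), tolerance = 1e-12)
})

test_that("orientation flips sign and stacking aligns probes by id", {
  base <- spot_tbl(R = c(1024, 64), G = c(256, 256))
  swapped <- base |>
    dplyr::mutate(array_id = "a2", orientation = "LAB_Cy5",
                  R = base$G, G = base$R)
  ma <- dplyr::bind_rows(base, swapped) |> ma_transform()
  ma$state <- "subarray"
  stacked <- orient_and_stack(ma)
  expect_equal(stacked$a1, stacked$a2)
  # a probe present on one array only keeps a missing cell
  ma2 <- dplyr::bind_rows(base,
                          swapped[1, ]) |> ma_transform()
  ma2$state <- "subarray"
  st2 <- orient_and_stack(ma2)
  expect_true(is.na(st2$a2[st2$probe_id == "p002"]))
  bad <- dplyr::mutate(ma, orientation = "Cy5")
  expect_error(orient_and_stack(bad), "unknown orientation")
})

test_that("the pipeline is equivariant under a global channel swap", {
  cfg <- cfg_small(seed = 21)
  tc <- synth_twocolor(cfg, "NAc")
  swapped <- tc$arrays |>
    dplyr::mutate(tmp = .data$R, R = .data$G, G = .data$tmp, tmp = NULL,
                  orientation = ifelse(.data$orientation == "HAB_Cy5",
                                       "LAB_Cy5", "HAB_Cy5"))
  s1 <- normalize_twocolor(tc$arrays)
  s2 <- normalize_twocolor(swapped)
  expect_identical(s1, s2)
})

test_that("full synthetic region recovers planted folds after stacking", {
  cfg <- cfg_small(seed = 33, noise_sd = 0.1)
  tc <- synth_twocolor(cfg, "CeA")
  stack <- normalize_twocolor(tc$arrays)
  planted <- tc$truth[tc$truth$fold != 1, ]
  m <- as.matrix(dplyr::select(stack, -"probe_id"))
  est <- rowMeans(m)[match(planted$probe_id, stack$probe_id)]
  expect_equal(unname(est), planted$log2_ratio, tolerance = 0.25)
  # non-DE probes: per-A-decile median M close to zero
  null_rows <- !stack$probe_id %in% planted$probe_id
  dec <- cut(tc$truth$baseline_A[match(stack$probe_id, tc$truth$probe_id)][null_rows], 10)
  med <- tapply(rowMeans(m)[null_rows], dec, median)
  expect_lt(max(abs(med)), 0.05)
})
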