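# Convert a wide probe-by-array tibble (or matrix) to a numeric matrix
# with probe ids as rownames.
stack_matrix <- function(stack) {
  if (is.matrix(stack)) {
    if (is.null(rownames(stack))) rownames(stack) <- sprintf("P%05d", seq_len(nrow(stack)))
    return(stack)
  }
  assert_cols(stack, "probe_id")
  m <- as.matrix(dplyr::select(stack, -"probe_id"))
  storage.mode(m) <- "double"
  rownames(m) <- stack$probe_id
  m
}

#' Per-probe location statistics on an oriented M stack
#'
#' For each probe, across the replicate arrays of one region, computes the
#' mean oriented log ratio `mean_M`, the one-sample statistic
#' `t_raw = mean_M / (sd / sqrt(n))`, and the fold expressed as percent
#' (100 * 2^mean_M, so values above 100 mean higher expression in the
#' high-anxiety line). Probes with fewer than two non-missing values are
#' dropped with a warning; probes with zero spread get an infinite
#' statistic, ranked above every finite one.
#'
#' @param stack Wide tibble (`probe_id` + one column per array) from
#'   [orient_and_stack()], or an equivalent numeric matrix.
#' @return Tibble `probe_id`, `n_arrays`, `mean_M`, `t_raw`, `fold_pct`,
#'   `regulation_pct` (percent regulation on the magnitude ratio scale,
#'   `100 * (2^|mean_M| - 1)`).
#' @examples
#' probe_stats(tibble::tibble(probe_id = "p1", a = 0.8, b = 1.2, c = 1, d = 1))
#' @export
probe_stats <- function(stack) {
  m <- stack_matrix(stack)
  if (nrow(m) == 0 || ncol(m) == 0) abort("empty stack")
  n <- rowSums(!is.na(m))
  drop <- n < 2
  if (all(drop)) abort("no probe has >= 2 non-missing values")
  if (any(drop)) {
    warn(sprintf("%d probe(s) with fewer than 2 observations dropped", sum(drop)))
    m <- m[!drop, , drop = FALSE]
    n <- n[!drop]
  }
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums(m^2, na.rm = TRUE)
  v <- (ss - n * mu^2) / (n - 1)
  v[v < 0] <- 0  # guard tiny negative round-off
  t_raw <- ifelse(v <= 1e-300, sign(mu) * Inf, mu / sqrt(v / n))
  t_raw[v <= 1e-300 & mu == 0] <- 0
  tibble::tibble(
    probe_id = rownames(m), n_arrays = as.integer(unname(n)),
    mean_M = unname(mu), t_raw = unname(t_raw),
    fold_pct = unname(100 * 2^mu),
    regulation_pct = unname(100 * (2^abs(mu) - 1))
  )
}

#' Permutation-adjusted p-values by step-down maxT
#'
#' Family-wise-error-controlling adjusted p-values for the per-probe
#' one-sample statistics of an oriented M stack, using the Westfall-Young
#' step-down maxT procedure. The permutation null flips the sign of whole
#' array columns, which is the exact exchangeability provided by the
#' dye-swap design: under the null of no line difference, each array's
#' oriented M vector is symmetric about zero.
#'
#' Adjusted p-values follow the add-one convention
#' `p = (1 + b) / (1 + B)`, where `b` counts permutations whose step-down
#' successive-maximum null `|t|` reaches the observed `|t|`, so p-values are
#' never zero. If `2^n_arrays <= n_perm` the `B = 2^n_arrays` sign
#' assignments are enumerated completely (the identity flip is part of the
#' orbit and always counts); otherwise `B = n_perm` random sign vectors are
#' drawn. Monotonicity in the rank of `|t_raw|` is enforced.
#'
#' @param stack As in [probe_stats()].
#' @param n_perm Number of permutations requested.
#' @param seed Integer seed for the random sign draws (ignored under
#'   complete enumeration).
#' @return Tibble `probe_id`, `t_raw`, `p_adj` plus attribute `"n_perm"`
#'   (permutations actually used) and `"enumerated"`.
#' @export
permutation_adjust <- function(stack, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  m <- stack_matrix(stack)
  if (ncol(m) < 2) abort("need >= 2 arrays for a permutation test")
  st <- probe_stats(stack)
  m <- m[st$probe_id, , drop = FALSE]
  n_arr <- ncol(m)
  enumerated <- 2^n_arr <= n_perm
  if (enumerated) {
    # arrays x 2^n matrix, one complete sign assignment per column
    S <- t(as.matrix(expand.grid(rep(list(c(-1L, 1L)), n_arr))))
  } else {
    S <- with_seed(derive_seed(seed, "signflip"), {
      matrix(sample(c(-1L, 1L), n_arr * n_perm, replace = TRUE), n_arr, n_perm)
    })
  }
  S <- matrix(as.integer(S), nrow = n_arr)
  dimnames(S) <- NULL
  Xz <- m
  Xz[is.na(Xz)] <- 0
  ss <- rowSums(m^2, na.rm = TRUE)
  # observed |t| from the same compiled arithmetic as the permutation loop,
  # so the identity flip reproduces it exactly under enumeration
  tabs <- .perm_obs_t(Xz, st$n_arrays, ss)
  ord <- order(tabs) - 1L  # ascending |t|, 0-based for C++
  counts <- .perm_stepdown_counts(Xz, st$n_arrays, ss, S, ord, tabs)
  p <- (1 + counts) / (1 + ncol(S))
  # enforce step-down monotonicity: p non-decreasing as |t| decreases
  o_desc <- order(tabs, decreasing = TRUE)
  p[o_desc] <- cummax(p[o_desc])
  out <- tibble::tibble(probe_id = st$probe_id, t_raw = st$t_raw, p_adj = pmin(p, 1))
  attr(out, "n_perm") <- if (enumerated) 2^n_arr else n_perm
  attr(out, "enumerated") <- enumerated
  out
}

#' Permutation differential-expression analysis of one region
#'
#' Combines [probe_stats()] and [permutation_adjust()] into one fitted
#' result object with [tidy()] / [glance()] / [autoplot()] methods.
#'
#' @inheritParams permutation_adjust
#' @param region Optional region label stored with the result.
#' @return An object of class `de_result`.
#' @export
de_permutation <- function(stack, n_perm = 1000L, seed = 1L, region = NA_character_) {
  st <- probe_stats(stack)
  pa <- permutation_adjust(stack, n_perm = n_perm, seed = seed)
  tab <- dplyr::left_join(st, dplyr::select(pa, "probe_id", "p_adj"), by = "probe_id")
  structure(list(table = tab, region = region,
                 n_perm = attr(pa, "n_perm"),
                 enumerated = attr(pa, "enumerated"),
                 seed = seed, n_arrays = max(st$n_arrays)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result>", if (!is.na(x$region)) paste0("region ", x$region), "\n")
  cat(sprintf("  %d probes, %d arrays, %d permutations%s\n",
              nrow(x$table), x$n_arrays, x$n_perm,
              if (x$enumerated) " (complete enumeration)" else ""))
  cat(sprintf("  probes with p_adj < 0.05: %d\n", sum(x$table$p_adj < 0.05)))
  invisible(x)
}

#' Quantile normalization of a single-channel expression matrix
#'
#' Maps every sample column of a probe-by-sample intensity table to the mean
#' quantile profile of the log2 intensities, so all column quantiles agree
#' after the operation. Non-positive intensities are flagged missing before
#' the log transform. The mapping is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param exprs Tibble `probe_id` plus positive intensity columns, or a
#'   numeric matrix.
#' @return A tibble of the same shape on the log2 scale, quantile
#'   normalized.
#' @export
normalize_singlechannel <- function(exprs) {
  m <- stack_matrix(exprs)
  if (ncol(m) < 2) abort("need >= 2 samples")
  if (any(m <= 0, na.rm = TRUE)) {
    warn("non-positive intensities flagged missing before log transform")
    m[m <= 0] <- NA
  }
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  lm2 <- log2(m)
  norm <- limma::normalizeQuantiles(lm2, ties = TRUE)
  dimnames(norm) <- dimnames(m)
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                   tibble::as_tibble(norm))
}

# Solve trigamma(x) = y by Newton iteration (y > 0).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

# Moment-matching fit of the scaled-F model for residual variances:
# s^2 ~ s0^2 * (chi^2_d / d) * (d0 / chi^2_d0), i.e. log s^2 has mean
# log s0^2 + digamma offsets and excess spread trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- var(z)
  excess <- ev - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-statistics for the single-channel path
#'
#' Ranks probes by an empirical-Bayes moderated t-statistic: per-probe
#' pooled variances are shrunk towards a prior variance `s0^2` with prior
#' degrees of freedom `d0`,
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and the group-mean difference is tested against
#' \eqn{\tilde{s}\sqrt{1/n_1 + 1/n_2}} on \eqn{d_0 + d} degrees of freedom.
#' The hyperparameters are estimated by closed-form moment matching on the
#' log residual variances (a scaled-F model). If the variance spread is not
#' wider than pure chi-square sampling noise the fit is degenerate
#' (`d0 = Inf`); if the fit cannot proceed at all the function falls back to
#' the ordinary t-test with a message.
#'
#' @param exprs Normalized log2 expression tibble (`probe_id` + sample
#'   columns) or matrix, e.g. from [normalize_singlechannel()].
#' @param groups Factor/character vector, one entry per sample column,
#'   with exactly two levels.
#' @param prior_df Optional override of the prior degrees of freedom `d0`
#'   (0 recovers the ordinary t-test, `Inf` a common-variance z-like
#'   statistic).
#' @return An object of class `modt_fit`; [tidy()] returns per-probe
#'   `log_ratio`, `t_mod`, `p_mod`, [glance()] the hyperparameters.
#' @export
moderated_t <- function(exprs, groups, prior_df = NULL) {
  m <- stack_matrix(exprs)
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) abort("`groups` must match the sample columns")
  lev <- unique(groups)
  if (length(lev) != 2) abort("exactly two groups required")
  m1 <- m[, groups == lev[1], drop = FALSE]
  m2 <- m[, groups == lev[2], drop = FALSE]
  n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
  if (any(n1 < 2) || any(n2 < 2)) abort("each group needs n >= 2 per probe")
  mu1 <- rowMeans(m1, na.rm = TRUE); mu2 <- rowMeans(m2, na.rm = TRUE)
  ss1 <- rowSums((m1 - mu1)^2, na.rm = TRUE)
  ss2 <- rowSums((m2 - mu2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  if (is.null(prior_df)) {
    prior <- tryCatch(fit_variance_prior(s2, df = stats::median(df)),
                      error = function(e) NULL)
    if (is.null(prior) || !is.finite(prior$s0_sq) || prior$s0_sq <= 0) {
      inform("degenerate variance prior; falling back to ordinary t")
      prior <- list(d0 = 0, s0_sq = NA_real_)
    }
  } else {
    prior <- list(d0 = prior_df,
                  s0_sq = if (is.finite(prior_df) && prior_df == 0) NA_real_
                          else exp(mean(log(s2[s2 > 0]))))
  }
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) rep(prior$s0_sq, length(s2))
              else if (d0 == 0) s2
              else (d0 * prior$s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  diff <- mu1 - mu2
  t_mod <- diff / se
  df_tot <- d0 + df
  p_mod <- 2 * pt(-abs(t_mod), df = ifelse(is.finite(df_tot), df_tot, 1e6))
  structure(list(
    table = tibble::tibble(probe_id = rownames(m), log_ratio = unname(diff),
                           s2 = unname(s2), t_mod = unname(t_mod),
                           p_mod = unname(p_mod)),
    d0 = d0, s0_sq = prior$s0_sq, groups = lev, df_residual = stats::median(df)
  ), class = "modt_fit")
}

#' @export
print.modt_fit <- function(x, ...) {
  cat("<modt_fit>", paste(x$groups, collapse = " vs "), "\n")
  cat(sprintf("  %d probes, prior df d0 = %s, prior variance s0^2 = %s\n",
              nrow(x$table), format(x$d0, digits = 4), format(x$s0_sq, digits = 4)))
  invisible(x)
}
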