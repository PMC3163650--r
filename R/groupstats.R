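#' Kruskal-Wallis rank test over two or more groups
#'
#' Rank-based H statistic with mid-rank tie correction and a chi-square
#' approximation on k - 1 degrees of freedom (via [stats::kruskal.test()]).
#' For small samples (`total n <= exact_max_n`, default 10) an exact
#' permutation p-value over all distinct group assignments can be requested
#' instead.
#'
#' @param data Tibble with one observation per row.
#' @param value,group Column names (strings) of the measurement and the
#'   group label.
#' @param exact If `TRUE` and the total sample size allows, compute the
#'   exact permutation p-value of H by complete enumeration.
#' @param exact_max_n Largest total n for which enumeration is attempted.
#' @return One-row tibble `statistic` (H), `df`, `p_value`, `method`.
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' kruskal_wallis(d, "y", "g")
#' @export
kruskal_wallis <- function(data, value = "value", group = "group",
                           exact = FALSE, exact_max_n = 10L) {
  assert_cols(data, c(value, group))
  y <- data[[value]]; g <- factor(data[[group]])
  if (any(!is.finite(y))) abort("values must be finite")
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (any(table(g) < 1) || length(y) < 3) abort("each group needs n >= 1, total n >= 3")
  if (length(unique(y)) == 1) {
    warn("all observations identical; H = 0 by convention")
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                          method = "degenerate"))
  }
  kw <- kruskal.test(y, g)
  if (exact && length(y) <= exact_max_n) {
    p <- kw_exact_p(y, g)
    return(tibble::tibble(statistic = unname(kw$statistic),
                          df = unname(kw$parameter), p_value = p,
                          method = "exact permutation"))
  }
  tibble::tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, method = "chi-square approximation")
}

# Exact permutation p-value of the (tie-corrected) H statistic by complete
# enumeration of all distinct assignments of observations to group sizes.
kw_exact_p <- function(y, g) {
  sizes <- as.integer(table(g))
  n <- length(y)
  h_stat <- function(assign) {
    suppressWarnings(unname(kruskal.test(y, factor(assign))$statistic))
  }
  obs <- h_stat(g)
  assigns <- enumerate_assignments(n, sizes)
  hs <- vapply(assigns, h_stat, numeric(1))
  mean(hs >= obs - 1e-12)
}

# All assignments of n items into ordered groups of the given sizes,
# as vectors of group indices.
enumerate_assignments <- function(n, sizes) {
  rec <- function(avail, sizes_left, g_idx, current) {
    if (length(sizes_left) == 0) return(list(current))
    if (length(sizes_left) == 1) {
      current[avail] <- g_idx
      return(list(current))
    }
    picks <- combn(avail, sizes_left[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      cur <- current
      cur[p] <- g_idx
      out <- c(out, rec(setdiff(avail, p), sizes_left[-1], g_idx + 1L, cur))
    }
    out
  }
  rec(seq_len(n), sizes, 1L, integer(n))
}

#' Mann-Whitney U test for two groups
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]: exact enumeration
#' when both groups are small and the data are tie-free, otherwise the
#' tie-corrected normal approximation. The reported U is the number of
#' (A, B) pairs with A ranked above B.
#'
#' @param a,b Numeric vectors of observations for the two groups.
#' @param exact `NULL` (decide automatically), `TRUE`, or `FALSE`.
#' @return One-row tibble `u`, `p_value`, `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact && !ties, correct = TRUE)
  )
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    method = if (exact && !ties) "exact enumeration" else "normal approximation (tie-corrected)"
  )
}

#' Holm step-down (sequential Bonferroni) correction
#'
#' Sorts p-values ascending and compares `p_(i) <= alpha / (m - i + 1)`,
#' rejecting until the first failure. Adjusted p-values are the
#' monotone-enforced `min(1, (m - i + 1) * p_(i))`; the rejection set
#' equals `p_adj <= alpha`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise error level.
#' @return Tibble `p`, `p_adj`, `reject`, in the input order.
#' @examples
#' sequential_bonferroni(c(0.01, 0.04, 0.03))
#' @export
sequential_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p_adj <- p.adjust(p, method = "holm")
  tibble::tibble(p = p, p_adj = p_adj, reject = !is.na(p_adj) & p_adj <= alpha)
}

#' Gated nonparametric multi-group comparison
#'
#' The reporting chain of the emulated study for qPCR folds and behavioural
#' endpoints: an omnibus Kruskal-Wallis test per endpoint (and optional sex
#' stratum); when its p-value falls below `gate_p`, all pairwise
#' Mann-Whitney tests followed by Holm (sequential Bonferroni) correction.
#'
#' @param data Tibble of observations.
#' @param value,group Column names of measurement and group.
#' @param gate_p Omnibus p-value below which pairwise tests are run.
#' @param alpha Level for the Holm decisions.
#' @param exact Passed to [kruskal_wallis()] and [mann_whitney()].
#' @return An object of class `group_comparison` with elements `omnibus`
#'   (tibble) and `pairwise` (tibble, empty when gated off); [tidy()]
#'   returns the pairwise table, [glance()] the omnibus row.
#' @export
group_compare <- function(data, value = "value", group = "group",
                          gate_p = 0.10, alpha = 0.05, exact = NULL) {
  omnibus <- kruskal_wallis(data, value, group, exact = isTRUE(exact))
  pairwise <- tibble::tibble(group1 = character(), group2 = character(),
                             u = numeric(), p = numeric(),
                             p_adj = numeric(), reject = logical())
  if (omnibus$p_value < gate_p) {
    g <- factor(data[[group]])
    pairs <- combn(levels(g), 2, simplify = FALSE)
    rows <- purrr::map_dfr(pairs, function(pr) {
      mw <- mann_whitney(data[[value]][g == pr[1]], data[[value]][g == pr[2]],
                         exact = exact)
      tibble::tibble(group1 = pr[1], group2 = pr[2], u = mw$u, p = mw$p_value)
    })
    adj <- sequential_bonferroni(rows$p, alpha = alpha)
    pairwise <- dplyr::bind_cols(rows, adj[, c("p_adj", "reject")])
  }
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 gate_p = gate_p, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  KWH: H = %.4g, df = %d, p = %.4g (%s)\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value,
              x$omnibus$method))
  if (nrow(x$pairwise) == 0) {
    cat(sprintf("  pairwise tests gated off (omnibus p >= %.2g)\n", x$gate_p))
  } else {
    print(x$pairwise)
  }
  invisible(x)
}
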