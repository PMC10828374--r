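# Statistical kernel: the rank tests, FDR control and exact tests the
# screens are built from, plus the two permutation engines the analysis
# rests on (hen-label permutation of a median difference; paired
# within-hen permutation of a noise-trajectory slope difference).

check_numeric_input <- function(x, what, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    abort(paste0("`", what, "` must be numeric with at least ",
                 min_len, " values."))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(paste0("`", what, "` contains missing or non-finite values."))
  }
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p-value by enumeration when the pooled sample is small
#' (`n1 + n2 <= 14`) and tie-free; otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `method`.
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_test <- function(x, y) {
  check_numeric_input(x, "x", 2L)
  check_numeric_input(y, "y", 2L)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 14) && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  p <- res$p.value
  if (is.nan(p)) p <- 1  # fully tied data: zero-variance rank statistic
  tibble(statistic = unname(res$statistic), p_value = min(p, 1),
         method = if (exact) "mann-whitney-exact" else "mann-whitney-normal")
}

# Fast path used in the per-feature screens: p-value only.
mw_p <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 14) && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
  if (is.nan(p)) 1 else min(p, 1)
}

#' Spearman rank correlation with p-value
#'
#' Rho is the Pearson correlation of (average) ranks; the p-value uses the
#' exact permutation distribution for `n <= 10` and the t-approximation
#' above that (the regime the pooled-cohort screens operate in).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `statistic` (rho), `p_value`, `method`.
#' @export
spearman_test <- function(x, y) {
  check_numeric_input(x, "x", 3L)
  check_numeric_input(y, "y", 3L)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation is undefined for constant input.")
  }
  exact <- length(x) <= 10
  res <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact)
  )
  tibble(statistic = unname(res$estimate), p_value = res$p.value,
         method = if (exact) "spearman-exact" else "spearman-t")
}

spearman_rho_p <- function(x, y) {
  r <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(r$estimate), p = r$p.value)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param q_cutoff FDR level (default 0.1).
#' @return List with `q_values` (monotone-adjusted p-values) and `rejected`
#'   (logical; `q_values <= q_cutoff`).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.2), q_cutoff = 0.1)
#' @export
bh_adjust <- function(p_values, q_cutoff = 0.1) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = q <= q_cutoff)
}

#' Permutation test on a difference of group medians
#'
#' Hens are permuted between the two groups and the number of permuted
#' configurations whose median difference is equal to or bigger than the
#' observed one, divided by the number of permutations, is the p-value.
#' The default statistic is the absolute median difference (two-sided);
#' `alternative = "greater"` uses the signed difference
#' `median(a) - median(b)`.
#'
#' The p-value is exactly `n_extreme / n_perm`, so it can be zero; raise
#' `n_perm` when finer resolution is needed.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @param alternative `"two.sided"` (absolute difference) or `"greater"`.
#' @return A `perm_test` object: `observed_stat`, `n_extreme`, `n_perm`,
#'   `p_value`.
#' @examples
#' perm_median_diff(rnorm(8), rnorm(8) + 2, n_perm = 200, seed = 1)
#' @export
perm_median_diff <- function(a, b, n_perm = 1000L, seed = NULL,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  check_numeric_input(a, "a")
  check_numeric_input(b, "b")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  stat <- function(g1, g2) {
    d <- median(g1) - median(g2)
    if (alternative == "two.sided") abs(d) else d
  }
  obs <- stat(a, b)
  pooled <- c(a, b)
  na <- length(a)
  n_extreme <- with_rng_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      stat(pooled[idx], pooled[-idx]) >= obs - 1e-12
    }, logical(1)))
  })
  new_perm_test(obs, n_extreme, n_perm,
                method = paste0("median-diff-", alternative))
}

#' Paired within-hen permutation test on noise-trajectory slopes
#'
#' The statistic is the ordinary-least-squares slope of group A's
#' per-month noise trajectory (across-hen CV per month) minus group B's,
#' over a common window of months. Because the hens are followed
#' longitudinally, the null shuffles each hen's values across months
#' independently *within that hen*, recomputes the per-month CVs and their
#' slopes, and counts permuted differences at least as extreme as the
#' observed one in its own direction (one-sided).
#'
#' With `alternative = "auto"` (the default) the rejection direction is
#' taken from the observed sign; because the direction is then data-driven,
#' the test's null rejection rate at level alpha is close to 2 alpha. Use a
#' prespecified `"greater"`/`"less"` (slope of A minus slope of B) when the
#' direction is known in advance and exact nominal calibration matters.
#'
#' @param series_a,series_b Numeric matrices, hens in rows, months in
#'   columns; column names give the month values (consecutive indices are
#'   assumed otherwise). At least 3 months.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @param alternative `"auto"` (direction of the observed difference),
#'   `"greater"`, or `"less"`.
#' @return A `perm_test` object.
#' @export
perm_slope_diff_paired <- function(series_a, series_b, n_perm = 1000L,
                                   seed = NULL,
                                   alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  for (m in list(series_a, series_b)) {
    if (!is.matrix(m) || ncol(m) < 3) {
      abort("Each series must be a matrix with >= 3 month columns (slope is unstable on fewer).")
    }
    if (anyNA(m)) abort("Series contain missing values.")
    if (any(colMeans(m) <= 0)) {
      abort("Each month's mean must be positive (CV trajectories are defined on positive values).")
    }
  }
  if (ncol(series_a) != ncol(series_b)) {
    abort("Groups must share the same month window.")
  }
  months <- suppressWarnings(as.numeric(colnames(series_a)))
  if (length(months) != ncol(series_a) || anyNA(months)) {
    months <- seq_len(ncol(series_a))
  }
  stat <- function(a, b) {
    cv_a <- apply(a, 2, sd) / colMeans(a)
    cv_b <- apply(b, 2, sd) / colMeans(b)
    ols_slope(months, cv_a) - ols_slope(months, cv_b)
  }
  obs <- stat(series_a, series_b)
  s <- switch(alternative,
              auto = if (obs >= 0) 1 else -1,
              greater = 1,
              less = -1)
  shuffle_rows <- function(m) {
    t(apply(m, 1, sample))
  }
  n_extreme <- with_rng_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      s * stat(shuffle_rows(series_a), shuffle_rows(series_b)) >=
        s * obs - 1e-12
    }, logical(1)))
  })
  new_perm_test(obs, n_extreme, n_perm, method = "paired-slope-diff")
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

new_perm_test <- function(observed_stat, n_extreme, n_perm, method) {
  structure(
    list(observed_stat = observed_stat, n_extreme = n_extreme,
         n_perm = n_perm, p_value = n_extreme / n_perm, method = method),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$method, ": stat = ", signif(x$observed_stat, 4),
      ", p = ", x$n_extreme, "/", x$n_perm, " = ", signif(x$p_value, 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$observed_stat, n_extreme = x$n_extreme,
         n_perm = x$n_perm, p_value = x$p_value, method = x$method)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided exact p-value (sum of hypergeometric probabilities no
#'   larger than the observed table's).
#' @examples
#' fisher_exact_2x2(matrix(c(10, 4, 1, 17), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2))) {
    abort("`table` must be a 2x2 matrix.")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be non-negative integers.")
  }
  fisher.test(table, alternative = "two.sided")$p.value
}

#' Two-sided binomial test comparing two groups' death counts
#'
#' Tests one group's death count against the other group's death
#' proportion taken as the null. The choice of which group supplies the
#' null proportion is a reporting convention, not a derivable fact, so
#' both directions are available.
#'
#' @param deaths_a,n_a Deaths and cohort size of group A.
#' @param deaths_b,n_b Deaths and cohort size of group B.
#' @param null Which group's proportion is the null hypothesis for the
#'   other's count: `"group_b"` (default; A's count tested against B's
#'   rate) or `"group_a"`.
#' @return Two-sided p-value.
#' @export
binomial_survival_test <- function(deaths_a, n_a, deaths_b, n_b,
                                   null = c("group_b", "group_a")) {
  null <- match.arg(null)
  if (n_a < 1 || n_b < 1) abort("Both groups must be non-empty.")
  if (deaths_a > n_a || deaths_b > n_b) abort("Deaths cannot exceed group size.")
  if (null == "group_b") {
    binom.test(deaths_a, n_a, p = deaths_b / n_b,
               alternative = "two.sided")$p.value
  } else {
    binom.test(deaths_b, n_b, p = deaths_a / n_a,
               alternative = "two.sided")$p.value
  }
}
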