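# The statistical battery used to evaluate the instruments:
# median/IQR on Tukey hinges, the Wilcoxon signed-rank test with exact
# sign enumeration for small samples, and the internal-consistency
# coefficients (Cronbach alpha and its dichotomous special case KR-20).

#' Median and interquartile range
#'
#' IQR is computed from Tukey hinges (`fivenum`), the convention used
#' throughout the package for descriptive summaries; set
#' `type = "quantile"` for the type-7 quantile convention instead.
#'
#' @param x numeric vector, `n >= 1` (NAs dropped).
#' @param type `"tukey"` (default) or `"quantile"`.
#' @return list with `median`, `iqr`, `q1`, `q3`, `n`.
#' @export
median_iqr <- function(x, type = c("tukey", "quantile")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  if (length(x) < 1L) contract_error("median_iqr: empty input")
  if (type == "tukey") {
    f <- stats::fivenum(x)
    q1 <- f[2]; q3 <- f[4]
  } else {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    q1 <- q[1]; q3 <- q[2]
  }
  list(median = stats::median(x), iqr = q3 - q1, q1 = q1, q3 = q3,
       n = length(x))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `post - pre` are ranked by absolute value with average
#' ranks for ties. Zero differences are handled per `zero_policy`:
#' `"discard"` (the classical Wilcoxon treatment, default) drops them
#' before ranking; `"pratt"` ranks them and then drops their ranks. The
#' p-value is exact — full enumeration of all `2^n` sign assignments,
#' valid under ties — when the effective sample size is at most
#' `exact_limit` (default 15) and `mode = "auto"`, otherwise a normal
#' approximation with tie-corrected variance (no continuity
#' correction) is used. When all differences are zero the test is
#' degenerate: `W` is `NA` and `p = 1` with a warning.
#'
#' @param pre,post paired numeric vectors of equal length >= 1.
#' @param zero_policy `"discard"` or `"pratt"`.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param alternative `"two.sided"` (default), `"greater"` (post > pre)
#'   or `"less"`.
#' @param exact_limit largest effective n for which `"auto"` enumerates.
#' @return list with `W` (sum of positive ranks), `Z`, `p_value`,
#'   `n_effective`, `n_zero`, `method`, `ties`.
#' @export
wilcoxon_signed_rank <- function(pre, post,
                                 zero_policy = c("discard", "pratt"),
                                 mode = c("auto", "exact", "normal"),
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 15L) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (length(pre) != length(post) || length(pre) < 1L)
    contract_error("wilcoxon_signed_rank: paired vectors of equal length >= 1 required")
  keep <- stats::complete.cases(pre, post)
  d <- post[keep] - pre[keep]
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    warning("all paired differences are zero; test is degenerate")
    return(list(W = NA_real_, Z = NA_real_, p_value = 1,
                n_effective = 0L, n_zero = n_zero,
                method = "degenerate", ties = FALSE))
  }
  if (zero_policy == "discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
    ranks <- r
    signs <- sign(d)
  } else {
    r <- rank(abs(d))
    ranks <- r[d != 0]
    signs <- sign(d[d != 0])
  }
  n_eff <- length(ranks)
  W <- sum(ranks[signs > 0])
  ties <- anyDuplicated(ranks) > 0L
  # tie-corrected normal moments (zeros already removed from `ranks`)
  mu <- sum(ranks) / 2
  tie_tab <- table(ranks)
  sigma2 <- sum(ranks^2) / 4
  Z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else NA_real_

  use_exact <- mode == "exact" || (mode == "auto" && n_eff <= exact_limit)
  if (use_exact && n_eff > 25L)
    contract_error("exact enumeration requested for n = %d (> 25)", n_eff)
  if (use_exact) {
    sums <- 0
    for (rk in ranks) sums <- c(sums, sums + rk)   # all 2^n subset sums
    tol <- 1e-9
    p_ge <- mean(sums >= W - tol)
    p_le <- mean(sums <= W + tol)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    p <- switch(alternative,
                greater = stats::pnorm(Z, lower.tail = FALSE),
                less = stats::pnorm(Z),
                two.sided = 2 * stats::pnorm(-abs(Z)))
    method <- "normal"
  }
  list(W = W, Z = Z, p_value = p, n_effective = n_eff, n_zero = n_zero,
       method = method, ties = ties)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / total variance)`, with
#' sample (n-1) variances; missing data handled by pairwise-complete
#' covariances. Returns `NA` with a warning when the total variance is
#' zero.
#'
#' @param item_matrix numeric matrix, respondents in rows, items (>= 2)
#'   in columns; at least 2 respondents.
#' @return alpha (a value <= 1, possibly negative).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L || nrow(m) < 2L)
    contract_error("cronbach_alpha: need >= 2 items and >= 2 respondents")
  C <- stats::cov(m, use = "pairwise.complete.obs")
  total <- sum(C)
  if (!is.finite(total) || total <= 0) {
    warning("total variance is zero or undefined; alpha is undefined")
    return(NA_real_)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / total)
}

#' Kuder-Richardson formula 20
#'
#' Internal consistency for dichotomously scored items: the Cronbach
#' alpha analogue with `p(1-p)` item variances. Item variances carry the
#' sample-size correction `n/(n-1)` so that on a complete 0/1 matrix
#' KR-20 equals [cronbach_alpha()] exactly; rows with missing values are
#' dropped (listwise) with a warning.
#'
#' @param binary_matrix matrix of 0/1 scores, respondents in rows.
#' @return the KR-20 coefficient (<= 1).
#' @export
kr20 <- function(binary_matrix) {
  m <- as.matrix(binary_matrix)
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sprintf("kr20: dropping %d incomplete row(s)", sum(!complete)))
    m <- m[complete, , drop = FALSE]
  }
  if (!all(m %in% c(0, 1)))
    contract_error("kr20: matrix must contain only 0/1 scores")
  n <- nrow(m); k <- ncol(m)
  if (k < 2L || n < 2L)
    contract_error("kr20: need >= 2 items and >= 2 complete respondents")
  p <- colMeans(m)
  item_var <- p * (1 - p) * n / (n - 1)
  total <- stats::var(rowSums(m))
  if (total <= 0) {
    warning("total variance is zero; KR-20 is undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(item_var) / total)
}

#' Pre/post comparison for a scored knowledge test
#'
#' Convenience wrapper pairing respondents present at both timepoints
#' (listwise), summarising each timepoint as median/IQR and running the
#' signed-rank test.
#'
#' @param pre,post named numeric vectors of scores; names are respondent
#'   ids used for pairing.
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return list with `summary_pre`, `summary_post`, `test`, `n_pairs`.
#' @export
compare_prepost <- function(pre, post, ...) {
  ids <- intersect(names(pre), names(post))
  if (length(ids) < 1L)
    contract_error("compare_prepost: no paired respondents")
  list(summary_pre = median_iqr(pre[ids]),
       summary_post = median_iqr(post[ids]),
       test = wilcoxon_signed_rank(pre[ids], post[ids], ...),
       n_pairs = length(ids))
}
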