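#' Friedman test with Kendall's W
#'
#' Friedman rank test over an n-blocks x k-treatments matrix. Within-block
#' ranks average ties; the statistic is
#' chi2 = 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1), referred to a
#' chi-square distribution with k - 1 degrees of freedom. Kendall's
#' concordance W = chi2 / (n (k - 1)) is attached as effect size. The tie
#' correction (dividing chi2 by 1 - sum(t^3 - t) / (n k (k^2 - 1))) is off
#' by default so the reported (chi2, W) pair always satisfies the identity
#' above; enable `tie_correct` for the classic corrected statistic.
#'
#' @param mat Numeric matrix, blocks in rows, treatments in columns, no
#'   missing cells, n >= 2 and k >= 2.
#' @param tie_correct Apply the tie correction to chi2 (default FALSE).
#' @return list of class `friedman_result`: `chi2`, `df`, `p`, `W`, `n`,
#'   `k`, `tie_correct`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6, 1, 5, 9), 3, byrow = TRUE)
#' friedman_w(m) # identical orderings: chi2 = n (k - 1), W = 1
friedman_w <- function(mat, tie_correct = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat))
    np_stop("napscope_design_error", "Friedman design has missing cells")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2)
    np_stop("napscope_design_error",
            "Friedman needs at least 2 blocks and 2 treatments")
  R <- t(apply(mat, 1, rank))
  chi2 <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  if (tie_correct) {
    tie_sum <- sum(apply(mat, 1, function(r) {
      t <- table(r); sum(t^3 - t)
    }))
    denom <- 1 - tie_sum / (n * k * (k^2 - 1))
    if (denom <= 0) chi2 <- 0 else chi2 <- chi2 / denom
  }
  chi2 <- max(0, chi2)
  structure(
    list(chi2 = chi2, df = k - 1,
         p = stats::pchisq(chi2, k - 1, lower.tail = FALSE),
         W = kendalls_w(chi2, n, k), n = n, k = k,
         tie_correct = tie_correct),
    class = "friedman_result"
  )
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman: chi2(%d) = %.3f, p = %.3g, W = %.3f (n = %d, k = %d)\n",
              x$df, x$chi2, x$p, x$W, x$n, x$k))
  invisible(x)
}

#' Kendall's W from a Friedman statistic
#'
#' W = chi2 / (n (k - 1)), the concordance effect size of a Friedman test
#' over n blocks and k treatments, in \[0, 1\].
#'
#' @param chi2 Friedman chi-square statistic (>= 0).
#' @param n Number of blocks (>= 1).
#' @param k Number of treatments (>= 2).
#' @return Kendall's W.
#' @export
#' @examples
#' kendalls_w(42.518, 10, 12) # 0.387
kendalls_w <- function(chi2, n, k) {
  if (chi2 < 0)
    np_stop("napscope_domain_error", "chi2 must be non-negative")
  if (n < 1 || k < 2)
    np_stop("napscope_domain_error", "need n >= 1 blocks and k >= 2 treatments")
  chi2 / (n * (k - 1))
}

# exact null distribution of W+ for (possibly tied) ranks, by polynomial
# convolution of the sign-flip generating function. Ranks are doubled so
# average ranks become integers; returns P(W+ = support/2).
signrank_dist <- function(r) {
  ri <- as.integer(round(2 * r))
  probs <- 1
  for (a in ri) probs <- c(probs, numeric(a)) / 2 + c(numeric(a), probs) / 2
  list(w = seq(0, sum(ri)) / 2, p = probs)
}

#' Wilcoxon signed-rank test with effect size r
#'
#' Paired signed-rank test. Zero differences are dropped; tied absolute
#' differences receive average ranks. The p-value is exact (full null
#' distribution of the rank sum, ties included) when the number of non-zero
#' pairs is at most `exact_max`, and a normal approximation with continuity
#' correction and tie-corrected variance otherwise. The standardized
#' statistic z is always reported, with effect size r = |z| / sqrt(n),
#' n counting non-zero pairs.
#'
#' @param x Numeric vector: first measurement, or differences if `y` NULL.
#' @param y Optional paired second measurement.
#' @param alternative "two.sided" (default), "greater" or "less"; sidedness
#'   refers to the location of `x - y`.
#' @param exact_max Largest n for which the exact p-value is used
#'   (default 12).
#' @return list of class `wilcoxon_result`: `w_plus`, `z`, `p`, `r`,
#'   `n_effective`, `method` ("exact" or "approx"), `alternative`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max = 12) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    np_stop("napscope_data_error",
            "all paired differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  dev <- w_plus - mu
  z <- if (v > 0) (dev - sign(dev) * 0.5) / sqrt(v) else 0
  if (n <= exact_max) {
    dist <- signrank_dist(r)
    eps <- 1e-9
    p <- switch(alternative,
      greater = sum(dist$p[dist$w >= w_plus - eps]),
      less = sum(dist$p[dist$w <= w_plus + eps]),
      two.sided = sum(dist$p[abs(dist$w - mu) >= abs(dev) - eps])
    )
    method <- "exact"
  } else {
    p <- switch(alternative,
      greater = stats::pnorm((dev - 0.5) / sqrt(v), lower.tail = FALSE),
      less = stats::pnorm((dev + 0.5) / sqrt(v)),
      two.sided = 2 * stats::pnorm(-abs(z))
    )
    p <- min(1, p)
    method <- "approx"
  }
  structure(
    list(w_plus = w_plus, z = z, p = p, r = abs(z) / sqrt(n),
         n_effective = n, method = method, alternative = alternative),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s, %s): W+ = %g, z = %.3f, p = %.3g, r = %.3f (n = %d)\n",
              x$alternative, x$method, x$w_plus, x$z, x$p, x$r,
              x$n_effective))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return list of class `correlation_result`: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n)
    np_stop("napscope_data_error",
            "Spearman needs equal-length vectors with n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    np_stop("napscope_data_error",
            "degenerate data: zero rank variance in Spearman correlation")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  structure(list(rho = rho, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman: rho = %.3f, p = %.3g (n = %d)\n", x$rho, x$p, x$n))
  invisible(x)
}

#' Bonferroni correction
#'
#' p_adj = min(1, m p) with m the family size (length of the input);
#' order preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    np_stop("napscope_domain_error", "p-values must lie in [0, 1]")
  pmin(1, length(p) * p)
}
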