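test_that("Friedman handles perfect concordance and full ties", {
  m <- matrix(c(1, 2, 3,
                2, 4, 6,
                1, 5, 9), 3, 3, byrow = TRUE)
  fr <- friedman_w(m)
  expect_equal(fr$chi2, 6)  # n (k - 1)
  expect_equal(fr$W, 1)
  expect_equal(fr$df, 2)

  m0 <- matrix(5, 4, 3)
  fr0 <- friedman_w(m0)
  expect_equal(fr0$chi2, 0)
  expect_equal(fr0$W, 0)
  expect_equal(fr0$p, 1)

  expect_error(friedman_w(matrix(c(1, NA, 2, 3), 2)),
               class = "napscope_design_error")
  expect_error(friedman_w(matrix(1:3, 1)), class = "napscope_design_error")
})

test_that("Friedman chi-square equals the brute-force rank-sum oracle on seeded matrices", {
  set.seed(1401)
  for (i in 1:100) {
    m <- matrix(rnorm(24), 6, 4)
    if (i %% 3 == 0) m <- round(m)  # induce ties in a third of the cases
    fr <- friedman_w(m)
    expect_equal(fr$chi2, oracle_friedman_chi2(m), tolerance = 1e-9)
    # the reported pair always satisfies the concordance identity
    expect_equal(fr$W, fr$chi2 / (fr$n * (fr$k - 1)), tolerance = 1e-12)
  }
})

test_that("tie-corrected Friedman matches the base R implementation", {
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(sample(1:5, 24, replace = TRUE), 6, 4)
    if (all(apply(m, 1, function(r) length(unique(r))) == 1)) next
    fr <- friedman_w(m, tie_correct = TRUE)
    ref <- stats::friedman.test(m)
    expect_equal(fr$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(fr$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Friedman is invariant to strictly monotone transforms within blocks", {
  set.seed(15)
  m <- matrix(rnorm(30), 10, 3)
  fr <- friedman_w(m)
  m2 <- t(apply(m, 1, function(r) exp(3 * r) - 1))
  expect_equal(friedman_w(m2)$chi2, fr$chi2, tolerance = 1e-12)
})

test_that("kendalls_w validates its domain", {
  expect_equal(kendalls_w(0, 10, 3), 0)
  expect_error(kendalls_w(-1, 10, 3), class = "napscope_domain_error")
  expect_error(kendalls_w(5, 10, 1), class = "napscope_domain_error")
})

test_that("Wilcoxon signed-rank: all-positive small sample has the textbook exact tail", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
  expect_equal(res$w_plus, 15)
  expect_equal(res$p, 1 / 32)  # single extreme assignment among 2^5
  expect_equal(res$method, "exact")
  expect_equal(res$n_effective, 5)
})

test_that("Wilcoxon is symmetric under sign flip and drops zero differences", {
  set.seed(9)
  d <- rnorm(10)
  a <- wilcoxon_signed_rank(d)
  b <- wilcoxon_signed_rank(-d)
  expect_equal(abs(a$z), abs(b$z))
  expect_equal(a$r, b$r)
  expect_equal(a$p, b$p)

  withz <- wilcoxon_signed_rank(c(0, 0, d))
  expect_equal(withz$n_effective, 10)
  expect_equal(withz$p, a$p)
  expect_error(wilcoxon_signed_rank(rep(0, 6)),
               class = "napscope_data_error")
})

test_that("exact Wilcoxon p equals full 2^n sign enumeration, ties included", {
  set.seed(1402)
  for (i in 1:60) {
    n <- sample(4:11, 1)
    d <- rnorm(n, mean = 0.4)
    if (i %% 2 == 0) d <- round(d, 1)  # ties in half the cases
    d <- d[d != 0]
    if (length(d) < 2) next
    for (alt in c("two.sided", "greater", "less")) {
      res <- wilcoxon_signed_rank(d, alternative = alt)
      expect_equal(res$p, oracle_wilcoxon_exact(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("untied exact Wilcoxon matches the base signed-rank distribution", {
  set.seed(88)
  for (i in 1:20) {
    d <- rnorm(9, 0.5)
    res <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon z matches a step-by-step normal-approximation oracle", {
  set.seed(1403)
  for (i in 1:20) {
    d <- rnorm(20, 0.3)
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$method, "approx")
    # oracle: rank |d|, sum positive ranks, tie-corrected variance,
    # continuity-corrected z
    r <- rank(abs(d))
    wp <- sum(r[d > 0])
    n <- length(d)
    mu <- n * (n + 1) / 4
    v <- n * (n + 1) * (2 * n + 1) / 24
    z <- (wp - mu - sign(wp - mu) * 0.5) / sqrt(v)
    expect_equal(res$z, z, tolerance = 1e-9)
    expect_equal(res$p, 2 * pnorm(-abs(z)), tolerance = 1e-9)
    expect_equal(res$r, abs(z) / sqrt(n), tolerance = 1e-9)
  }
})

test_that("exact and approximate Wilcoxon p stay within the verified bound at n = 12", {
  # the continuity-corrected normal approximation deviates from the exact
  # symmetric-tail p by at most 0.0137 anywhere on the untied n = 12
  # support (worst in mid-range p); 0.015 is the documented bound
  set.seed(1404)
  for (i in 1:100) {
    d <- rnorm(12, 0.3)
    pe <- wilcoxon_signed_rank(d, exact_max = 12)$p
    pa <- wilcoxon_signed_rank(d, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.015)
  }
})

test_that("Spearman recovers monotone association and matches the rank-Pearson oracle", {
  x <- c(1, 4, 9, 12, 20)
  expect_equal(spearman_cor(x, x^3 + 2)$rho, 1)
  expect_equal(spearman_cor(x, -sqrt(x))$rho, -1)

  set.seed(1405)
  for (i in 1:30) {
    x <- sample(1:8, 12, replace = TRUE)  # heavy ties
    y <- x + rnorm(12, 0, 2)
    res <- spearman_cor(x, y)
    expect_equal(res$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_cor(rep(3, 5), 1:5), class = "napscope_data_error")
})

test_that("Bonferroni caps at 1, preserves order and never decreases a p-value", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.2, 0.04, 0.3, 0.02)),
               c(0.05, 1, 0.2, 1, 0.1))
  expect_error(bonferroni(c(0.5, 1.2)), class = "napscope_domain_error")
  set.seed(2)
  p <- runif(20)
  expect_true(all(bonferroni(p) >= p))
})

test_that("condition_comparison has the expected structure and rejects incomplete designs", {
  study <- generate_study(study_config(n_subjects = 10, seed = 303),
                          render = "indices")
  long <- indices_long(study_true_indices(study))
  rep_ <- condition_comparison(long, weights = study$design)
  a <- rep_$omnibus[rep_$omnibus$scope == "conditions_within_angle", ]
  b <- rep_$omnibus[rep_$omnibus$scope == "angles_within_condition", ]
  expect_equal(unique(a$df), 2)
  expect_equal(unique(b$df), 11)
  expect_equal(nrow(a), 12 * 4)  # 12 angles x 4 indices
  expect_equal(nrow(b), 3 * 4)   # 3 conditions x 4 indices
  # effect sizes only attach to significant omnibus tests
  expect_true(all(is.na(rep_$omnibus$effect_W[!rep_$omnibus$significant])))
  expect_equal(nrow(rep_$correlations), 3 * 12 * 4)

  expect_error(condition_comparison(long[-1, ]),
               class = "napscope_design_error")
})
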