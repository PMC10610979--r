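# independent brute-force oracles, deliberately naive and separate from the
# package's implementations

# Friedman chi-square via per-row selection-sort ranking and the bare
# rank-sum formula
oracle_friedman_chi2 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- matrix(0, n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      less <- 0; equal <- 0
      for (l in seq_len(k)) {
        if (m[i, l] < m[i, j]) less <- less + 1
        if (m[i, l] == m[i, j]) equal <- equal + 1
      }
      R[i, j] <- less + (equal + 1) / 2
    }
  }
  12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
}

# exact signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_exact <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  eps <- 1e-9
  switch(alternative,
         greater = mean(ws >= w_obs - eps),
         less = mean(ws <= w_obs + eps),
         two.sided = mean(abs(ws - mu) >= abs(w_obs - mu) - eps))
}

# Spearman rho as Pearson on average ranks, written out by hand
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# a complete synthetic pose frame with every limb straight: torso, legs and
# arms all colinear per side. The 8 chain angles (shoulder, elbow, hip,
# knee) are exactly 0; the 4 terminal chord angles (wrist, ankle) are
# exactly 180 because their chord doubles back along the straight limb.
straight_frame <- function(width = 640, height = 640) {
  pts <- rbind(
    ANL = c(0.15, 0.60), ANR = c(0.15, 0.40),
    KL  = c(0.25, 0.60), KR  = c(0.25, 0.40),
    HL  = c(0.40, 0.60), HR  = c(0.40, 0.40),
    SHL = c(0.60, 0.60), SHR = c(0.60, 0.40),
    ELL = c(0.75, 0.60), ELR = c(0.75, 0.40),
    WL  = c(0.85, 0.60), WR  = c(0.85, 0.40)
  )
  pose_frame(0, 0, width, height, pts)
}

# a generic complete frame with landmarks in general position (square frame
# so normalized-space checks are aspect-ratio free)
random_frame <- function(width = 640, height = 640) {
  pts <- matrix(runif(24, 0.1, 0.9), ncol = 2,
                dimnames = list(landmark_names(), NULL))
  pose_frame(0, 0, width, height, pts)
}

make_series <- function(values, fps = 1, angle = "KR") {
  angle_series(angle, (seq_along(values) - 1) / fps, values, fps = fps)
}
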