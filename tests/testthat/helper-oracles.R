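# Independent statistical oracles, kept free of any package code path.

# Brute-force one-way fixed-effects ANOVA from sums of squares.
anova_oracle <- function(groups) {
  k <- length(groups); n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  c(F = F, p = stats::pf(F, k - 1, n - k, lower.tail = FALSE))
}

# Closed-form Welch and Student two-sided t-tests.
ttest_oracle <- function(x, y, welch = TRUE) {
  nx <- length(x); ny <- length(y)
  if (welch) {
    se2x <- stats::var(x) / nx; se2y <- stats::var(y) / ny
    t <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  c(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Torgerson double-centering oracle for classical scaling.
mds_oracle <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  keep <- pos[seq_len(min(k, length(pos)))]
  sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(e$values[keep]), `*`)
}

# Wrap explicit linear-scale values as a normalized matrix for direct
# statistical testing (bypasses re-normalization).
as_normalized <- function(m) {
  plasmapanel:::new_normalized_matrix(m$values, m$runs,
                                      "linear_normalized", "none")
}
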