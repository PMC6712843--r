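# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce condition / arm labels to canonical factors, erroring on unknowns.
as_condition <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), PANEL_CONDITIONS)
  if (length(bad) > 0L)
    stopf("unknown condition label(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(PANEL_CONDITIONS, collapse = ", "))
  factor(x, levels = PANEL_CONDITIONS)
}

as_arm <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), PANEL_ARMS)
  if (length(bad) > 0L)
    stopf("unknown depletion arm label(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(PANEL_ARMS, collapse = ", "))
  factor(x, levels = PANEL_ARMS)
}

# Unbiasing constant for the sample SD of n normal draws: E[s] = c4(n) * sigma.
c4_constant <- function(n) {
  stopifnot(n >= 2)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# ---------------------------------------------------------------------------
# Replicate-CV calibration.
#
# Replicate values are drawn as centroid * max(0, 1 + tau * Z), Z ~ N(0,1).
# The observed per-protein CV (sample SD / sample mean over n_rep replicates)
# is a biased estimate of tau: the sample SD underestimates tau (c4 factor),
# the random denominator inflates the ratio, and zero-truncation trims the
# lower tail. The generator therefore treats a configured CV as the TARGET
# OBSERVED replicate CV and solves for tau such that E[sample CV] equals it,
# using a fixed deterministic standard-normal block and uniroot. Cached per
# (cv, n_rep) for speed; independent of the caller's RNG state.
# ---------------------------------------------------------------------------

.calib_cache <- new.env(parent = emptyenv())

calibration_block <- function(n_rep, n_sim = 100000L) {
  key <- sprintf("Z_%d", n_rep)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  Z <- withr::with_seed(104729L + n_rep,
                        matrix(stats::rnorm(n_sim * n_rep), nrow = n_sim))
  .calib_cache[[key]] <- Z
  Z
}

# Mean observed sample CV (fraction, not percent) for multiplicative noise
# scale tau under zero truncation, estimated on the fixed normal block.
expected_sample_cv <- function(tau, n_rep) {
  if (tau <= 0) return(0)
  Z <- calibration_block(n_rep)
  X <- 1 + tau * Z
  X[X < 0] <- 0
  m <- rowMeans(X)
  ss <- rowSums(X^2) - n_rep * m^2
  s <- sqrt(pmax(ss, 0) / (n_rep - 1))
  keep <- m > 0
  mean(s[keep] / m[keep])
}

calibrate_cv_tau <- function(cv_percent, n_rep) {
  if (cv_percent < 0) stopf("CV must be non-negative, got %g", cv_percent)
  if (cv_percent == 0) return(0)
  key <- sprintf("tau_%g_%d", cv_percent, n_rep)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  target <- cv_percent / 100
  f <- function(tau) expected_sample_cv(tau, n_rep) - target
  upper <- max(3, 4 * target)
  if (f(upper) < 0)
    stopf(paste("target CV %g%% is not achievable as an observed replicate",
                "CV under zero-truncated noise"), cv_percent)
  tau <- stats::uniroot(f, lower = 1e-8, upper = upper, tol = 1e-8)$root
  .calib_cache[[key]] <- tau
  tau
}

# ---------------------------------------------------------------------------
# Orthogonal Procrustes residual between two configurations (rows = items).
# Both are column-centered; Y is rotated/reflected onto X by the SVD
# solution; returns the root-mean-square coordinate residual.
# ---------------------------------------------------------------------------
procrustes_rms <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  d <- max(ncol(X), ncol(Y))
  if (ncol(X) < d) X <- cbind(X, matrix(0, nrow(X), d - ncol(X)))
  if (ncol(Y) < d) Y <- cbind(Y, matrix(0, nrow(Y), d - ncol(Y)))
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(crossprod(X, Y))
  R <- sv$v %*% t(sv$u)
  sqrt(mean((X - Y %*% R)^2))
}

# Seed helper: evaluates expr under a temporary seed when seed is non-NULL,
# leaving the caller's RNG state untouched; otherwise evaluates directly.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
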