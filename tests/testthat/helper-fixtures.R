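# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Small quantitation matrix with explicit values: one arm, all five
# conditions, `reps` technical replicates. `values` is protein x run in
# condition-major, replicate-minor column order.
make_quant <- function(values, reps = 3, arm = "none",
                       conditions = PANEL_CONDITIONS,
                       protein_ids = NULL) {
  values <- as.matrix(values)
  n_runs <- length(conditions) * reps
  stopifnot(ncol(values) == n_runs)
  protein_ids <- protein_ids %||% sprintf("P%03d", seq_len(nrow(values)))
  run_id <- paste0(rep(conditions, each = reps), "_r", rep(seq_len(reps),
                                                           length(conditions)))
  rownames(values) <- protein_ids
  colnames(values) <- run_id
  meta <- data.frame(run_id = run_id,
                     condition = rep(conditions, each = reps),
                     arm = arm, replicate = rep(seq_len(reps),
                                                length(conditions)))
  quant_matrix(values, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Null matrix with multiplicative log-normal replicate noise: no planted
# differential expression, Gaussian noise on the log scale.
lognull_matrix <- function(n_prot = 300, sdlog = 0.35, reps = 3, seed = 1) {
  withr::with_seed(seed, {
    centroid <- 10^stats::runif(n_prot, 2, 8)
    noise <- exp(matrix(stats::rnorm(n_prot * 5 * reps, 0, sdlog), n_prot))
    make_quant(centroid * noise, reps = reps)
  })
}

# Separable toy cohort: distinct per-class centroids, optional noise.
toy_centroids <- function(n_prot = 6) {
  cen <- outer(seq(1, 3, length.out = 5), seq_len(n_prot)) * 100
  dimnames(cen) <- list(PANEL_CONDITIONS, sprintf("P%03d", seq_len(n_prot)))
  cen
}

toy_sds <- function(cen, frac = 0.1) {
  sds <- cen * frac
  sds
}
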