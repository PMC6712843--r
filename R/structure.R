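# Unsupervised structure: run- and protein-level dissimilarities, classical
# multidimensional scaling and a PCA cross-check.

new_dissimilarity <- function(D, labels, metric, items) {
  dimnames(D) <- list(labels, labels)
  structure(list(labels = labels, D = D, metric = metric, items = items),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d %s, metric = %s\n",
              length(x$labels), x$items, x$metric))
  invisible(x)
}

dist_from_profiles <- function(P, metric) {
  # rows of P are items
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(P, method = "euclidean"))
  } else {
    R <- stats::cor(t(P))
    D <- 1 - R
  }
  D[D < 0 & D > -1e-12] <- 0
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Dissimilarity between replicate runs over a protein subset
#'
#' Pairwise distances between runs computed from log-normalized abundance
#' profiles of the given proteins; Euclidean by default, correlation
#' distance (1 - Pearson r) optionally.
#'
#' @param m A `normalized_matrix`.
#' @param proteins Protein ids to use (`NULL` = all proteins observed in
#'   every run).
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @return A `dissimilarity_matrix` over runs.
#' @export
condition_dissimilarity <- function(m, proteins = NULL,
                                    metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  lv <- log_scale_values(m)
  if (!is.null(proteins)) {
    absent <- setdiff(proteins, rownames(lv))
    if (length(absent) > 0L)
      stopf("protein(s) absent from matrix: %s", paste(absent, collapse = ", "))
    lv <- lv[proteins, , drop = FALSE]
  }
  complete <- stats::complete.cases(lv)
  if (!all(complete)) {
    warnf("condition_dissimilarity: dropping %d protein(s) with missing values",
          sum(!complete))
    lv <- lv[complete, , drop = FALSE]
  }
  if (nrow(lv) == 0L) stopf("no proteins observed in all runs")
  new_dissimilarity(dist_from_profiles(t(lv), metric),
                    colnames(lv), metric, "runs")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2/2`, eigendecomposes, and scales eigenvectors by the
#' square roots of the positive eigenvalues. Negative eigenvalues (from
#' non-Euclidean dissimilarities) are truncated to zero and their relative
#' mass reported.
#'
#' @param D A `dissimilarity_matrix` (or square symmetric matrix).
#' @param dims Number of dimensions to keep (default 3).
#' @return An `mds_embedding`: `coordinates` (item x dims; zero-padded past
#'   the rank), `eigenvalues` (non-increasing, full spectrum), `dims_kept`,
#'   `negative_mass`.
#' @export
classical_mds <- function(D, dims = 3) {
  M <- if (inherits(D, "dissimilarity_matrix")) D$D else as.matrix(D)
  stopifnot(dims >= 1, nrow(M) == ncol(M))
  n <- nrow(M)
  if (dims > n - 1L) dims <- n - 1L
  # cmdscale warns when fewer than k eigenvalues are positive; the embedding
  # is zero-padded and the spectrum reported instead
  fit <- suppressWarnings(stats::cmdscale(M, k = dims, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  if (all(eig <= 1e-12 * max(abs(eig), 1)))
    stopf("degenerate dissimilarity: no positive eigenvalues")
  pts <- fit$points
  if (ncol(pts) < dims)   # rank-deficient: pad with zero coordinates
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  colnames(pts) <- paste0("dim", seq_len(dims))
  rownames(pts) <- rownames(M)
  neg <- sum(abs(eig[eig < 0]))
  structure(list(coordinates = pts, eigenvalues = eig, dims_kept = dims,
                 negative_mass = neg / sum(abs(eig))),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d items, %d dims, negative eigenvalue mass %.2g\n",
              nrow(x$coordinates), x$dims_kept, x$negative_mass))
  invisible(x)
}

#' PCA of run profiles, cross-checked against classical MDS
#'
#' Principal components of centered log-scale run profiles. For Euclidean
#' dissimilarities classical MDS and PCA give the same configuration up to
#' rotation/reflection; the orthogonal-Procrustes RMS residual against the
#' MDS embedding of the same data is recorded in the
#' `"procrustes_rms_vs_mds"` attribute.
#'
#' @param m A `normalized_matrix` with at least two runs.
#' @param dims Dimensions to keep (default 3).
#' @param proteins Optional protein subset (as in
#'   [condition_dissimilarity()]).
#' @return An `mds_embedding` (PCA scores; eigenvalues are the centered
#'   scatter-matrix eigenvalues, matching the Torgerson spectrum).
#' @export
pca_check <- function(m, dims = 3, proteins = NULL) {
  lv <- log_scale_values(m)
  if (!is.null(proteins)) {
    absent <- setdiff(proteins, rownames(lv))
    if (length(absent) > 0L)
      stopf("protein(s) absent from matrix: %s", paste(absent, collapse = ", "))
    lv <- lv[proteins, , drop = FALSE]
  }
  lv <- lv[stats::complete.cases(lv), , drop = FALSE]
  n <- ncol(lv)
  stopifnot(n >= 2L)
  dims <- min(dims, n - 1L)
  pr <- stats::prcomp(t(lv), center = TRUE)
  pts <- pr$x[, seq_len(min(dims, ncol(pr$x))), drop = FALSE]
  if (ncol(pts) < dims) pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  colnames(pts) <- paste0("dim", seq_len(dims))
  eig <- pr$sdev^2 * (n - 1)
  emb <- structure(list(coordinates = pts, eigenvalues = eig,
                        dims_kept = dims, negative_mass = 0),
                   class = "mds_embedding")
  mds <- classical_mds(condition_dissimilarity(m, proteins, "euclidean"), dims)
  attr(emb, "procrustes_rms_vs_mds") <-
    procrustes_rms(mds$coordinates, pts)
  emb
}

#' Dissimilarity between protein stage profiles
#'
#' Each protein is summarized by its five condition means (linear
#' normalized scale, averaged over replicates). Profiles are z-scored across
#' the five means by default so that the stage response, not the absolute
#' abundance, drives the distances; this is essential when comparing
#' proteins spanning many orders of magnitude. Proteins with zero profile
#' variance cannot be standardized (or correlated) and raise an error.
#'
#' @param m A `normalized_matrix`, or a 5 x protein condition-mean matrix
#'   (rows named by [PANEL_CONDITIONS]).
#' @param proteins Protein ids to compare (`NULL` = all).
#' @param metric `"euclidean"` (default, on standardized profiles) or
#'   `"correlation"` (1 - Pearson r, standardization-invariant).
#' @param standardize z-score profiles before Euclidean distances
#'   (default `TRUE`).
#' @return A `dissimilarity_matrix` over proteins.
#' @export
protein_dissimilarity <- function(m, proteins = NULL,
                                  metric = c("euclidean", "correlation"),
                                  standardize = TRUE) {
  metric <- match.arg(metric)
  prof <- if (inherits(m, "quant_matrix")) condition_mean_profiles(m) else {
    M <- as.matrix(m)
    stopifnot(all(PANEL_CONDITIONS %in% rownames(M)))
    M[PANEL_CONDITIONS, , drop = FALSE]
  }
  if (!is.null(proteins)) {
    absent <- setdiff(proteins, colnames(prof))
    if (length(absent) > 0L)
      stopf("protein(s) absent from matrix: %s", paste(absent, collapse = ", "))
    prof <- prof[, proteins, drop = FALSE]
  }
  if (anyNA(prof)) {
    keep <- !apply(is.na(prof), 2, any)
    warnf("protein_dissimilarity: dropping %d protein(s) with undefined condition means",
          sum(!keep))
    prof <- prof[, keep, drop = FALSE]
  }
  sdv <- apply(prof, 2, stats::sd)
  if (any(sdv == 0))
    stopf("flat stage profile(s) (zero variance): %s",
          paste(colnames(prof)[sdv == 0], collapse = ", "))
  P <- t(prof)
  if (metric == "euclidean" && standardize)
    P <- t(scale(prof))   # z-score each protein across the 5 condition means
  new_dissimilarity(dist_from_profiles(P, metric), colnames(prof),
                    metric, "proteins")
}

# 5 x protein matrix of per-condition replicate means on the linear scale.
condition_mean_profiles <- function(m) {
  linv <- linear_values(m)
  cond <- as.character(m$runs$condition)
  prof <- vapply(PANEL_CONDITIONS, function(cc) {
    idx <- cond == cc
    if (!any(idx)) return(rep(NA_real_, nrow(linv)))
    rowMeans(linv[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(linv)))
  t(prof)  # conditions x proteins
}

#' Write embedding coordinates to TSV
#'
#' @param emb An `mds_embedding`.
#' @param path Output path (columns: item, dim1..dimk).
#' @return Invisibly, `emb`.
#' @export
write_embedding <- function(emb, path) {
  tab <- data.frame(item = rownames(emb$coordinates), emb$coordinates,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(emb)
}
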