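# Data model and I/O for protein-by-run peak-area quantitation matrices.

#' Construct a protein quantitation matrix
#'
#' Bundles a protein x run matrix of non-negative peak areas with per-run
#' metadata. Missing values are encoded as `NA`. This is the universal input
#' of the pipeline; one object per depletion arm is the typical layout.
#'
#' @param values Numeric matrix, proteins in rows (rownames = accessions),
#'   runs in columns (colnames = run ids). Non-negative; `NA` = missing.
#' @param runs Data frame with columns `run_id`, `condition` (one of
#'   [PANEL_CONDITIONS]), `arm` (one of [PANEL_ARMS]) and `replicate`
#'   (positive integer), one row per column of `values`.
#' @return An object of class `quant_matrix`: a list with elements `values`
#'   and `runs`.
#' @export
quant_matrix <- function(values, runs) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stopf("values must have protein rownames")
  if (is.null(colnames(values))) stopf("values must have run colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0L)
    stopf("duplicate protein id(s): %s", paste(dup, collapse = ", "))
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  need <- c("run_id", "condition", "arm", "replicate")
  miss <- setdiff(need, names(runs))
  if (length(miss) > 0L)
    stopf("run metadata lacks column(s): %s", paste(miss, collapse = ", "))
  runs$run_id <- as.character(runs$run_id)
  if (anyDuplicated(runs$run_id))
    stopf("duplicate run_id(s) in metadata: %s",
          paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "))
  unmatched <- setdiff(colnames(values), runs$run_id)
  if (length(unmatched) > 0L)
    stopf("run(s) without metadata: %s", paste(unmatched, collapse = ", "))
  runs <- runs[match(colnames(values), runs$run_id), , drop = FALSE]
  rownames(runs) <- NULL
  runs$condition <- as_condition(runs$condition)
  runs$arm <- as_arm(runs$arm)
  runs$replicate <- as.integer(runs$replicate)
  if (any(is.na(runs$replicate)) || any(runs$replicate < 1L))
    stopf("replicate indices must be positive integers")
  bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("negative peak area at protein %s, run %s (value %g)",
          rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
          values[bad[1, 1], bad[1, 2]])
  if (any(!is.finite(values) & !is.na(values)))
    stopf("non-finite peak areas present; encode missing values as NA")
  empty <- colSums(!is.na(values)) == 0L
  if (any(empty))
    stopf("run(s) with no observed value: %s",
          paste(colnames(values)[empty], collapse = ", "))
  structure(list(values = values, runs = runs), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  sc <- attr(x, "scale") %||% "raw"
  cat(sprintf("<%s> %d proteins x %d runs [%s]\n",
              class(x)[1], nrow(x$values), ncol(x$values), sc))
  tab <- table(x$runs$condition, x$runs$arm)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  print(tab)
  nmiss <- sum(is.na(x$values))
  cat(sprintf("missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

new_normalized_matrix <- function(values, runs, scale, method, log_base = NA) {
  out <- structure(list(values = values, runs = runs),
                   class = c("normalized_matrix", "quant_matrix"))
  attr(out, "scale") <- scale
  attr(out, "normalization_method") <- method
  attr(out, "log_base") <- log_base
  out
}

is_log_scale <- function(m) identical(attr(m, "scale"), "log")

#' Values of a quantitation matrix on the linear scale
#'
#' Back-transforms log-scale matrices using their recorded base; raw and
#' linear-normalized matrices are returned as stored.
#'
#' @param m A `quant_matrix` or `normalized_matrix`.
#' @return Numeric matrix (proteins x runs).
#' @export
linear_values <- function(m) {
  if (is_log_scale(m)) attr(m, "log_base")^m$values else m$values
}

# Log-scale values for statistics; non-positive cells become NA.
log_scale_values <- function(m, base = 2) {
  if (is_log_scale(m)) return(m$values)
  v <- m$values
  v[!is.na(v) & v <= 0] <- NA
  log(v, base = base)
}

#' Read a quantitation table and its run metadata
#'
#' The table is delimited text (TSV, or CSV for a `.csv` extension) whose
#' first column holds protein accessions and remaining columns one run each.
#' The metadata file maps `run_id` to `condition`, `arm` and `replicate`.
#'
#' @param path Path to the quantitation table.
#' @param meta_path Path to the run-metadata table.
#' @param missing_as Values to treat as missing in addition to empty cells
#'   (default `"NA"`).
#' @return A [quant_matrix()].
#' @export
read_quant_table <- function(path, meta_path, missing_as = "NA") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, na.strings = missing_as,
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 2L) stopf("quantitation table needs >= 1 run column")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  msep <- if (grepl("\\.csv$", meta_path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(meta_path, sep = msep, header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
  quant_matrix(vals, meta)
}

#' Write a quantitation matrix and its metadata to delimited text
#'
#' @param m A `quant_matrix`.
#' @param path Output path for the values table (TSV; first column
#'   `protein_id`).
#' @param meta_path Output path for the run metadata (TSV).
#' @return Invisibly, `m`.
#' @export
write_quant_table <- function(m, path, meta_path) {
  tab <- data.frame(protein_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$runs, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Total-area normalization
#'
#' Scales every run so that its summed signal over observed proteins equals
#' the mean of the original run totals, removing run-to-run loading and
#' injection differences while keeping values on a peak-area-like scale.
#' Depletion arms are normalized independently by default, since each arm is
#' a separate experiment with its own total signal.
#'
#' @param m A `quant_matrix` (raw) or linear-scale `normalized_matrix`
#'   (the operation is idempotent).
#' @param by_arm Normalize each depletion arm separately (default `TRUE`).
#' @return A `normalized_matrix` with scale `"linear_normalized"`.
#' @export
total_area_normalize <- function(m, by_arm = TRUE) {
  stopifnot(inherits(m, "quant_matrix"))
  if (is_log_scale(m))
    stopf("total_area_normalize expects linear-scale input")
  v <- m$values
  totals <- colSums(v, na.rm = TRUE)
  zero <- totals <= 0
  if (any(zero))
    stopf("run(s) with zero total signal: %s",
          paste(colnames(v)[zero], collapse = ", "))
  groups <- if (by_arm) split(seq_len(ncol(v)), m$runs$arm, drop = TRUE)
            else list(seq_len(ncol(v)))
  for (idx in groups) {
    target <- mean(totals[idx])
    v[, idx] <- sweep(v[, idx, drop = FALSE], 2, target / totals[idx], `*`)
  }
  new_normalized_matrix(v, m$runs, "linear_normalized", "total_area")
}

#' Log-transform a normalized matrix
#'
#' Non-positive cells (zeros after normalization) are masked as missing
#' rather than shifted by an arbitrary offset; an optional pseudo-count can
#' be added first. The number of newly masked cells is recorded in the
#' `"n_masked"` attribute.
#'
#' @param m A linear-scale `normalized_matrix`.
#' @param base Logarithm base (default 2).
#' @param pseudocount Offset added before taking logs (default 0).
#' @return A `normalized_matrix` with scale `"log"` and the base recorded.
#' @export
log_transform <- function(m, base = 2, pseudocount = 0) {
  stopifnot(inherits(m, "normalized_matrix"))
  if (is_log_scale(m)) stopf("matrix is already log-scale")
  v <- m$values + pseudocount
  newly <- !is.na(v) & v <= 0
  v[newly] <- NA
  out <- new_normalized_matrix(log(v, base = base), m$runs, "log",
                               attr(m, "normalization_method"), base)
  attr(out, "n_masked") <- sum(newly)
  if (any(newly))
    message(sprintf("log_transform: masked %d non-positive cell(s) as missing",
                    sum(newly)))
  out
}

#' Replicate-consistency quality-control summary
#'
#' For every (condition, arm) replicate group: mean pairwise Pearson
#' correlation of log-scale run profiles and the distribution of per-protein
#' replicate CVs (linear scale). Also returns centered PCA coordinates of
#' the runs for plotting. Groups with fewer than two runs are skipped with a
#' warning.
#'
#' @param m A `normalized_matrix` (either scale).
#' @return A list of class `qc_report`: `group_summary` (condition, arm,
#'   n_runs, mean_correlation, mean_cv, median_cv), `protein_cv` (long table
#'   of per-protein CVs), `pca` (run coordinates and variance explained).
#' @export
qc_replicate_summary <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  lv <- log_scale_values(m)
  linv <- linear_values(m)
  key <- interaction(m$runs$condition, m$runs$arm, drop = TRUE, sep = "|")
  groups <- split(seq_len(ncol(lv)), key)
  gs <- list(); pc <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    if (length(idx) < 2L) {
      warnf("qc_replicate_summary: group %s has < 2 runs; skipped", g)
      next
    }
    cmat <- stats::cor(lv[, idx, drop = FALSE], use = "pairwise.complete.obs")
    mean_r <- mean(cmat[upper.tri(cmat)])
    sub <- linv[, idx, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1, stats::sd, na.rm = TRUE)
    cv <- ifelse(!is.na(mu) & mu > 0, 100 * sdv / mu, NA_real_)
    gs[[g]] <- data.frame(condition = parts[1], arm = parts[2],
                          n_runs = length(idx), mean_correlation = mean_r,
                          mean_cv = mean(cv, na.rm = TRUE),
                          median_cv = stats::median(cv, na.rm = TRUE),
                          stringsAsFactors = FALSE)
    pc[[g]] <- data.frame(protein_id = rownames(linv), condition = parts[1],
                          arm = parts[2], cv_percent = cv,
                          stringsAsFactors = FALSE, row.names = NULL)
  }
  complete <- stats::complete.cases(lv)
  pca <- NULL
  if (sum(complete) >= 2L && ncol(lv) >= 2L) {
    pr <- stats::prcomp(t(lv[complete, , drop = FALSE]), center = TRUE)
    ve <- pr$sdev^2 / sum(pr$sdev^2)
    pca <- list(coordinates = pr$x, variance_explained = ve)
  }
  structure(list(group_summary = do.call(rbind, gs),
                 protein_cv = do.call(rbind, pc), pca = pca),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> replicate consistency by (condition, arm)\n")
  print(x$group_summary, row.names = FALSE, digits = 3)
  invisible(x)
}
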