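# Synthetic patient-cohort augmentation from pooled class centroids and
# technical-replicate standard deviations.

#' Augmentation configuration
#'
#' Synthetic patients are drawn per class and protein from
#' `Normal(mean = class centroid, SD = k_sd x replicate SD)`. The default
#' noise multiplier of 10 deliberately inflates the technical-replicate
#' variance to emulate a heterogeneous patient population and to make the
#' downstream classification task conservative.
#'
#' @param n_per_class Synthetic patients per class (default 1000).
#' @param k_sd Noise multiplier applied to the replicate SD (default 10).
#' @param seed Integer seed; the cohort is bit-reproducible given
#'   (seed, config, inputs).
#' @param negative_policy What to do with negative draws: `"truncate_zero"`
#'   (default; concentrations are non-negative), `"resample"` (redraw until
#'   non-negative) or `"allow"`.
#' @param sd_scale `"raw"` (default): SDs are on the linear normalized
#'   peak-area scale.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(n_per_class = 1000L, k_sd = 10, seed = NULL,
                           negative_policy = c("truncate_zero", "resample",
                                               "allow"),
                           sd_scale = c("raw", "log")) {
  n_per_class <- as.integer(n_per_class)
  stopifnot(n_per_class >= 1L)
  if (k_sd < 0) stopf("k_sd must be >= 0, got %g", k_sd)
  structure(list(n_per_class = n_per_class, k_sd = k_sd, seed = seed,
                 negative_policy = match.arg(negative_policy),
                 sd_scale = match.arg(sd_scale)),
            class = "augment_config")
}

#' Technical-replicate variance report
#'
#' Per-protein coefficient of variation (sample SD / mean x 100) over
#' technical replicates on the linear normalized scale, summarized per
#' condition as mean +/- SD across proteins. This is the verification step
#' that precedes augmentation: the per-stage replicate variances should be
#' comparable before their SDs are reused as the augmentation noise scale.
#'
#' @param m A `normalized_matrix` (single arm; linear values used).
#' @param proteins Protein subset (`NULL` = all).
#' @return A list of class `replicate_variance_report`: `summary`
#'   (condition, n_proteins, mean_cv, sd_cv) and `protein_cv` (long table).
#'   Proteins with zero replicate mean in a condition are skipped there.
#' @export
replicate_variance_report <- function(m, proteins = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  linv <- linear_values(m)
  if (!is.null(proteins)) {
    absent <- setdiff(proteins, rownames(linv))
    if (length(absent) > 0L)
      stopf("protein(s) absent from matrix: %s", paste(absent, collapse = ", "))
    linv <- linv[proteins, , drop = FALSE]
  }
  cond <- as.character(m$runs$condition)
  rows <- list(); summ <- list()
  for (cc in intersect(PANEL_CONDITIONS, unique(cond))) {
    sub <- linv[, cond == cc, drop = FALSE]
    if (ncol(sub) < 2L) {
      warnf("replicate_variance_report: condition %s has < 2 replicates; skipped", cc)
      next
    }
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1, stats::sd, na.rm = TRUE)
    ok <- !is.na(mu) & mu > 0 & !is.na(sdv)
    cv <- 100 * sdv[ok] / mu[ok]
    rows[[cc]] <- data.frame(protein_id = rownames(sub)[ok], condition = cc,
                             cv_percent = cv, stringsAsFactors = FALSE,
                             row.names = NULL)
    summ[[cc]] <- data.frame(condition = cc, n_proteins = sum(ok),
                             mean_cv = mean(cv), sd_cv = stats::sd(cv),
                             stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, summ),
                 protein_cv = do.call(rbind, rows)),
            class = "replicate_variance_report")
}

#' @export
print.replicate_variance_report <- function(x, ...) {
  cat("<replicate_variance_report> per-condition replicate CV (%)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %.0f +/- %.0f%%  (n = %d proteins)\n",
                s$condition[i], s$mean_cv[i], s$sd_cv[i], s$n_proteins[i]))
  invisible(x)
}

#' Generate a synthetic patient cohort by noise augmentation
#'
#' Each synthetic patient value is drawn independently per protein from a
#' normal distribution centered on its class (pooled-sample) centroid with
#' standard deviation `k_sd` times the technical-replicate SD. Draw order is
#' fixed as (class, patient, protein) under one seeded generator, so cohorts
#' are bit-reproducible across machines.
#'
#' @param centroids Class x protein matrix of replicate means (rownames
#'   must be the class labels, canonically [PANEL_CONDITIONS]).
#' @param sds Class x protein matrix of replicate SDs, same dimnames.
#' @param cfg An [augment_config()].
#' @return A list of class `synthetic_cohort`: `values` (patient x protein),
#'   `labels` (factor), `config`, `provenance`.
#' @export
augment_cohort <- function(centroids, sds, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  centroids <- as.matrix(centroids); sds <- as.matrix(sds)
  if (!identical(dim(centroids), dim(sds)) ||
      !identical(dimnames(centroids), dimnames(sds)))
    stopf("centroids and sds must share dimensions and dimnames")
  if (is.null(rownames(centroids)) || is.null(colnames(centroids)))
    stopf("centroids need class rownames and protein colnames")
  if (any(is.na(sds)) || any(sds < 0)) stopf("SDs must be non-negative")
  if (any(is.na(centroids))) stopf("centroids must be complete")
  classes <- rownames(centroids)
  if (all(classes %in% PANEL_CONDITIONS))
    classes <- PANEL_CONDITIONS[PANEL_CONDITIONS %in% classes]
  P <- ncol(centroids); n <- cfg$n_per_class
  draw_class <- function(cc) {
    mu <- matrix(centroids[cc, ], n, P, byrow = TRUE)
    sd <- matrix(cfg$k_sd * sds[cc, ], n, P, byrow = TRUE)
    # row-major fill = (patient, protein) draw order
    X <- mu + sd * matrix(stats::rnorm(n * P), n, P, byrow = TRUE)
    if (cfg$negative_policy == "truncate_zero") {
      X[X < 0] <- 0
    } else if (cfg$negative_policy == "resample") {
      repeat {
        neg <- which(X < 0)
        if (length(neg) == 0L) break
        X[neg] <- mu[neg] + sd[neg] * stats::rnorm(length(neg))
      }
    }
    X
  }
  blocks <- with_seed_if(cfg$seed, lapply(classes, draw_class))
  values <- do.call(rbind, blocks)
  colnames(values) <- colnames(centroids)
  labels <- factor(rep(classes, each = n), levels = classes)
  rownames(values) <- paste(rep(classes, each = n),
                            sprintf("%04d", sequence(rep(n, length(classes)))),
                            sep = "_")
  structure(list(values = values, labels = labels, config = cfg,
                 provenance = list(classes = classes,
                                   proteins = colnames(centroids))),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients x %d proteins (%s per class, k_sd = %g)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(table(x$labels)), collapse = "/"), x$config$k_sd))
  invisible(x)
}

#' Write a synthetic cohort to TSV with a JSON config sidecar
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output TSV path (`label` column + one column per protein);
#'   the configuration is written next to it as `<path>.json`.
#' @return Invisibly, `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  tab <- data.frame(label = as.character(cohort$labels), cohort$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(cohort)
}
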