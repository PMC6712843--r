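# Differential-expression statistics, selection filters and cross-arm
# consolidation of candidate biomarkers.

#' Differential-expression configuration
#'
#' @param alpha ANOVA significance threshold (default 0.05).
#' @param fc_threshold Symmetric fold-change cutoff, strict (default 1.5):
#'   a protein passes the magnitude filter when `max(FC, 1/FC) > fc_threshold`
#'   for at least one stage-vs-healthy contrast.
#' @param require_consistent_trend Require the same direction of change vs
#'   healthy in all four stages (default `TRUE`).
#' @param ttest_variant `"welch"` (default, unequal variances) or
#'   `"student"` (pooled variance).
#' @param multiple_testing `"none"` (default; raw ANOVA p drives selection)
#'   or `"BH"` (Benjamini-Hochberg adjusted p drives selection; the raw p is
#'   still reported).
#' @return A list of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, fc_threshold = 1.5,
                      require_consistent_trend = TRUE,
                      ttest_variant = c("welch", "student"),
                      multiple_testing = c("none", "BH")) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold > 1)
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 require_consistent_trend = require_consistent_trend,
                 ttest_variant = match.arg(ttest_variant),
                 multiple_testing = match.arg(multiple_testing)),
            class = "de_config")
}

# Restrict a matrix to one depletion arm. arm = NULL is allowed when the
# matrix holds a single arm.
arm_subset <- function(m, arm = NULL) {
  arms <- unique(as.character(m$runs$arm))
  if (is.null(arm)) {
    if (length(arms) > 1L)
      stopf("matrix holds arms %s; specify one", paste(arms, collapse = ", "))
    return(m)
  }
  arm <- as.character(as_arm(arm))
  idx <- which(as.character(m$runs$arm) == arm)
  if (length(idx) == 0L) stopf("no runs for arm %s", arm)
  out <- m
  out$values <- m$values[, idx, drop = FALSE]
  out$runs <- m$runs[idx, , drop = FALSE]
  rownames(out$runs) <- NULL
  out
}

# Per-protein observation lists by condition, dropping NAs.
condition_groups <- function(v, cond) {
  lapply(split(seq_along(cond), cond), function(idx) {
    x <- v[idx]
    x[!is.na(x)]
  })
}

#' Per-protein one-way ANOVA across the five condition groups
#'
#' Classical fixed-effects one-way ANOVA on log-scale values, run
#' independently for each protein. Proteins with fewer than two observed
#' replicates in any condition group are excluded (recorded in the
#' `"excluded"` attribute). Degenerate cases follow a stated policy: all
#' group means equal with zero within-group variance gives F = 0, p = 1;
#' zero within-group variance with distinct means gives F = Inf, p = 0.
#'
#' @param m A `normalized_matrix` (log scale used internally).
#' @param arm Depletion arm to analyze (`NULL` when `m` holds one arm).
#' @return Data frame `protein_id`, `arm`, `anova_F`, `anova_p`.
#' @export
anova_per_protein <- function(m, arm = NULL) {
  m <- arm_subset(m, arm)
  lv <- log_scale_values(m)
  cond <- m$runs$condition
  res <- vector("list", nrow(lv)); excluded <- character(0)
  for (i in seq_len(nrow(lv))) {
    gr <- condition_groups(lv[i, ], cond)
    if (any(lengths(gr) < 2L)) {
      excluded <- c(excluded, rownames(lv)[i])
      next
    }
    x <- unlist(gr, use.names = FALSE)
    g <- factor(rep(names(gr), lengths(gr)))
    mu_g <- vapply(gr, mean, 0)
    ssw <- sum((x - mu_g[as.character(g)])^2)
    ssb <- sum(lengths(gr) * (mu_g - mean(x))^2)
    tol <- 1e-12 * max(1, sum(x^2))
    if (ssw <= tol) {
      Fp <- if (ssb <= tol) c(0, 1) else c(Inf, 0)
    } else {
      fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
      Fp <- c(unname(fit$statistic), unname(fit$p.value))
    }
    res[[i]] <- data.frame(protein_id = rownames(lv)[i],
                           anova_F = Fp[1], anova_p = Fp[2],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), anova_F = numeric(0),
                      anova_p = numeric(0))
  out <- cbind(out[1], arm = as.character(m$runs$arm[1]), out[-1])
  if (length(excluded) > 0L)
    message(sprintf("anova_per_protein: %d protein(s) excluded (< 2 replicates in some group)",
                    length(excluded)))
  attr(out, "excluded") <- excluded
  rownames(out) <- NULL
  out
}

#' Per-protein pairwise t-tests of each stage against healthy
#'
#' Unpaired two-sided t-tests on log-scale values, one per stage-vs-healthy
#' contrast. With zero variance in both groups the policy is p = 1 for equal
#' means and p = 0 otherwise. Contrasts with fewer than two observations in
#' either group are `NA`.
#'
#' @param m A `normalized_matrix`.
#' @param arm Depletion arm (`NULL` when `m` holds one arm).
#' @param variant `"welch"` (default) or `"student"`.
#' @return Data frame with `protein_id`, then `t_<stage>` and `p_<stage>`
#'   for stages I--IV.
#' @export
pairwise_ttests <- function(m, arm = NULL, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  m <- arm_subset(m, arm)
  lv <- log_scale_values(m)
  cond <- as.character(m$runs$condition)
  stages <- PANEL_CONDITIONS[-1]
  tmat <- matrix(NA_real_, nrow(lv), length(stages),
                 dimnames = list(rownames(lv), stages))
  pmat <- tmat
  healthy_idx <- cond == "healthy"
  for (i in seq_len(nrow(lv))) {
    y <- lv[i, healthy_idx]; y <- y[!is.na(y)]
    for (s in stages) {
      x <- lv[i, cond == s]; x <- x[!is.na(x)]
      if (length(x) < 2L || length(y) < 2L) next
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        eq <- isTRUE(all.equal(mean(x), mean(y)))
        tmat[i, s] <- if (eq) 0 else sign(mean(x) - mean(y)) * Inf
        pmat[i, s] <- if (eq) 1 else 0
      } else {
        fit <- stats::t.test(x, y, var.equal = (variant == "student"))
        tmat[i, s] <- unname(fit$statistic)
        pmat[i, s] <- unname(fit$p.value)
      }
    }
  }
  out <- data.frame(protein_id = rownames(lv), stringsAsFactors = FALSE)
  for (s in stages) out[[paste0("t_", s)]] <- tmat[, s]
  for (s in stages) out[[paste0("p_", s)]] <- pmat[, s]
  rownames(out) <- NULL
  out
}

#' Per-protein stage fold changes and trend signs
#'
#' Fold change is the ratio of the stage group mean to the healthy group
#' mean on the linear normalized scale. The trend sign is +1 for FC > 1,
#' -1 for FC < 1 and 0 at equality. Proteins whose healthy mean is zero get
#' `NA` fold changes and are flagged.
#'
#' @param m A `normalized_matrix`.
#' @param arm Depletion arm (`NULL` when `m` holds one arm).
#' @return Data frame `protein_id`, `fc_<stage>`, `trend_<stage>`,
#'   `fc_defined`.
#' @export
stage_fold_changes <- function(m, arm = NULL) {
  m <- arm_subset(m, arm)
  linv <- linear_values(m)
  cond <- as.character(m$runs$condition)
  stages <- PANEL_CONDITIONS[-1]
  healthy_mean <- rowMeans(linv[, cond == "healthy", drop = FALSE], na.rm = TRUE)
  out <- data.frame(protein_id = rownames(linv), stringsAsFactors = FALSE)
  defined <- !is.na(healthy_mean) & healthy_mean > 0
  for (s in stages) {
    sm <- rowMeans(linv[, cond == s, drop = FALSE], na.rm = TRUE)
    fc <- ifelse(defined & !is.na(sm), sm / healthy_mean, NA_real_)
    out[[paste0("fc_", s)]] <- fc
    out[[paste0("trend_", s)]] <- sign(fc - 1)
  }
  out$fc_defined <- defined & stats::complete.cases(
    out[paste0("fc_", stages)])
  rownames(out) <- NULL
  out
}

#' Full per-protein differential-expression statistics for one arm
#'
#' Combines [anova_per_protein()], [pairwise_ttests()] and
#' [stage_fold_changes()] and applies the selection rule: ANOVA p below
#' `alpha`, maximum symmetric fold change `max(FC, 1/FC)` strictly above
#' `fc_threshold` in at least one stage, and (by default) the same trend
#' direction in all four stages.
#'
#' @param m A `normalized_matrix`.
#' @param arm Depletion arm (`NULL` when `m` holds one arm).
#' @param cfg A [de_config()].
#' @return Data frame of class `protein_stats` with per-stage fold changes,
#'   t-test p-values, `anova_F`, `anova_p` (and `anova_p_adj` under BH),
#'   `max_abs_fc`, `trend_consistent`, `direction`, `passes`.
#' @export
protein_de_stats <- function(m, arm = NULL, cfg = de_config()) {
  stopifnot(inherits(cfg, "de_config"))
  an <- anova_per_protein(m, arm)
  tt <- pairwise_ttests(m, arm, cfg$ttest_variant)
  fc <- stage_fold_changes(m, arm)
  out <- merge(an, tt, by = "protein_id", sort = FALSE)
  out <- merge(out, fc, by = "protein_id", sort = FALSE)
  stages <- PANEL_CONDITIONS[-1]
  fcm <- as.matrix(out[paste0("fc_", stages)])
  sym <- pmax(fcm, 1 / fcm)
  out$max_abs_fc <- apply(sym, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  trm <- as.matrix(out[paste0("trend_", stages)])
  out$trend_consistent <- apply(trm, 1, function(x)
    !any(is.na(x)) && all(x == x[1]) && x[1] != 0)
  out$direction <- ifelse(out$trend_consistent,
                          ifelse(trm[, 1] > 0, "up", "down"), NA_character_)
  p_use <- out$anova_p
  if (cfg$multiple_testing == "BH") {
    out$anova_p_adj <- stats::p.adjust(out$anova_p, method = "BH")
    p_use <- out$anova_p_adj
  }
  out$passes <- !is.na(p_use) & p_use < cfg$alpha &
    !is.na(out$max_abs_fc) & out$max_abs_fc > cfg$fc_threshold &
    (!cfg$require_consistent_trend | out$trend_consistent)
  class(out) <- c("protein_stats", class(out))
  attr(out, "config") <- cfg
  out
}

#' Select candidate proteins from per-arm statistics
#'
#' Returns exactly the rows with `passes = TRUE`, ordered by ascending ANOVA
#' p-value with ties broken by protein id, so outputs are reproducible.
#'
#' @param stats A `protein_stats` data frame from [protein_de_stats()].
#' @param cfg A [de_config()]; when it differs from the one used to compute
#'   `stats`, the pass rule is re-evaluated with the new thresholds.
#' @return The selected subset, same columns as `stats`.
#' @export
select_candidates <- function(stats, cfg = NULL) {
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "de_config"))
    p_use <- if (cfg$multiple_testing == "BH")
      stats::p.adjust(stats$anova_p, method = "BH") else stats$anova_p
    stats$passes <- !is.na(p_use) & p_use < cfg$alpha &
      !is.na(stats$max_abs_fc) & stats$max_abs_fc > cfg$fc_threshold &
      (!cfg$require_consistent_trend | stats$trend_consistent)
  }
  sel <- stats[which(stats$passes), , drop = FALSE]
  sel[order(sel$anova_p, sel$protein_id), , drop = FALSE]
}

#' Consolidate per-arm candidate selections into one table
#'
#' Union of the per-arm selections; a protein selected in several arms is
#' merged into one row listing its supporting arms. Opposite directions
#' across arms set `conflict_flag` and exclude the protein from the default
#' candidate list (see [default_candidates()]).
#'
#' @param per_arm Named list (arm -> data frame from [select_candidates()]).
#' @return Data frame of class `candidate_table`: `protein_id`, `direction`,
#'   `arms` (semicolon-separated), `n_arms`, `min_anova_p`, `max_abs_fc`,
#'   `conflict_flag`; per-arm statistics kept in the `"per_arm"` attribute.
#' @export
consolidate_arms <- function(per_arm) {
  stopifnot(is.list(per_arm), length(per_arm) >= 1L)
  if (is.null(names(per_arm)) || any(names(per_arm) == ""))
    stopf("per_arm must be a named list (arm -> selection)")
  rows <- list()
  for (a in names(per_arm)) {
    df <- per_arm[[a]]
    if (is.null(df) || nrow(df) == 0L) next
    rows[[a]] <- data.frame(protein_id = df$protein_id, arm = a,
                            direction = df$direction, anova_p = df$anova_p,
                            max_abs_fc = df$max_abs_fc,
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  if (is.null(long))
    long <- data.frame(protein_id = character(0), arm = character(0),
                       direction = character(0), anova_p = numeric(0),
                       max_abs_fc = numeric(0))
  ids <- sort(unique(long$protein_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- long[long$protein_id == id, , drop = FALSE]
    dirs <- unique(sub$direction)
    conflict <- length(dirs) > 1L
    data.frame(protein_id = id,
               direction = if (conflict) NA_character_ else dirs,
               arms = paste(sub$arm, collapse = ";"),
               n_arms = nrow(sub),
               min_anova_p = min(sub$anova_p),
               max_abs_fc = max(sub$max_abs_fc),
               conflict_flag = conflict, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(protein_id = character(0), direction = character(0),
                      arms = character(0), n_arms = integer(0),
                      min_anova_p = numeric(0), max_abs_fc = numeric(0),
                      conflict_flag = logical(0))
  out <- out[order(out$min_anova_p, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", class(out))
  attr(out, "per_arm") <- per_arm
  out
}

#' Default candidate list from a consolidated table
#'
#' Conflict-flagged proteins (opposite directions in different arms) are
#' excluded.
#'
#' @param tbl A `candidate_table` from [consolidate_arms()].
#' @return Character vector of protein ids.
#' @export
default_candidates <- function(tbl) {
  stopifnot(inherits(tbl, "candidate_table"))
  tbl$protein_id[!tbl$conflict_flag]
}

#' Write a candidate table to TSV
#'
#' @param tbl A `candidate_table`.
#' @param path Output path.
#' @return Invisibly, `tbl`.
#' @export
write_candidate_table <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tbl)
}
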