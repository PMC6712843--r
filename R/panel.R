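# Panel narrowing: protein-profile grouping plus a greedy retrain-evaluate
# search for the smallest panel maintaining classification accuracy.

#' Group candidate proteins by stage-profile dissimilarity
#'
#' Average-linkage hierarchical clustering of protein stage profiles. Within
#' each group proteins are ordered by a representativeness score (mean
#' dissimilarity to the other members of the group, ascending; ties broken
#' lexicographically). The grouping is deterministic given the input.
#'
#' @param D A protein `dissimilarity_matrix` from
#'   [protein_dissimilarity()].
#' @param n_groups Number of groups; `NULL` (default) picks the cut with
#'   the best average silhouette width over 2..min(8, n-1).
#' @return Data frame `protein_id`, `group`, `representativeness`,
#'   `rank_in_group`, ordered by (group, rank); the `hclust` tree is in the
#'   `"tree"` attribute.
#' @export
rank_protein_groups <- function(D, n_groups = NULL) {
  stopifnot(inherits(D, "dissimilarity_matrix"))
  n <- length(D$labels)
  if (n < 2L) {
    out <- data.frame(protein_id = D$labels, group = rep(1L, n),
                      representativeness = rep(0, n),
                      rank_in_group = rep(1L, n), stringsAsFactors = FALSE)
    return(out)
  }
  hc <- stats::hclust(stats::as.dist(D$D), method = "average")
  if (is.null(n_groups)) {
    ks <- if (n <= 3L) 2L else 2:min(8L, n - 1L)
    sil <- vapply(ks, function(k)
      mean_silhouette(D$D, stats::cutree(hc, k = k)), 0)
    n_groups <- ks[which.max(sil)]
  }
  grp <- stats::cutree(hc, k = min(n_groups, n))
  rep_score <- vapply(seq_len(n), function(i) {
    own <- which(grp == grp[i])
    own <- setdiff(own, i)
    if (length(own) == 0L) 0 else mean(D$D[i, own])
  }, 0)
  out <- data.frame(protein_id = D$labels, group = as.integer(grp),
                    representativeness = rep_score, stringsAsFactors = FALSE)
  out <- out[order(out$group, out$representativeness, out$protein_id), ,
             drop = FALSE]
  out$rank_in_group <- unlist(lapply(split(seq_len(nrow(out)), out$group),
                                     seq_along), use.names = FALSE)
  rownames(out) <- NULL
  attr(out, "tree") <- hc
  out
}

# Average silhouette width for a hard clustering on a dissimilarity matrix.
mean_silhouette <- function(D, grp) {
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    own <- setdiff(which(grp == grp[i]), i)
    others <- setdiff(unique(grp), grp[i])
    if (length(own) == 0L || length(others) == 0L) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(others, function(g) mean(D[i, grp == g]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Evaluate a protein panel end-to-end
#'
#' Restricts centroids, SDs and real data to the panel, then for every seed
#' runs augment -> stratified split -> shallow-network training -> test-set
#' confusion matrix -> deployment on the held-out real runs. Accuracies are
#' aggregated as median and IQR over seeds (robust to network training
#' variance).
#'
#' @param proteins Panel protein ids.
#' @param centroids,sds Class x protein matrices (see [augment_cohort()]).
#' @param real A `normalized_matrix` of real pooled runs for deployment.
#' @param augment_cfg An [augment_config()] (its seed is replaced by each
#'   element of `seeds`).
#' @param nn_cfg An [nn_config()] (seed likewise).
#' @param split A [split_spec()] (seed likewise).
#' @param seeds Integer vector of seeds (default 1:5).
#' @param deploy_unit Passed to [deploy_on_real()].
#' @return A list of class `panel_evaluation`: `proteins`, `per_seed` data
#'   frame (seed, test_accuracy, deploy_accuracy), `synthetic_test_accuracy`
#'   (median), `real_deploy_accuracy` (median), IQRs, `seeds`.
#' @export
evaluate_panel <- function(proteins, centroids, sds, real,
                           augment_cfg = augment_config(),
                           nn_cfg = nn_config(),
                           split = split_spec(),
                           seeds = 1:5,
                           deploy_unit = "replicate") {
  absent <- setdiff(proteins, colnames(centroids))
  if (length(absent) > 0L)
    stopf("panel protein(s) absent from centroids: %s",
          paste(absent, collapse = ", "))
  cen <- centroids[, proteins, drop = FALSE]
  sdm <- sds[, proteins, drop = FALSE]
  rows <- lapply(seeds, function(s) {
    acfg <- augment_cfg; acfg$seed <- s
    scfg <- split; scfg$seed <- s
    ncfg <- nn_cfg; ncfg$seed <- s
    cohort <- augment_cohort(cen, sdm, acfg)
    sp <- split_cohort(cohort, scfg)
    model <- train_nn(sp$train, sp$val, ncfg)
    test_cm <- evaluate(model, sp$test)
    dep_cm <- deploy_on_real(model, real, proteins, unit = deploy_unit)
    data.frame(seed = s, test_accuracy = test_cm$correct_rate,
               deploy_accuracy = dep_cm$correct_rate)
  })
  per_seed <- do.call(rbind, rows)
  structure(list(proteins = proteins, per_seed = per_seed, seeds = seeds,
                 synthetic_test_accuracy = stats::median(per_seed$test_accuracy),
                 synthetic_test_iqr = stats::IQR(per_seed$test_accuracy),
                 real_deploy_accuracy = stats::median(per_seed$deploy_accuracy),
                 real_deploy_iqr = stats::IQR(per_seed$deploy_accuracy)),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("<panel_evaluation> %d proteins, %d seeds\n",
              length(x$proteins), length(x$seeds)))
  cat(sprintf("  synthetic test accuracy: %.1f%% (IQR %.1f)\n",
              x$synthetic_test_accuracy, x$synthetic_test_iqr))
  cat(sprintf("  real deploy accuracy:    %.1f%% (IQR %.1f)\n",
              x$real_deploy_accuracy, x$real_deploy_iqr))
  invisible(x)
}

#' Minimize a candidate list to a compact panel
#'
#' Greedy forward selection over the candidate proteins, seeded by the
#' group representatives from [rank_protein_groups()] (the candidate
#' ordering prioritizes one representative per profile group before the
#' rest). At each step every remaining candidate is tried and the one with
#' the best marginal median synthetic-test accuracy is added; the search
#' stops as soon as the target accuracy is met or candidates are exhausted.
#' An exhaustive subset search is available for small candidate sets.
#'
#' @param candidates Candidate protein ids (must be columns of
#'   `centroids`).
#' @param centroids,sds,real,augment_cfg,nn_cfg,split,seeds,deploy_unit
#'   As in [evaluate_panel()].
#' @param target_accuracy Percent synthetic-test accuracy to reach.
#' @param exhaustive Exhaustive search over all subsets by increasing size
#'   (only allowed for <= 12 candidates; default `FALSE`).
#' @return A `panel_evaluation` for the returned panel, with extra fields
#'   `target_accuracy`, `target_met` and `search_log` (one row per
#'   evaluated panel: step, panel, median test accuracy, selected flag).
#' @export
minimize_panel <- function(candidates, centroids, sds, real,
                           target_accuracy,
                           augment_cfg = augment_config(),
                           nn_cfg = nn_config(),
                           split = split_spec(),
                           seeds = 1:5,
                           deploy_unit = "replicate",
                           exhaustive = FALSE) {
  stopifnot(length(candidates) >= 1L,
            target_accuracy > 0, target_accuracy <= 100)
  eval_panel <- function(p)
    evaluate_panel(p, centroids, sds, real, augment_cfg, nn_cfg, split,
                   seeds, deploy_unit)
  log_rows <- list()
  log_panel <- function(step, p, ev, selected) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      step = step, panel = paste(p, collapse = ";"),
      size = length(p), test_accuracy = ev$synthetic_test_accuracy,
      deploy_accuracy = ev$real_deploy_accuracy, selected = selected,
      stringsAsFactors = FALSE)
  }
  finish <- function(ev, met) {
    ev$target_accuracy <- target_accuracy
    ev$target_met <- met
    ev$search_log <- do.call(rbind, log_rows)
    ev
  }
  if (exhaustive) {
    if (length(candidates) > 12L)
      stopf("exhaustive search limited to <= 12 candidates")
    best_ev <- NULL
    for (size in seq_along(candidates)) {
      subsets <- utils::combn(candidates, size, simplify = FALSE)
      evs <- lapply(subsets, eval_panel)
      accs <- vapply(evs, `[[`, 0, "synthetic_test_accuracy")
      for (j in seq_along(subsets))
        log_panel(size, subsets[[j]], evs[[j]], FALSE)
      hit <- which(accs >= target_accuracy)
      if (length(hit) > 0L) {
        j <- hit[which.max(accs[hit])]
        return(finish(evs[[j]], TRUE))
      }
      j <- which.max(accs)
      if (is.null(best_ev) ||
          evs[[j]]$synthetic_test_accuracy > best_ev$synthetic_test_accuracy)
        best_ev <- evs[[j]]
    }
    return(finish(best_ev, FALSE))
  }
  # Candidate ordering: group representatives first (rank 1 per group),
  # then the remainder, from the protein-profile dissimilarity structure.
  ord <- candidates
  if (length(candidates) >= 2L) {
    D <- protein_dissimilarity(centroids[, candidates, drop = FALSE])
    grp <- rank_protein_groups(D)
    ord <- c(grp$protein_id[grp$rank_in_group == 1L],
             grp$protein_id[grp$rank_in_group != 1L])
  }
  panel <- character(0)
  best_ev <- NULL
  step <- 0L
  while (length(panel) < length(candidates)) {
    step <- step + 1L
    remaining <- setdiff(ord, panel)
    trials <- lapply(remaining, function(p) eval_panel(c(panel, p)))
    accs <- vapply(trials, `[[`, 0, "synthetic_test_accuracy")
    for (j in seq_along(remaining))
      log_panel(step, c(panel, remaining[j]), trials[[j]], FALSE)
    j <- which.max(accs)
    panel <- c(panel, remaining[j])
    best_ev <- trials[[j]]
    log_panel(step, panel, best_ev, TRUE)
    if (best_ev$synthetic_test_accuracy >= target_accuracy)
      return(finish(best_ev, TRUE))
  }
  finish(best_ev, FALSE)
}

#' Write a panel search log to TSV
#'
#' @param evaluation A `panel_evaluation` from [minimize_panel()].
#' @param path Output path.
#' @return Invisibly, `evaluation`.
#' @export
write_search_log <- function(evaluation, path) {
  stopifnot(!is.null(evaluation$search_log))
  utils::write.table(evaluation$search_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(evaluation)
}
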