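# End-to-end convenience wrapper: raw matrices -> candidates -> augmented
# cohort -> trained network -> synthetic-test and real-deploy confusion
# matrices.

#' Run the full discovery pipeline on a set of quantitation matrices
#'
#' Normalizes each depletion arm independently, computes per-arm
#' differential-expression statistics, consolidates the per-arm selections,
#' builds class centroids and replicate SDs for the consolidated candidates
#' from the chosen arm, augments a synthetic patient cohort, trains the
#' shallow network on its stratified split, and evaluates on the synthetic
#' test set and on the real (held-out) pooled replicate runs.
#'
#' @param arms Named list of [quant_matrix()] objects (one per arm), e.g.
#'   `generate_fixture(...)$arms`.
#' @param de_cfg A [de_config()].
#' @param augment_cfg An [augment_config()].
#' @param nn_cfg An [nn_config()].
#' @param split A [split_spec()].
#' @param centroid_arm Arm supplying centroids/SDs and the real deployment
#'   runs (default `"none"`, the non-depleted arm).
#' @param seed Optional master seed copied into the augment, split and
#'   network configurations.
#' @param candidates Optional explicit candidate list; by default the
#'   consolidated DE selection restricted to proteins quantified in
#'   `centroid_arm`.
#' @return A list of class `pipeline_result`: `candidates`,
#'   `candidate_table`, `model`, `test_confusion`, `deploy_confusion`,
#'   `centroids`, `sds`, `normalized` (per-arm normalized matrices).
#' @export
run_discovery_pipeline <- function(arms, de_cfg = de_config(),
                                   augment_cfg = augment_config(),
                                   nn_cfg = nn_config(),
                                   split = split_spec(),
                                   centroid_arm = "none", seed = NULL,
                                   candidates = NULL) {
  stopifnot(is.list(arms), length(arms) >= 1L, !is.null(names(arms)))
  if (!centroid_arm %in% names(arms))
    stopf("centroid_arm %s not among supplied arms", centroid_arm)
  if (!is.null(seed)) {
    augment_cfg$seed <- seed
    split$seed <- seed
    nn_cfg$seed <- seed
  }
  normalized <- lapply(arms, total_area_normalize)
  tbl <- NULL
  if (is.null(candidates)) {
    selections <- lapply(names(arms), function(a)
      select_candidates(protein_de_stats(normalized[[a]], cfg = de_cfg)))
    names(selections) <- names(arms)
    tbl <- consolidate_arms(selections)
    candidates <- default_candidates(tbl)
  }
  norm_real <- normalized[[centroid_arm]]
  candidates <- intersect(candidates, rownames(norm_real$values))
  if (length(candidates) < 2L)
    stopf("fewer than 2 candidate proteins available in arm %s", centroid_arm)
  exports <- export_centroids_and_sds(norm_real, candidates)
  cohort <- augment_cohort(exports$centroids, exports$sds, augment_cfg)
  parts <- split_cohort(cohort, split)
  model <- train_nn(parts$train, parts$val, nn_cfg)
  structure(list(candidates = candidates, candidate_table = tbl,
                 model = model,
                 test_confusion = evaluate(model, parts$test),
                 deploy_confusion = deploy_on_real(model, norm_real,
                                                   candidates),
                 centroids = exports$centroids, sds = exports$sds,
                 normalized = normalized),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d candidate proteins\n",
              length(x$candidates)))
  cat(sprintf("  synthetic test accuracy: %.2f%%\n",
              x$test_confusion$correct_rate))
  cat(sprintf("  real deploy accuracy:    %.2f%%\n",
              x$deploy_confusion$correct_rate))
  invisible(x)
}
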