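# Seeded fixture generator emulating the statistical structure of a pooled
# plasma SWATH experiment: wide abundance dynamic range, per-stage
# technical-replicate CVs, planted stage-consistent fold changes, and
# depletion-arm-specific protein subsets.

#' Fixture generator configuration
#'
#' Defaults emulate the study conditions of a pooled five-class plasma
#' experiment: 300 proteins spanning ten orders of magnitude, 37 planted
#' differentially-expressed proteins with stage-consistent symmetric fold
#' changes between 1.5 and 8, technical triplicates with per-stage target
#' CVs of 33/36/42/45/31 percent (healthy, I--IV), and a five-protein
#' "driver" subset carrying the largest fold changes so that panel
#' minimization has a recoverable truth.
#'
#' A configured CV is the *target observed* triplicate CV: the generator
#' internally calibrates the multiplicative noise scale so that the
#' expected sample CV over `n_replicates` zero-truncated draws equals the
#' target (see the methods vignette).
#'
#' @param n_proteins Number of proteins (default 300).
#' @param abundance_decades Orders of magnitude spanned by the (log-uniform)
#'   healthy centroids (default 10).
#' @param n_de Number of planted DE proteins (default 37).
#' @param de_fc_range Range of planted symmetric fold-change magnitudes
#'   (default `c(1.5, 8)`; lower bound must exceed 1).
#' @param de_exclude_top Fraction of the most abundant proteins that are
#'   ineligible for DE planting (default 0.1). Total-area normalization
#'   assumes the bulk high-abundance signal is condition-invariant; a
#'   fixture violating that assumption would not emulate a study in which
#'   the normalization was valid.
#' @param fc_monotone Sort each protein's planted magnitudes so they are
#'   non-decreasing with stage (default `TRUE`, mirroring progressive
#'   disease).
#' @param per_stage_cv Named target replicate CVs in percent for
#'   healthy, I, II, III, IV (defaults 33, 36, 42, 45, 31).
#' @param cv_spread Optional named per-stage SDs of a heteroscedastic
#'   per-protein CV draw (truncated normal); `NULL` (default) uses the
#'   fixed per-stage CVs, which keeps oracle tests clean.
#' @param n_replicates Technical replicates per condition (default 3).
#' @param arms Depletion arms to emit (default: all four).
#' @param retention Named per-arm probability that a protein is quantified
#'   in that arm (defaults: non-depleted arm complete, depleted arms 0.9 /
#'   0.8 / 0.8).
#' @param driver_panel_size Number of driver proteins (default 5).
#' @param seed Integer seed; fixtures are bit-reproducible given the config.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_proteins = 300L, abundance_decades = 10,
                           n_de = 37L, de_fc_range = c(1.5, 8),
                           de_exclude_top = 0.1,
                           fc_monotone = TRUE,
                           per_stage_cv = c(healthy = 33, I = 36, II = 42,
                                            III = 45, IV = 31),
                           cv_spread = NULL,
                           n_replicates = 3L, arms = PANEL_ARMS,
                           retention = c(none = 1, MARS14 = 0.9,
                                         MARS14_API = 0.8, API_MARS14 = 0.8),
                           driver_panel_size = 5L,
                           seed = NULL) {
  n_proteins <- as.integer(n_proteins); n_de <- as.integer(n_de)
  n_replicates <- as.integer(n_replicates)
  driver_panel_size <- as.integer(driver_panel_size)
  if (n_de > n_proteins)
    stopf("n_de (%d) cannot exceed n_proteins (%d)", n_de, n_proteins)
  stopifnot(n_replicates >= 2L, abundance_decades > 0,
            length(de_fc_range) == 2L, de_fc_range[1] > 1,
            de_fc_range[2] >= de_fc_range[1], driver_panel_size >= 0L)
  driver_panel_size <- min(driver_panel_size, n_de)
  arms <- as.character(as_arm(arms))
  stopifnot(all(PANEL_CONDITIONS %in% names(per_stage_cv)),
            de_exclude_top >= 0, de_exclude_top < 1)
  per_stage_cv <- per_stage_cv[PANEL_CONDITIONS]
  if (any(per_stage_cv < 0)) stopf("CVs must be non-negative")
  if (!all(arms %in% names(retention)))
    stopf("retention must be named for every arm")
  retention <- retention[arms]
  if (any(retention <= 0 | retention > 1))
    stopf("retention probabilities must be in (0, 1]")
  if (!is.null(cv_spread)) {
    stopifnot(all(PANEL_CONDITIONS %in% names(cv_spread)))
    cv_spread <- cv_spread[PANEL_CONDITIONS]
    if (any(cv_spread < 0)) stopf("cv_spread must be non-negative")
  }
  structure(list(n_proteins = n_proteins,
                 abundance_decades = abundance_decades, n_de = n_de,
                 de_fc_range = de_fc_range, de_exclude_top = de_exclude_top,
                 fc_monotone = fc_monotone,
                 per_stage_cv = per_stage_cv, cv_spread = cv_spread,
                 n_replicates = n_replicates, arms = arms,
                 retention = retention,
                 driver_panel_size = driver_panel_size, seed = seed),
            class = "fixture_config")
}

#' Consolidated multi-arm fixture preset
#'
#' The default [fixture_config()]: four depletion arms (full retention in
#' the non-depleted arm, partial protein retention in the depleted arms),
#' 300 proteins over ten abundance decades, 37 planted DE proteins and the
#' per-stage replicate CV targets -- the consolidated multi-arm study
#' design the pipeline is built for.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [fixture_config()].
#' @return A `fixture_config`.
#' @export
fixture_preset_consolidated <- function(seed = NULL, ...) {
  fixture_config(seed = seed, ...)
}

# Monotone cv -> tau interpolator for heteroscedastic per-protein CVs.
cv_tau_interpolator <- function(n_rep) {
  key <- sprintf("interp_%d", n_rep)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  grid <- seq(0, 110, by = 5)
  taus <- vapply(grid, calibrate_cv_tau, 0, n_rep = n_rep)
  f <- stats::splinefun(grid, taus, method = "hyman")
  .calib_cache[[key]] <- f
  f
}

#' Generate a synthetic pooled-plasma fixture
#'
#' Healthy centroids are log-uniform over the configured abundance decades;
#' planted DE proteins get stage centroids `healthy x FC_s` with a
#' consistent direction per protein; replicate values are
#' `centroid x max(0, 1 + tau x N(0,1))` with `tau` calibrated per stage so
#' that observed replicate CVs match the configured targets; each arm
#' retains each protein independently with its retention probability.
#' Byte-reproducible given the seed.
#'
#' @param cfg A [fixture_config()].
#' @return A list of class `plasma_fixture`: `arms` (named list of
#'   [quant_matrix()]s) and `truth` (planted DE table with directions and
#'   per-stage fold changes, driver ids, per-arm retained sets, the true
#'   centroid matrix, and the config).
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  P <- cfg$n_proteins
  ids <- sprintf("PROT%04d", seq_len(P))
  stages <- PANEL_CONDITIONS[-1]
  out <- with_seed_if(cfg$seed, {
    base <- 10^stats::runif(P, 0, cfg$abundance_decades)
    n_top <- floor(cfg$de_exclude_top * P)
    eligible <- seq_len(P)
    if (n_top > 0L && P - n_top >= cfg$n_de)
      eligible <- order(base)[seq_len(P - n_top)]
    de_idx <- sort(sample(eligible, cfg$n_de))
    dirs <- sample(c(1, -1), cfg$n_de, replace = TRUE)
    fcs <- matrix(stats::runif(cfg$n_de * 4, cfg$de_fc_range[1],
                               cfg$de_fc_range[2]),
                  nrow = cfg$n_de, ncol = 4,
                  dimnames = list(ids[de_idx], stages))
    if (cfg$fc_monotone && cfg$n_de > 0) {
      fcs <- matrix(t(apply(fcs, 1, sort, method = "radix")),
                    nrow = cfg$n_de, ncol = 4,
                    dimnames = list(ids[de_idx], stages))
    }
    centroids <- matrix(rep(base, each = 5), nrow = 5,
                        dimnames = list(PANEL_CONDITIONS, ids))
    for (j in seq_along(de_idx))
      centroids[stages, de_idx[j]] <-
        base[de_idx[j]] * fcs[j, ]^dirs[j]
    max_fc <- if (cfg$n_de > 0) apply(fcs, 1, max) else numeric(0)
    drivers <- if (cfg$n_de > 0)
      ids[de_idx][order(-max_fc, ids[de_idx])][seq_len(cfg$driver_panel_size)]
    else character(0)
    # per-stage noise scales (or per-protein when heteroscedastic)
    arms <- list(); retained <- list()
    for (a in cfg$arms) {
      keep <- stats::runif(P) <= cfg$retention[[a]]
      if (!any(keep)) stopf("arm %s retained no proteins", a)
      pa <- which(keep)
      vals <- matrix(NA_real_, length(pa), 5L * cfg$n_replicates)
      run_ids <- character(0); conds <- character(0); reps <- integer(0)
      col <- 0L
      for (cc in PANEL_CONDITIONS) {
        if (is.null(cfg$cv_spread)) {
          tau <- rep(calibrate_cv_tau(cfg$per_stage_cv[[cc]],
                                      cfg$n_replicates), length(pa))
        } else {
          # truncated-normal per-protein CV draw, capped at the largest
          # observed CV achievable under zero-truncated replicate noise
          cvp <- pmin(pmax(0, stats::rnorm(length(pa), cfg$per_stage_cv[[cc]],
                                           cfg$cv_spread[[cc]])), 110)
          tau <- cv_tau_interpolator(cfg$n_replicates)(cvp)
        }
        for (r in seq_len(cfg$n_replicates)) {
          col <- col + 1L
          z <- stats::rnorm(length(pa))
          vals[, col] <- centroids[cc, pa] * pmax(0, 1 + tau * z)
          run_ids <- c(run_ids, sprintf("%s_%s_r%d", a, cc, r))
          conds <- c(conds, cc); reps <- c(reps, r)
        }
      }
      rownames(vals) <- ids[pa]; colnames(vals) <- run_ids
      meta <- data.frame(run_id = run_ids, condition = conds, arm = a,
                         replicate = reps, stringsAsFactors = FALSE)
      arms[[a]] <- quant_matrix(vals, meta)
      retained[[a]] <- ids[pa]
    }
    de_tab <- data.frame(protein_id = ids[de_idx],
                         direction = ifelse(dirs > 0, "up", "down"),
                         stringsAsFactors = FALSE)
    for (s in stages) de_tab[[paste0("fc_", s)]] <- fcs[, s]^dirs
    list(arms = arms,
         truth = list(de = de_tab, drivers = drivers, retained = retained,
                      centroids = centroids, config = cfg))
  })
  structure(out, class = "plasma_fixture")
}

#' @export
print.plasma_fixture <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<plasma_fixture> %d proteins, %d DE (drivers: %s), arms: %s\n",
              cfg$n_proteins, cfg$n_de,
              paste(x$truth$drivers, collapse = ", "),
              paste(names(x$arms), collapse = ", ")))
  invisible(x)
}

#' Export per-class centroids and replicate SDs from a quantitation matrix
#'
#' Per-class, per-protein replicate means and sample SDs on the linear
#' normalized scale, aligned on the same protein panel -- the bridge from a
#' measured (or generated) matrix to [augment_cohort()]. Raw matrices are
#' total-area normalized first.
#'
#' @param m A `quant_matrix` (single arm) or `normalized_matrix`.
#' @param proteins Protein subset (`NULL` = all).
#' @return A list with `centroids` and `sds`, both class x protein matrices
#'   with identical dimnames.
#' @export
export_centroids_and_sds <- function(m, proteins = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  if (!inherits(m, "normalized_matrix")) m <- total_area_normalize(m)
  linv <- linear_values(m)
  if (!is.null(proteins)) {
    absent <- setdiff(proteins, rownames(linv))
    if (length(absent) > 0L)
      stopf("protein(s) absent from matrix: %s", paste(absent, collapse = ", "))
    linv <- linv[proteins, , drop = FALSE]
  }
  cond <- as.character(m$runs$condition)
  classes <- PANEL_CONDITIONS[PANEL_CONDITIONS %in% unique(cond)]
  cen <- matrix(NA_real_, length(classes), nrow(linv),
                dimnames = list(classes, rownames(linv)))
  sdm <- cen
  for (cc in classes) {
    sub <- linv[, cond == cc, drop = FALSE]
    cen[cc, ] <- rowMeans(sub, na.rm = TRUE)
    sdm[cc, ] <- apply(sub, 1, stats::sd, na.rm = TRUE)
  }
  list(centroids = cen, sds = sdm)
}

#' Write a fixture to disk as TSV tables plus a ground-truth JSON
#'
#' Emits, per arm, the same TSV dialect consumed by [read_quant_table()]
#' (`<arm>_matrix.tsv`, `<arm>_runs.tsv`), plus `truth.json`.
#'
#' @param fixture A `plasma_fixture`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "plasma_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (a in names(fixture$arms)) {
    fm <- file.path(dir, paste0(a, "_matrix.tsv"))
    fr <- file.path(dir, paste0(a, "_runs.tsv"))
    write_quant_table(fixture$arms[[a]], fm, fr)
    files <- c(files, fm, fr)
  }
  ft <- file.path(dir, "truth.json")
  tr <- fixture$truth
  jsonlite::write_json(list(de = tr$de, drivers = tr$drivers,
                            retained = tr$retained,
                            config = tr$config[!vapply(tr$config, is.null, TRUE)]),
                       ft, digits = NA, auto_unbox = TRUE)
  invisible(c(files, ft))
}
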