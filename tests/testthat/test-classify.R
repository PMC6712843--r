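# Splitting, the shallow network, baselines, confusion matrices and
# deployment on real replicate runs.

make_cohort <- function(n_per_class = 40, k_sd = 1, seed = 1,
                        n_prot = 6, policy = "allow") {
  cen <- toy_centroids(n_prot)
  augment_cohort(cen, toy_sds(cen), augment_config(n_per_class, k_sd, seed,
                                                   negative_policy = policy))
}

test_that("stratified split: exact arithmetic, partition, determinism", {
  co <- make_cohort(100, seed = 2)
  sp <- split_cohort(co, split_spec(seed = 5))
  expect_equal(nrow(sp$train$values), 350L)
  expect_equal(nrow(sp$val$values), 75L)
  expect_equal(nrow(sp$test$values), 75L)
  expect_equal(unname(table(sp$train$labels)), rep(70L, 5),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$labels)), rep(15L, 5), ignore_attr = TRUE)
  # disjoint and exhaustive
  ids <- c(rownames(sp$train$values), rownames(sp$val$values),
           rownames(sp$test$values))
  expect_setequal(ids, rownames(co$values))
  expect_equal(anyDuplicated(ids), 0L)
  # determinism and seed sensitivity
  sp2 <- split_cohort(co, split_spec(seed = 5))
  expect_identical(sp$train$values, sp2$train$values)
  sp3 <- split_cohort(co, split_spec(seed = 6))
  expect_false(identical(rownames(sp$train$values),
                         rownames(sp3$train$values)))
  expect_error(split_spec(0.8, 0.15, 0.15), "sum to 1")
})

test_that("all three classifier kinds are perfect on a zero-noise cohort", {
  co <- make_cohort(20, k_sd = 0, seed = 3)
  sp <- split_cohort(co, split_spec(seed = 3))
  nn <- train_nn(sp$train, sp$val, nn_config(seed = 3, max_epochs = 300))
  expect_equal(evaluate(nn, sp$train)$correct_rate, 100)
  expect_equal(evaluate(nn, sp$val)$correct_rate, 100)
  expect_equal(evaluate(nn, sp$test)$correct_rate, 100)
  knn <- train_baselines(sp$train, sp$val, "knn")
  expect_equal(evaluate(knn, sp$test)$correct_rate, 100)
  tree <- train_baselines(sp$train, sp$val, "tree")
  expect_equal(evaluate(tree, sp$test)$correct_rate, 100)
  # knn with k = 1 classifies its own training data perfectly
  knn1 <- train_baselines(sp$train, sp$val, "knn", grid = 1L)
  expect_equal(evaluate(knn1, sp$train)$correct_rate, 100)
})

test_that("permuted labels give chance-level test accuracy for all kinds", {
  co <- make_cohort(60, k_sd = 1, seed = 4)
  co$labels <- withr::with_seed(9, sample(co$labels))
  sp <- split_cohort(co, split_spec(seed = 4))
  n_test <- nrow(sp$test$values)
  se <- 100 * sqrt(0.2 * 0.8 / n_test)
  accs <- c(
    evaluate(train_nn(sp$train, sp$val,
                      nn_config(seed = 4, max_epochs = 150)),
             sp$test)$correct_rate,
    evaluate(train_baselines(sp$train, sp$val, "knn"), sp$test)$correct_rate,
    evaluate(train_baselines(sp$train, sp$val, "tree"), sp$test)$correct_rate)
  for (a in accs) expect_lt(abs(a - 20), 3.5 * se)
})

test_that("confusion matrices conserve counts and define the correct rate", {
  co <- make_cohort(10, k_sd = 1, seed = 5)
  sp <- split_cohort(co, split_spec(seed = 5))
  nn <- train_nn(sp$train, sp$val, nn_config(seed = 5, max_epochs = 60))
  cm <- evaluate(nn, sp$test)
  expect_equal(sum(cm$counts), nrow(sp$test$values))
  expect_equal(unname(rowSums(cm$counts)),
               unname(table(sp$test$labels)), ignore_attr = TRUE)
  expect_equal(cm$correct_rate, 100 * sum(diag(cm$counts)) / sum(cm$counts))
  expect_error(evaluate(nn, list(values = sp$test$values,
                                 labels = factor(rep("V", 15)))), "unseen")
})

test_that("network training is deterministic under seed and logs early stopping", {
  co <- make_cohort(30, k_sd = 2, seed = 6)
  sp <- split_cohort(co, split_spec(seed = 6))
  cfg <- nn_config(seed = 11, max_epochs = 120, patience = 10)
  m1 <- train_nn(sp$train, sp$val, cfg)
  m2 <- train_nn(sp$train, sp$val, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, sp$test$values), predict(m2, sp$test$values))
  expect_true(all(c("epoch", "train_loss", "val_loss") %in%
                  names(m1$training_log)))
  expect_lte(m1$epochs_run, cfg$max_epochs)
  expect_error(train_nn(list(values = matrix(c(1, NA, 1, 2), 2),
                             labels = factor(c("healthy", "I"))),
                        sp$val, cfg), "non-finite")
})

test_that("the hand-rolled network agrees with an independent learner", {
  skip_if_not_installed("nnet")
  co <- make_cohort(30, k_sd = 3, seed = 7)
  sp <- split_cohort(co, split_spec(seed = 7))
  ours <- evaluate(train_nn(sp$train, sp$val,
                            nn_config(seed = 7, max_epochs = 300)),
                   sp$test)$correct_rate
  Xs <- scale(sp$train$values)
  Xt <- scale(sp$test$values, center = attr(Xs, "scaled:center"),
              scale = attr(Xs, "scaled:scale"))
  ref <- withr::with_seed(7, nnet::nnet(Xs, nnet::class.ind(sp$train$labels),
                                        size = 10, softmax = TRUE,
                                        maxit = 300, trace = FALSE))
  ref_acc <- 100 * mean(levels(sp$train$labels)[max.col(
    predict(ref, Xt))] == as.character(sp$test$labels))
  expect_lt(abs(ours - ref_acc), 15)  # same task, comparable skill
})

test_that("deployment aligns panel proteins by id, not column position", {
  fx <- generate_fixture(fixture_config(n_proteins = 40, n_de = 8,
                                        de_fc_range = c(3, 6),
                                        arms = "none", seed = 12))
  nm <- total_area_normalize(fx$arms$none)
  panel <- fx$truth$de$protein_id
  ex <- export_centroids_and_sds(nm, panel)
  co <- augment_cohort(ex$centroids, ex$sds,
                       augment_config(n_per_class = 60, k_sd = 2, seed = 12))
  sp <- split_cohort(co, split_spec(seed = 12))
  nn <- train_nn(sp$train, sp$val, nn_config(seed = 12, max_epochs = 200))
  cm <- deploy_on_real(nn, nm, panel)
  expect_equal(sum(cm$counts), 15)
  expect_equal(unname(rowSums(cm$counts)), rep(3, 5), ignore_attr = TRUE)

  # shuffling the row order of the real matrix leaves predictions unchanged
  perm <- withr::with_seed(2, sample(nrow(nm$values)))
  nm_shuf <- nm; nm_shuf$values <- nm$values[perm, , drop = FALSE]
  cm2 <- deploy_on_real(nn, nm_shuf, panel)
  expect_identical(cm$counts, cm2$counts)
  expect_error(deploy_on_real(nn, nm, c(panel, "GHOST")), "GHOST")

  # pooled-mean mode classifies 5 items
  cm3 <- deploy_on_real(nn, nm, panel, unit = "pooled_mean")
  expect_equal(sum(cm3$counts), 5)
})

test_that("real centroids under a zero-noise-trained model classify perfectly", {
  fx <- generate_fixture(fixture_config(
    n_proteins = 25, n_de = 6, arms = "none", seed = 13,
    per_stage_cv = c(healthy = 0, I = 0, II = 0, III = 0, IV = 0)))
  nm <- total_area_normalize(fx$arms$none)
  panel <- fx$truth$de$protein_id
  ex <- export_centroids_and_sds(nm, panel)
  co <- augment_cohort(ex$centroids, ex$sds,
                       augment_config(n_per_class = 20, k_sd = 0, seed = 13))
  sp <- split_cohort(co, split_spec(seed = 13))
  nn <- train_nn(sp$train, sp$val, nn_config(seed = 13, max_epochs = 300))
  expect_equal(deploy_on_real(nn, nm, panel)$correct_rate, 100)
})

test_that("accuracy degrades monotonically (in median) as k_sd grows", {
  fx <- generate_fixture(fixture_config(n_proteins = 50, n_de = 12,
                                        arms = "none", seed = 20))
  nm <- total_area_normalize(fx$arms$none)
  panel <- fx$truth$de$protein_id
  ex <- export_centroids_and_sds(nm, panel)
  # pooled SDs + `allow` isolate the noise-scale effect: per-class SDs are
  # a covariance signature that keeps discriminating at large k_sd, and
  # truncation adds a class-dependent point mass at zero
  pooled <- matrix(colMeans(ex$sds), 5, ncol(ex$sds), byrow = TRUE,
                   dimnames = dimnames(ex$sds))
  med_acc <- vapply(c(0, 1, 5, 10, 20), function(k) {
    accs <- vapply(1:10, function(s) {
      co <- augment_cohort(ex$centroids, pooled,
                           augment_config(n_per_class = 120, k_sd = k,
                                          seed = s,
                                          negative_policy = "allow"))
      sp <- split_cohort(co, split_spec(seed = s))
      nn <- train_nn(sp$train, sp$val,
                     nn_config(seed = s, max_epochs = 150, patience = 15))
      evaluate(nn, sp$test)$correct_rate
    }, 0)
    stats::median(accs)
  }, 0)
  expect_true(all(diff(med_acc) <= 0))
})

test_that("network JSON serialization round-trips predictions exactly", {
  co <- make_cohort(15, k_sd = 2, seed = 21)
  sp <- split_cohort(co, split_spec(seed = 21))
  nn <- train_nn(sp$train, sp$val, nn_config(seed = 21, max_epochs = 80))
  tf <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(nn, tf)
  back <- read_classifier_json(tf)
  expect_identical(predict(back, sp$test$values),
                   predict(nn, sp$test$values))
})
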