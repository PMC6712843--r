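# Supervised stage classification: stratified splitting, a shallow
# feed-forward network, k-nearest-neighbor / decision-tree baselines,
# confusion-matrix evaluation and deployment on held-out real runs.

#' Train/validation/test split specification
#'
#' @param train_frac,val_frac,test_frac Fractions summing to 1
#'   (defaults 0.70 / 0.15 / 0.15).
#' @param seed Integer seed for the shuffle.
#' @param stratified Split within each class (default `TRUE`).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.70, val_frac = 0.15, test_frac = 0.15,
                       seed = NULL, stratified = TRUE) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-12)
    stopf("split fractions must sum to 1")
  stopifnot(train_frac > 0, val_frac >= 0, test_frac >= 0)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = seed, stratified = stratified),
            class = "split_spec")
}

# Internal labelled-data container used by all classifiers.
labelled_data <- function(values, labels) {
  stopifnot(nrow(values) == length(labels))
  list(values = as.matrix(values), labels = labels)
}

#' Split a cohort into train / validation / test sets
#'
#' Disjoint, exhaustive, seeded partition; stratified by class by default so
#' per-class counts are within one of `fraction x n`.
#'
#' @param cohort A `synthetic_cohort` (or any list with `values` and
#'   `labels`).
#' @param spec A [split_spec()].
#' @return A list with elements `train`, `val`, `test`, each holding
#'   `values` and `labels`.
#' @export
split_cohort <- function(cohort, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  labels <- cohort$labels; values <- cohort$values
  n <- length(labels)
  assign_group <- function(idx) {
    k <- length(idx)
    n_tr <- round(spec$train_frac * k)
    n_va <- round(spec$val_frac * k)
    n_te <- k - n_tr - n_va
    if (min(n_tr, n_va, n_te) < 0) stopf("split produced a negative count")
    split(idx, rep(c("train", "val", "test"), c(n_tr, n_va, n_te)))
  }
  parts <- with_seed_if(spec$seed, {
    if (spec$stratified) {
      per_class <- lapply(split(seq_len(n), labels),
                          function(idx) assign_group(sample(idx)))
      list(train = unlist(lapply(per_class, `[[`, "train"), use.names = FALSE),
           val = unlist(lapply(per_class, `[[`, "val"), use.names = FALSE),
           test = unlist(lapply(per_class, `[[`, "test"), use.names = FALSE))
    } else assign_group(sample(seq_len(n)))
  })
  out <- lapply(parts[c("train", "val", "test")], function(idx) {
    idx <- sort(idx)
    labelled_data(values[idx, , drop = FALSE], labels[idx])
  })
  names(out) <- c("train", "val", "test")
  out
}

#' Shallow-network configuration
#'
#' One hidden layer (10 units by default, matching a classical pattern-
#' recognition network), tanh activation, softmax output trained by
#' full-batch Adam on the cross-entropy loss, with early stopping on the
#' validation loss.
#'
#' @param hidden_units Hidden-layer width (default 10).
#' @param activation Hidden activation; only `"tanh"` is implemented.
#' @param max_epochs Maximum training epochs (default 400).
#' @param patience Epochs without validation improvement before stopping
#'   (default 30).
#' @param learning_rate Adam step size (default 0.02).
#' @param seed Integer seed for weight initialization.
#' @param standardize_inputs z-score features by training-set statistics
#'   (default `TRUE`; raw peak areas span orders of magnitude).
#' @return A list of class `nn_config`.
#' @export
nn_config <- function(hidden_units = 10L, activation = "tanh",
                      max_epochs = 400L, patience = 30L,
                      learning_rate = 0.02, seed = NULL,
                      standardize_inputs = TRUE) {
  stopifnot(hidden_units >= 1L, patience >= 1L, max_epochs >= 1L,
            learning_rate > 0, identical(activation, "tanh"))
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = activation,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = seed,
                 standardize_inputs = standardize_inputs),
            class = "nn_config")
}

standardizer_from <- function(X, on) {
  if (!on) return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center, `-`), 2, std$scale, `/`)
}

nn_forward <- function(X, w) {
  A <- tanh(sweep(X %*% w$W1, 2, w$b1, `+`))
  Z <- sweep(A %*% w$W2, 2, w$b2, `+`)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(A = A, P = P)
}

nn_loss <- function(P, Yidx) {
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), Yidx)], 1e-300)))
}

#' Train the shallow neural network
#'
#' Full-batch Adam on softmax cross-entropy with validation-loss early
#' stopping; the weights achieving the best validation loss are kept.
#' Training is deterministic given the seed.
#'
#' @param train,val Labelled data (`values`, `labels`), e.g. from
#'   [split_cohort()].
#' @param cfg An [nn_config()].
#' @return A `trained_classifier` (kind `"nn"`) with weights,
#'   standardization statistics, class levels and a per-epoch training log.
#' @export
train_nn <- function(train, val, cfg = nn_config()) {
  stopifnot(inherits(cfg, "nn_config"))
  X <- as.matrix(train$values)
  if (!all(is.finite(X))) stopf("non-finite training inputs")
  classes <- levels(train$labels)
  if (length(unique(train$labels)) < 2L) stopf("need >= 2 classes in training data")
  std <- standardizer_from(X, cfg$standardize_inputs)
  Xs <- apply_standardizer(X, std)
  Xv <- apply_standardizer(as.matrix(val$values), std)
  if (!all(is.finite(Xv))) stopf("non-finite validation inputs")
  Yidx <- as.integer(train$labels)
  Yv <- as.integer(val$labels)
  n <- nrow(Xs); d <- ncol(Xs); h <- cfg$hidden_units; K <- length(classes)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), Yidx)] <- 1
  w <- with_seed_if(cfg$seed, list(
    W1 = matrix(stats::rnorm(d * h, sd = 1 / sqrt(d)), d, h),
    b1 = rep(0, h),
    W2 = matrix(stats::rnorm(h * K, sd = 1 / sqrt(h)), h, K),
    b2 = rep(0, K)))
  mom <- lapply(w, function(p) p * 0)
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- NULL; best_val <- Inf; wait <- 0L; log_rows <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- nn_forward(Xs, w)
    dZ <- (fw$P - Y) / n
    gr <- list(W1 = crossprod(Xs, (dZ %*% t(w$W2)) * (1 - fw$A^2)),
               b1 = colSums((dZ %*% t(w$W2)) * (1 - fw$A^2)),
               W2 = crossprod(fw$A, dZ),
               b2 = colSums(dZ))
    for (p in names(w)) {
      mom[[p]] <- b1 * mom[[p]] + (1 - b1) * gr[[p]]
      vel[[p]] <- b2 * vel[[p]] + (1 - b2) * gr[[p]]^2
      mhat <- mom[[p]] / (1 - b1^epoch)
      vhat <- vel[[p]] / (1 - b2^epoch)
      w[[p]] <- w[[p]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    train_loss <- nn_loss(fw$P, Yidx)
    val_loss <- nn_loss(nn_forward(Xv, w)$P, Yv)
    log_rows[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                           val_loss = val_loss)
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best <- w; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  log <- as.data.frame(do.call(rbind, log_rows))
  structure(list(kind = "nn", weights = best %||% w, standardizer = std,
                 classes = classes, features = colnames(X),
                 config = cfg,
                 training_log = log,
                 best_val_loss = best_val, epochs_run = nrow(log)),
            class = "trained_classifier")
}

#' Train a baseline classifier (k-nearest-neighbor or decision tree)
#'
#' The hyperparameter (k, or tree depth) is picked on the validation set
#' over a small grid; ties go to the simpler model. kNN distances are
#' computed on features standardized by training statistics; the tree works
#' on raw features (scale-invariant).
#'
#' @param train,val Labelled data (`values`, `labels`).
#' @param kind `"knn"` or `"tree"`.
#' @param grid Candidate k values (knn; default 1,3,5,7,9,11) or maximum
#'   depths (tree; default 1..6).
#' @return A `trained_classifier`.
#' @export
train_baselines <- function(train, val, kind = c("knn", "tree"), grid = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(train$values)
  classes <- levels(train$labels)
  if (kind == "knn") {
    grid <- grid %||% c(1L, 3L, 5L, 7L, 9L, 11L)
    if (any(grid > nrow(X)))
      stopf("k = %d exceeds training size %d", max(grid), nrow(X))
    std <- standardizer_from(X, TRUE)
    Xs <- apply_standardizer(X, std)
    Xv <- apply_standardizer(as.matrix(val$values), std)
    acc <- vapply(grid, function(k) {
      pred <- knn_deterministic(Xs, Xv, train$labels, k)
      mean(pred == val$labels)
    }, 0)
    k_best <- grid[which.max(acc)]
    structure(list(kind = "knn", train_x = Xs, train_y = train$labels,
                   k = k_best, standardizer = std, classes = classes,
                   features = colnames(X),
                   validation = data.frame(k = grid, accuracy = acc)),
              class = "trained_classifier")
  } else {
    grid <- grid %||% 1:6
    df <- data.frame(.y = train$labels, X, check.names = FALSE)
    vdf <- data.frame(as.matrix(val$values), check.names = FALSE)
    fits <- lapply(grid, function(d)
      rpart::rpart(.y ~ ., data = df,
                   method = "class",
                   control = rpart::rpart.control(maxdepth = d, cp = 0,
                                                  xval = 0, minsplit = 2)))
    acc <- vapply(fits, function(f) {
      pred <- predict(f, vdf, type = "class")
      mean(pred == val$labels)
    }, 0)
    best <- which.max(acc)
    structure(list(kind = "tree", fit = fits[[best]], depth = grid[best],
                   classes = classes, features = colnames(X),
                   validation = data.frame(depth = grid, accuracy = acc)),
              class = "trained_classifier")
  }
}

# class::knn with vote ties broken under a fixed local RNG state, so
# predictions are a pure function of (model, input).
knn_deterministic <- function(train_x, test_x, train_y, k) {
  withr::with_seed(1L, class::knn(train_x, test_x, train_y, k = k))
}

#' @export
print.trained_classifier <- function(x, ...) {
  extra <- switch(x$kind,
                  nn = sprintf("%d hidden units, %d epochs, best val loss %.4f",
                               x$config$hidden_units, x$epochs_run,
                               x$best_val_loss),
                  knn = sprintf("k = %d", x$k),
                  tree = sprintf("depth = %d", x$depth))
  cat(sprintf("<trained_classifier:%s> %d features, %d classes (%s)\n",
              x$kind, length(x$features), length(x$classes), extra))
  invisible(x)
}

#' Predict class labels
#'
#' @param object A `trained_classifier`.
#' @param newdata Numeric matrix (samples x features). When column names
#'   are present they are aligned to the model's feature order.
#' @param ... Unused.
#' @return Factor of predicted labels. Argmax ties break toward the lowest
#'   class index.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$features)) {
    absent <- setdiff(object$features, colnames(X))
    if (length(absent) > 0L)
      stopf("missing model feature(s): %s", paste(absent, collapse = ", "))
    X <- X[, object$features, drop = FALSE]
  }
  if (object$kind == "nn") {
    Xs <- apply_standardizer(X, object$standardizer)
    P <- nn_forward(Xs, object$weights)$P
    factor(object$classes[max.col(P, ties.method = "first")],
           levels = object$classes)
  } else if (object$kind == "knn") {
    Xs <- apply_standardizer(X, object$standardizer)
    factor(as.character(knn_deterministic(object$train_x, Xs,
                                          object$train_y, object$k)),
           levels = object$classes)
  } else {
    df <- data.frame(X, check.names = FALSE)
    factor(as.character(predict(object$fit, df, type = "class")),
           levels = object$classes)
  }
}

new_confusion_matrix <- function(truth, pred, classes) {
  counts <- table(factor(truth, levels = classes),
                  factor(pred, levels = classes))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("true", "predicted")
  structure(list(classes = classes, counts = counts,
                 correct_rate = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' Evaluate a classifier on labelled data
#'
#' @param model A `trained_classifier`.
#' @param data Labelled data (`values`, `labels`).
#' @return A `confusion_matrix`: 5 x 5 counts (rows = true, columns =
#'   predicted) and the correct-classification rate in percent.
#' @export
evaluate <- function(model, data) {
  unseen <- setdiff(unique(as.character(data$labels)), model$classes)
  if (length(unseen) > 0L)
    stopf("label(s) unseen by the model: %s", paste(unseen, collapse = ", "))
  pred <- predict(model, data$values)
  new_confusion_matrix(as.character(data$labels), pred, model$classes)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> correct classification %.1f%% (n = %d)\n",
              x$correct_rate, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Deploy a trained classifier on real pooled replicate runs
#'
#' Classifies the real (never-trained-on) pooled values: each technical
#' replicate run independently by default, or the per-condition replicate
#' means (`unit = "pooled_mean"`). Features are taken on the linear
#' normalized scale and aligned to the model's panel by protein id, never
#' by column position.
#'
#' @param model A `trained_classifier`.
#' @param real A `normalized_matrix` of the real pooled runs (single arm).
#' @param panel Protein ids to use (default: the model's features).
#' @param unit `"replicate"` (default; one item per run) or
#'   `"pooled_mean"` (one item per condition).
#' @return A `confusion_matrix` over the classified items.
#' @export
deploy_on_real <- function(model, real, panel = NULL,
                           unit = c("replicate", "pooled_mean")) {
  unit <- match.arg(unit)
  panel <- panel %||% model$features
  linv <- linear_values(real)
  absent <- setdiff(panel, rownames(linv))
  if (length(absent) > 0L)
    stopf("panel protein(s) missing from real data: %s",
          paste(absent, collapse = ", "))
  X <- t(linv[panel, , drop = FALSE])
  truth <- as.character(real$runs$condition)
  if (unit == "pooled_mean") {
    agg <- rowsum(X, truth, na.rm = TRUE) /
      as.vector(table(truth)[sort(unique(truth))])
    X <- agg
    truth <- rownames(agg)
  }
  if (anyNA(X)) stopf("missing values in the real panel data")
  pred <- predict(model, X)
  unseen <- setdiff(unique(truth), model$classes)
  if (length(unseen) > 0L)
    stopf("label(s) unseen by the model: %s", paste(unseen, collapse = ", "))
  new_confusion_matrix(truth, pred, model$classes)
}

#' Serialize a trained shallow network to JSON
#'
#' Writes architecture, weights, standardization statistics and class
#' levels; [read_classifier_json()] restores a predictor that reproduces
#' the original predictions exactly.
#'
#' @param model A `trained_classifier` of kind `"nn"`.
#' @param path Output JSON path.
#' @return Invisibly, `model`.
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(model$kind == "nn")
  obj <- list(kind = "nn",
              classes = model$classes, features = model$features,
              hidden_units = model$config$hidden_units,
              activation = model$config$activation,
              center = model$standardizer$center,
              scale = model$standardizer$scale,
              W1 = model$weights$W1, b1 = model$weights$b1,
              W2 = model$weights$W2, b2 = model$weights$b2)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(model)
}

#' Restore a shallow network from JSON
#'
#' @param path Path written by [write_classifier_json()].
#' @return A `trained_classifier` of kind `"nn"` (prediction-only; no
#'   training log).
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$kind, "nn"))
  structure(list(kind = "nn",
                 weights = list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
                                W2 = as.matrix(obj$W2), b2 = as.numeric(obj$b2)),
                 standardizer = list(center = as.numeric(obj$center),
                                     scale = as.numeric(obj$scale)),
                 classes = obj$classes, features = obj$features,
                 config = nn_config(hidden_units = obj$hidden_units)),
            class = "trained_classifier")
}
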