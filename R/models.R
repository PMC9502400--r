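# Classifier families, hyperparameter grids, MCC-scored grid search and
# repeated random-split cross-validation.
#
# Four families operate on binary fingerprint matrices:
#
#   rf    random forest (randomForest); n_estimators in {100, 500},
#         max_features in {log2, sqrt, none}
#   svm   C-SVC (kernlab) on a precomputed linear or Tanimoto Gram matrix;
#         C in {0.01, 0.1, 1, 10, 100}; probability scores via kernlab's
#         seeded Platt calibration
#   knn   k-nearest neighbours on Tanimoto distance; k in 1..30, uniform or
#         distance weights
#   mlp   multi-layer perceptron (see mlp.R); architectures {[50,50,50],
#         [50,100,50], [100]}, solvers {lbfgs, adam, sgd}, activations
#         {identity, logistic, tanh, relu}, learning_rate_init in
#         {1e-2 .. 1e-5}
#
# Every model exposes a probability score (PS) for the ACTIVE class; a
# compound is predicted active when PS >= 0.5 unless a different threshold
# is requested.

.MODEL_FAMILIES <- c("rf", "svm", "knn", "mlp")
.CLASSES <- c("INACTIVE", "ACTIVE")

.as_labels <- function(y) {
  y <- toupper(as.character(y))
  if (!all(y %in% .CLASSES)) .stopf("labels must be ACTIVE or INACTIVE")
  factor(y, levels = .CLASSES)
}

#' Declared hyperparameter grid of a model family
#'
#' Returns the full grid in its deterministic enumeration order (the order
#' that breaks grid-search ties: earlier entries win).
#'
#' @param family one of `"rf"`, `"svm"`, `"knn"`, `"mlp"`.
#' @return list of hyperparameter lists.
#' @export
default_grid <- function(family) {
  family <- match.arg(tolower(family), .MODEL_FAMILIES)
  grid <- list()
  add <- function(...) grid[[length(grid) + 1L]] <<- list(...)
  switch(family,
    rf = for (n in c(100L, 500L)) {
      for (mf in c("log2", "sqrt", "none")) add(n_estimators = n, max_features = mf)
    },
    svm = for (C in c(0.01, 0.1, 1, 10, 100)) {
      for (k in c("linear", "tanimoto")) add(C = C, kernel = k)
    },
    knn = for (k in 1:30) {
      for (w in c("uniform", "distance")) add(n_neighbors = k, weights = w)
    },
    mlp = for (h in list(c(50L, 50L, 50L), c(50L, 100L, 50L), 100L)) {
      for (s in c("lbfgs", "adam", "sgd")) {
        for (a in c("identity", "logistic", "tanh", "relu")) {
          for (lr in c(0.01, 0.001, 0.0001, 0.00001)) {
            add(hidden_layer_sizes = h, solver = s, activation = a,
                learning_rate_init = lr)
          }
        }
      }
    }
  )
  grid
}

.default_hyperparams <- function(family) {
  switch(family,
    rf  = list(n_estimators = 500L, max_features = "sqrt"),
    svm = list(C = 1, kernel = "tanimoto"),
    knn = list(n_neighbors = 5L, weights = "distance"),
    mlp = list(hidden_layer_sizes = 100L, solver = "adam",
               activation = "relu", learning_rate_init = 0.001))
}

.check_hyperparams <- function(family, hp) {
  allowed <- switch(family,
    rf = c("n_estimators", "max_features"),
    svm = c("C", "kernel"),
    knn = c("n_neighbors", "weights"),
    mlp = c("hidden_layer_sizes", "solver", "activation", "learning_rate_init",
            "max_iter"))
  bad <- setdiff(names(hp), allowed)
  if (length(bad)) .stopf("unknown %s hyperparameter(s): %s", family,
                          paste(bad, collapse = ", "))
  modifyList(.default_hyperparams(family), hp)
}

.svm_kernel_matrix <- function(kernel, X, Y = X) {
  switch(kernel,
    linear = {
      Xd <- as.matrix(X); Yd <- as.matrix(Y)
      storage.mode(Xd) <- "double"; storage.mode(Yd) <- "double"
      unname(Xd %*% t(Yd))
    },
    tanimoto = tanimoto_kernel_matrix(X, Y),
    .stopf("unknown SVM kernel '%s'", kernel))
}

# PS of the ACTIVE class for test rows given a test-by-train Tanimoto
# distance matrix. Zero distances dominate under distance weighting.
.knn_ps <- function(D, y01, k, weights) {
  k <- min(k, ncol(D))
  apply(D, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    if (weights == "uniform") {
      mean(y01[nn])
    } else {
      dz <- d[nn]
      if (any(dz <= 1e-12)) return(mean(y01[nn[dz <= 1e-12]]))
      w <- 1 / dz
      sum(w * y01[nn]) / sum(w)
    }
  })
}

#' Train a fingerprint classifier
#'
#' Fits one model of the given family on a binary fingerprint matrix.
#' The fitted object exposes probability scores for the ACTIVE class through
#' [predict.vs_model()] and is deterministic given `seed`.
#'
#' @param X binary fingerprint matrix (one row per compound), as produced by
#'   [fingerprint_matrix()].
#' @param y labels, `"ACTIVE"`/`"INACTIVE"`, aligned with the rows of `X`.
#'   Both classes must be present.
#' @param family `"rf"`, `"svm"`, `"knn"` or `"mlp"`.
#' @param hyperparams named list of hyperparameters (defaults filled in from
#'   the family's defaults; see [default_grid()] for the tunable names).
#' @param seed integer seed for the stochastic families.
#' @return object of class `vs_model`.
#' @export
vs_train <- function(X, y, family = "rf", hyperparams = list(), seed = 1L) {
  family <- match.arg(tolower(family), .MODEL_FAMILIES)
  X <- as.matrix(X)
  yf <- .as_labels(y)
  if (nrow(X) != length(yf)) .stopf("X and y sizes differ")
  if (length(unique(yf)) < 2) {
    .stopf("training data must contain both classes")
  }
  hp <- .check_hyperparams(family, hyperparams)
  y01 <- as.integer(yf == "ACTIVE")

  fit <- switch(family,
    rf = {
      mtry <- switch(hp$max_features,
        log2 = max(1L, floor(log2(ncol(X)))),
        sqrt = max(1L, floor(sqrt(ncol(X)))),
        none = ncol(X),
        .stopf("unknown max_features '%s'", hp$max_features))
      .with_seed(seed,
        randomForest::randomForest(x = X, y = yf, ntree = hp$n_estimators,
                                   mtry = mtry))
    },
    svm = {
      K <- .svm_kernel_matrix(hp$kernel, X)
      .with_seed(seed,
        kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                      C = hp$C, prob.model = TRUE))
    },
    knn = NULL,  # lazy learner: the training set is the model
    mlp = .mlp_fit(X, y01,
                   hidden = hp$hidden_layer_sizes,
                   activation = hp$activation,
                   solver = hp$solver,
                   learning_rate_init = hp$learning_rate_init,
                   max_iter = if (is.null(hp$max_iter)) 200L else hp$max_iter,
                   seed = seed)
  )

  structure(list(
    family = family,
    hyperparams = hp,
    seed = as.integer(seed),
    classes = .CLASSES,
    fingerprint = list(family = attr(X, "family"), params = attr(X, "params")),
    fit = fit,
    X_train = if (family %in% c("svm", "knn")) X else NULL,
    n_bits = ncol(X),
    y01 = y01,
    n_train = nrow(X),
    n_active = sum(y01)
  ), class = "vs_model")
}

#' Probability scores and labels from a fitted classifier
#'
#' @param object a `vs_model` from [vs_train()].
#' @param newdata fingerprint matrix with the same column count (and family,
#'   if tagged) as the training matrix.
#' @param type `"ps"` for the numeric probability scores of the ACTIVE
#'   class, `"label"` for thresholded labels, `"both"` for a data.frame.
#' @param threshold classification threshold (active when PS >= threshold).
#' @param ... unused.
#' @return numeric vector, character vector, or data.frame.
#' @export
predict.vs_model <- function(object, newdata, type = c("ps", "label", "both"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  fam_new <- attr(newdata, "family")
  if (!is.null(fam_new) && !is.null(object$fingerprint$family) &&
      !identical(fam_new, object$fingerprint$family)) {
    .stopf("fingerprint family mismatch: model uses %s, data is %s",
           object$fingerprint$family, fam_new)
  }
  if (nrow(newdata) > 0 && ncol(newdata) != object$n_bits) {
    .stopf("fingerprint length mismatch: model expects %d bits, data has %d",
           object$n_bits, ncol(newdata))
  }
  ps <- if (nrow(newdata) == 0) {
    numeric(0)
  } else {
    switch(object$family,
      rf = unname(stats::predict(object$fit, newdata, type = "prob")[, "ACTIVE"]),
      svm = {
        kern <- object$hyperparams$kernel
        Kt <- .svm_kernel_matrix(kern, newdata, object$X_train)
        sv <- kernlab::SVindex(object$fit)
        p <- kernlab::predict(object$fit,
                              kernlab::as.kernelMatrix(Kt[, sv, drop = FALSE]),
                              type = "probabilities")
        unname(p[, "ACTIVE"])
      },
      knn = {
        D <- 1 - tanimoto_kernel_matrix(newdata, object$X_train)
        .knn_ps(D, object$y01, object$hyperparams$n_neighbors,
                object$hyperparams$weights)
      },
      mlp = .mlp_ps(object$fit, newdata)
    )
  }
  ps <- pmin(pmax(ps, 0), 1)
  if (type == "ps") return(ps)
  label <- ifelse(ps >= threshold, "ACTIVE", "INACTIVE")
  if (type == "label") return(label)
  data.frame(ps = ps, label = label, stringsAsFactors = FALSE)
}

#' @export
print.vs_model <- function(x, ...) {
  hp <- vapply(x$hyperparams, function(v) paste(format(v), collapse = ","), "")
  cat(sprintf("Fingerprint classifier: %s\n", toupper(x$family)))
  cat(sprintf("  hyperparameters: %s\n",
              paste(names(hp), hp, sep = "=", collapse = ", ")))
  if (!is.null(x$fingerprint$family)) {
    cat(sprintf("  fingerprint:     %s (%d bits)\n", x$fingerprint$family,
                x$fingerprint$params$n_bits))
  }
  cat(sprintf("  training set:    %d compounds (%d active), seed %d\n",
              x$n_train, x$n_active, x$seed))
  invisible(x)
}

#' @export
summary.vs_model <- function(object, X = NULL, y = NULL, threshold = 0.5, ...) {
  print(object)
  if (!is.null(X) && !is.null(y)) {
    rep <- .metrics_at(predict(object, X), as.character(.as_labels(y)), threshold)
    cat("Evaluation on supplied data:\n")
    print(rep)
    return(invisible(rep))
  }
  invisible(object)
}

# Stratified fold ids (1..n_folds) preserving the class ratio.
.stratified_folds <- function(yf, n_folds, seed) {
  fold <- integer(length(yf))
  .with_seed(seed, {
    for (cl in levels(yf)) {
      idx <- sample(which(yf == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Fit one grid point on X[tr,] and return predicted labels for X[va,].
# `cache` is an environment holding Gram/distance matrices shared across the
# whole grid.
.fit_predict_labels <- function(family, hp, X, yf, tr, va, seed, cache) {
  y01 <- as.integer(yf == "ACTIVE")
  if (family == "knn") {
    if (is.null(cache$D)) cache$D <- 1 - tanimoto_kernel_matrix(X)
    ps <- .knn_ps(cache$D[va, tr, drop = FALSE], y01[tr],
                  hp$n_neighbors, hp$weights)
    return(ifelse(ps >= 0.5, "ACTIVE", "INACTIVE"))
  }
  if (family == "svm") {
    key <- paste0("K_", hp$kernel)
    if (is.null(cache[[key]])) cache[[key]] <- .svm_kernel_matrix(hp$kernel, X)
    K <- cache[[key]]
    m <- .with_seed(seed,
      kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE]),
                    yf[tr], type = "C-svc", C = hp$C, prob.model = FALSE))
    sv <- kernlab::SVindex(m)
    pred <- kernlab::predict(
      m, kernlab::as.kernelMatrix(K[va, tr, drop = FALSE][, sv, drop = FALSE]))
    return(as.character(pred))
  }
  model <- vs_train(X[tr, , drop = FALSE], yf[tr], family, hp, seed = seed)
  predict(model, X[va, , drop = FALSE], type = "label")
}

#' Exhaustive MCC-scored grid search
#'
#' Evaluates every hyperparameter combination of a family's grid by
#' stratified k-fold cross-validation (default 5 folds) on the training set,
#' scoring each combination by the mean MCC of its fold predictions at the
#' default 0.5 threshold. Ties are broken in favour of the first grid point
#' in the declared enumeration order.
#'
#' @inheritParams vs_train
#' @param grid list of hyperparameter lists; defaults to the family's full
#'   declared grid ([default_grid()]).
#' @param n_folds number of stratified folds.
#' @return object of class `vs_grid_search` with the winning `best`
#'   hyperparameters, the per-point mean MCCs (`scores`) and bookkeeping.
#' @export
grid_search <- function(X, y, family = "rf", grid = NULL, n_folds = 5L,
                        seed = 1L) {
  family <- match.arg(tolower(family), .MODEL_FAMILIES)
  X <- as.matrix(X)
  yf <- .as_labels(y)
  if (length(unique(yf)) < 2) .stopf("grid search needs both classes")
  if (min(table(yf)) < n_folds) {
    .stopf("each class needs at least %d members for %d-fold CV",
           n_folds, n_folds)
  }
  if (is.null(grid)) grid <- default_grid(family)
  if (length(grid) == 0) .stopf("empty grid")

  fold <- .stratified_folds(yf, n_folds, seed)
  cache <- new.env(parent = emptyenv())
  scores <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    hp <- .check_hyperparams(family, grid[[gi]])
    fold_mcc <- vapply(seq_len(n_folds), function(f) {
      tr <- which(fold != f); va <- which(fold == f)
      pred <- .fit_predict_labels(family, hp, X, yf, tr, va,
                                  seed = .child_seed(seed, gi * 100L + f),
                                  cache = cache)
      cm <- confusion_matrix(as.character(yf[va]), pred)
      as.numeric(.mcc(cm$tp, cm$tn, cm$fp, cm$fn))
    }, 0)
    scores[gi] <- mean(fold_mcc)
  }
  best_index <- which.max(scores)
  structure(list(
    family = family,
    best = .check_hyperparams(family, grid[[best_index]]),
    best_index = best_index,
    best_score = scores[best_index],
    scores = scores,
    grid = grid,
    n_folds = as.integer(n_folds),
    seed = as.integer(seed)
  ), class = "vs_grid_search")
}

#' @export
print.vs_grid_search <- function(x, ...) {
  hp <- vapply(x$best, function(v) paste(format(v), collapse = ","), "")
  cat(sprintf("Grid search (%s, %d-fold stratified CV, MCC-scored)\n",
              toupper(x$family), x$n_folds))
  cat(sprintf("  evaluated %d grid points; best mean MCC %.3f\n",
              length(x$scores), x$best_score))
  cat(sprintf("  best: %s\n", paste(names(hp), hp, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Repeated random-split cross-validation
#'
#' Estimates generalization performance of one hyperparameter configuration
#' by `n_repeats` independent stratified random splits, each holding out
#' `test_frac` of the data (default 10 repeats of a 70/30 split). Each
#' repeat fits on the retained fraction and scores MCC on the held-out
#' fraction at the 0.5 threshold.
#'
#' @inheritParams vs_train
#' @param n_repeats number of random splits.
#' @param test_frac held-out fraction per split.
#' @return object of class `vs_cv` with per-repeat `scores` and their mean.
#' @export
cross_validate <- function(X, y, family = "rf", hyperparams = list(),
                           n_repeats = 10L, test_frac = 0.30, seed = 1L) {
  family <- match.arg(tolower(family), .MODEL_FAMILIES)
  X <- as.matrix(X)
  yf <- .as_labels(y)
  if (length(unique(yf)) < 2) .stopf("cross-validation needs both classes")
  hp <- .check_hyperparams(family, hyperparams)

  scores <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      split_seed <- .child_seed(seed, r * 1000L + attempt)
      test_idx <- .with_seed(split_seed, {
        unlist(lapply(levels(yf), function(cl) {
          idx <- which(yf == cl)
          k <- min(max(round(test_frac * length(idx)), 1L), length(idx) - 1L)
          sample(idx, k)
        }))
      })
      tr <- setdiff(seq_along(yf), test_idx)
      if (length(unique(yf[test_idx])) == 2 && length(unique(yf[tr])) == 2) break
      if (attempt >= 10L) .stopf("could not draw a two-class split")
      .warnf("degenerate split resampled (repeat %d, attempt %d)", r, attempt)
    }
    model <- vs_train(X[tr, , drop = FALSE], yf[tr], family, hp,
                      seed = .child_seed(seed, r))
    pred <- predict(model, X[test_idx, , drop = FALSE], type = "label")
    cm <- confusion_matrix(as.character(yf[test_idx]), pred)
    scores[r] <- as.numeric(.mcc(cm$tp, cm$tn, cm$fp, cm$fn))
  }
  structure(list(
    family = family, hyperparams = hp,
    scores = scores, mean_mcc = mean(scores),
    n_repeats = as.integer(n_repeats), test_frac = test_frac,
    seed = as.integer(seed)
  ), class = "vs_cv")
}

#' @export
print.vs_cv <- function(x, ...) {
  cat(sprintf("Repeated random-split CV (%s): %d repeats, %.0f%% held out\n",
              toupper(x$family), x$n_repeats, 100 * x$test_frac))
  cat(sprintf("  MCC mean %.3f (sd %.3f; range %.3f..%.3f)\n",
              x$mean_mcc, stats::sd(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Combine fitted models into a consensus classifier
#'
#' @param ... fitted `vs_model` objects (or one list of them), typically the
#'   best model of each family.
#' @return object of class `vs_consensus`.
#' @export
vs_consensus <- function(...) {
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !inherits(models[[1]], "vs_model")) {
    models <- models[[1]]
  }
  if (length(models) == 0 || !all(vapply(models, inherits, FALSE, "vs_model"))) {
    .stopf("vs_consensus() expects one or more vs_model objects")
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, "", "family")
  }
  structure(list(models = models), class = "vs_consensus")
}

#' Consensus probability scores and labels
#'
#' Collects each member model's PS and combines them: `"mean"` mode
#' classifies a compound active when the average PS is at least the
#' threshold, `"unanimity"` mode when every member's PS is.
#'
#' @param object a `vs_consensus`.
#' @param newdata fingerprint matrix shared by all members, or a list of
#'   matrices (one per member, in member order).
#' @param mode `"mean"` or `"unanimity"`.
#' @param threshold activity threshold on the combined score.
#' @param ... unused.
#' @return data.frame with the combined `ps` (mean PS across members), the
#'   consensus `label`, and the per-member PS matrix as attribute
#'   `"ps_matrix"`.
#' @export
predict.vs_consensus <- function(object, newdata, mode = c("mean", "unanimity"),
                                 threshold = 0.5, ...) {
  mode <- match.arg(mode)
  k <- length(object$models)
  data_list <- if (is.list(newdata) && !is.matrix(newdata) &&
                   !is.data.frame(newdata)) {
    if (length(newdata) != k) {
      .stopf("newdata list length (%d) must match the number of member models (%d)",
             length(newdata), k)
    }
    newdata
  } else {
    rep(list(newdata), k)
  }
  ps <- vapply(seq_len(k),
               function(i) predict(object$models[[i]], data_list[[i]]),
               numeric(nrow(as.matrix(data_list[[1]]))))
  if (!is.matrix(ps)) ps <- matrix(ps, nrow = 1)
  colnames(ps) <- names(object$models)
  label <- consensus_classify(ps, mode = mode, threshold = threshold)
  out <- data.frame(ps = rowMeans(ps), label = label, stringsAsFactors = FALSE)
  attr(out, "ps_matrix") <- ps
  out
}

#' @export
print.vs_consensus <- function(x, ...) {
  cat(sprintf("Consensus classifier over %d models: %s\n",
              length(x$models),
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}
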