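# Model families, Tanimoto kernel, grid search and cross-validation.

test_that("tanimoto kernel matrix equals the pairwise brute-force oracle", {
  withr::with_seed(3, {
    X <- matrix(rbinom(20 * 64, 1, 0.2), 20)
    K <- tanimoto_kernel_matrix(X)
    K_brute <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) K_brute[i, j] <- brute_tanimoto(X[i, ], X[j, ])
    expect_equal(K, K_brute)
    expect_equal(K, t(K))
    expect_equal(diag(K), rep(1, 20))
    # positive semidefinite within tolerance
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  })
})

test_that("kernel of disjoint-support rows is the identity matrix", {
  X <- diag(1, 6, 10)
  expect_equal(tanimoto_kernel_matrix(X), diag(1, 6))
  expect_equal(tanimoto_kernel_matrix(matrix(c(1, 1, 0), 1),
                                      matrix(c(1, 0, 1), 1)),
               matrix(1 / 3, 1, 1))
  expect_error(tanimoto_kernel_matrix(matrix(0, 2, 4), matrix(0, 2, 5)),
               "lengths differ")
})

test_that("declared grids have the documented cardinality and content", {
  expect_length(default_grid("rf"), 2 * 3)
  expect_length(default_grid("svm"), 5 * 2)
  expect_length(default_grid("knn"), 30 * 2)
  expect_length(default_grid("mlp"), 3 * 3 * 4 * 4)
  expect_setequal(unique(vapply(default_grid("knn"), `[[`, 0L, "n_neighbors")),
                  1:30)
  expect_setequal(unique(vapply(default_grid("svm"), `[[`, 0, "C")),
                  c(0.01, 0.1, 1, 10, 100))
})

test_that("grid search returns a grid member and honours degenerate grids", {
  toy <- make_separable_toy()
  gs <- grid_search(toy$X, toy$y, "rf", seed = 3)
  expect_true(any(vapply(default_grid("rf"), function(g) {
    identical(g$n_estimators, gs$best$n_estimators) &&
      identical(g$max_features, gs$best$max_features)
  }, FALSE)))
  expect_length(gs$scores, 6)
  one <- grid_search(toy$X, toy$y, "knn",
                     grid = list(list(n_neighbors = 3L, weights = "uniform")),
                     seed = 3)
  expect_equal(one$best$n_neighbors, 3L)
  expect_equal(one$best_index, 1L)
})

test_that("grid search achieves fold-mean MCC 1 on a separable toy set", {
  toy <- make_separable_toy()
  gs <- grid_search(toy$X, toy$y, "rf", seed = 3)
  expect_equal(gs$best_score, 1.0)
  gs_svm <- grid_search(toy$X, toy$y, "svm", seed = 3)
  expect_equal(gs_svm$best_score, 1.0)
})

test_that("grid search refuses single-class or undersized input", {
  toy <- make_separable_toy()
  expect_error(grid_search(toy$X, rep("ACTIVE", nrow(toy$X)), "rf"),
               "both classes")
  expect_error(grid_search(toy$X[1:8, ], toy$y[c(1:4, 31:34)], "rf",
                           n_folds = 5), "at least")
})

test_that("training rejects single-class data and unknown hyperparameters", {
  toy <- make_separable_toy()
  expect_error(vs_train(toy$X, rep("ACTIVE", nrow(toy$X)), "rf"),
               "both classes")
  expect_error(vs_train(toy$X, toy$y, "rf", list(ntree = 10)), "unknown")
})

test_that("SVM with tanimoto kernel separates the toy set perfectly", {
  toy <- make_separable_toy()
  m <- vs_train(toy$X, toy$y, "svm", list(C = 10, kernel = "tanimoto"), seed = 3)
  pred <- predict(m, toy$X, type = "label")
  expect_identical(pred, toy$y)
  ps <- predict(m, toy$X)
  expect_true(all(ps[toy$y == "ACTIVE"] >= 0.5))
})

test_that("1-NN reproduces training labels and predictions are stable", {
  toy <- make_separable_toy()
  m <- vs_train(toy$X, toy$y, "knn",
                list(n_neighbors = 1L, weights = "distance"))
  expect_identical(predict(m, toy$X, type = "label"), toy$y)
  for (fam in c("rf", "svm", "knn", "mlp")) {
    m <- vs_train(toy$X, toy$y, fam, seed = 5)
    p1 <- predict(m, toy$X)
    p2 <- predict(m, toy$X)
    expect_identical(p1, p2, info = fam)
    expect_true(all(p1 >= 0 & p1 <= 1), info = fam)
    expect_length(predict(m, toy$X[0, , drop = FALSE]), 0)
  }
})

test_that("all MLP solvers and activations learn the separable toy set", {
  toy <- make_separable_toy(n_per_class = 20, n_bits = 32)
  for (solver in c("adam", "sgd", "lbfgs")) {
    m <- vs_train(toy$X, toy$y, "mlp",
                  list(hidden_layer_sizes = c(16L, 8L), solver = solver,
                       activation = "relu", learning_rate_init = 0.01,
                       max_iter = 150L),
                  seed = 3)
    acc <- mean(predict(m, toy$X, type = "label") == toy$y)
    expect_gte(acc, 0.95)
  }
  m <- vs_train(toy$X, toy$y, "mlp",
                list(hidden_layer_sizes = 8L, solver = "adam",
                     activation = "tanh", learning_rate_init = 0.01),
                seed = 3)
  expect_true(all(predict(m, toy$X) >= 0 & predict(m, toy$X) <= 1))
})

test_that("MLP backpropagation gradients match numeric differentiation", {
  withr::with_seed(8, {
    X <- matrix(rbinom(10 * 6, 1, 0.5), 10)
    y <- rbinom(10, 1, 0.5)
    act <- fpscreen:::.mlp_act("tanh")
    sizes <- c(6L, 4L, 3L, 1L)
    par <- fpscreen:::.mlp_init(sizes, seed = 1)
    theta <- fpscreen:::.mlp_flatten(par$W, par$b)
    loss_at <- function(th) {
      p <- fpscreen:::.mlp_unflatten(th, sizes)
      fpscreen:::.mlp_grad(p$W, p$b, act, X, y, l2 = 1e-3)$loss
    }
    g <- fpscreen:::.mlp_grad(par$W, par$b, act, X, y, l2 = 1e-3)
    analytic <- fpscreen:::.mlp_flatten(g$gW, g$gb)
    idx <- sample(length(theta), 12)
    for (i in idx) {
      e <- numeric(length(theta)); e[i] <- 1e-5
      numeric_grad <- (loss_at(theta + e) - loss_at(theta - e)) / 2e-5
      expect_equal(analytic[i], numeric_grad, tolerance = 1e-4)
    }
  })
})

test_that("cross-validation is reproducible and scores a null signal near 0", {
  toy <- make_separable_toy()
  cv1 <- cross_validate(toy$X, toy$y, "knn",
                        list(n_neighbors = 3L, weights = "distance"), seed = 9)
  cv2 <- cross_validate(toy$X, toy$y, "knn",
                        list(n_neighbors = 3L, weights = "distance"), seed = 9)
  expect_identical(cv1$scores, cv2$scores)
  expect_length(cv1$scores, 10)
  expect_equal(cv1$mean_mcc, 1.0)

  withr::with_seed(17, {
    X <- matrix(rbinom(400 * 64, 1, 0.3), 400)
    y <- sample(rep(c("ACTIVE", "INACTIVE"), each = 200))
  })
  cv_null <- cross_validate(X, y, "knn",
                            list(n_neighbors = 5L, weights = "uniform"),
                            seed = 9)
  expect_lt(abs(cv_null$mean_mcc), 0.15)
})

test_that("fingerprint-family and width mismatches are caught at predict time", {
  toy <- make_separable_toy()
  Xtagged <- toy$X
  attr(Xtagged, "family") <- "morgan"
  m <- vs_train(Xtagged, toy$y, "rf", seed = 1)
  bad <- toy$X
  attr(bad, "family") <- "maccs"
  expect_error(predict(m, bad), "family mismatch")
  expect_error(predict(m, toy$X[, 1:10]), "length mismatch")
})

test_that("consensus members agree with their individual predictions", {
  toy <- make_separable_toy()
  m1 <- vs_train(toy$X, toy$y, "rf", seed = 1)
  m2 <- vs_train(toy$X, toy$y, "knn", seed = 1)
  cons <- vs_consensus(m1, m2)
  out <- predict(cons, toy$X)
  psm <- attr(out, "ps_matrix")
  expect_equal(psm[, 1], predict(m1, toy$X))
  expect_equal(psm[, 2], predict(m2, toy$X))
  expect_equal(out$ps, rowMeans(psm))
  # unanimity is never more permissive than the mean rule
  una <- predict(cons, toy$X, mode = "unanimity")
  expect_true(all(!(una$label == "ACTIVE" & out$label == "INACTIVE")))
})
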