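test_that("rbf_kernel evaluates the Gaussian radial basis formula", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), gamma = 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), gamma = 0.5), exp(-1))
  expect_equal(rbf_kernel(c(0, 3), c(4, 0), gamma = 1e-12), 1, tolerance = 1e-9)
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), gamma = 1), "equal length")
})

test_that("a separable toy problem is fit perfectly and respects the box constraint", {
  toy <- separable_toy()
  model <- train_svm(toy$x, toy$y, svm_params(C = 10, gamma = 0.5))
  expect_s3_class(model, "svm_model")
  expect_true(all(abs(model$dual_coefs) <= 10 + 1e-8))
  pred <- predict_labels(model, toy$x)
  expect_identical(unname(pred), unname(toy$y))
  expect_equal(accuracy_score(pred, toy$y), 1.0)
  # KKT: unbounded support vectors sit on the margin, |f| = 1 up to the
  # solver's convergence tolerance (libsvm default 1e-3)
  f <- decision_values(model, toy$x)
  sv_ids <- rownames(model$support_vectors)
  unbounded <- sv_ids[abs(model$dual_coefs) < 10 - 1e-6]
  expect_gt(length(unbounded), 0)
  expect_true(all(abs(abs(f[unbounded]) - 1) < 2e-3))
})

test_that("the decision function reproduces the backing solver's predictions", {
  ds <- generate_dataset(synthetic_spec(n_probes = 15, n_informative = 5,
                                        shift_delta = 1, noise_sd = 1,
                                        seed = 31))
  params <- svm_params(C = 2, gamma = 0.05)
  model <- train_svm(ds$x, ds$y, params)
  ref <- e1071::svm(t(ds$x), factor(ds$y, levels = c(-1L, 1L)),
                    type = "C-classification", kernel = "radial",
                    cost = 2, gamma = 0.05, scale = FALSE)
  expect_identical(unname(predict_labels(model, ds$x)),
                   as.integer(as.character(predict(ref, t(ds$x)))))
})

test_that("duplicating every training sample leaves predictions unchanged", {
  toy <- separable_toy()
  x2 <- cbind(toy$x, toy$x)
  colnames(x2) <- c(colnames(toy$x), paste0(colnames(toy$x), "_dup"))
  y2 <- setNames(c(toy$y, toy$y), colnames(x2))
  params <- svm_params(C = 10, gamma = 0.5)
  m1 <- train_svm(toy$x, toy$y, params)
  m2 <- train_svm(x2, y2, params)
  set.seed(44)
  grid <- toy$x + matrix(runif(length(toy$x), -0.2, 0.2), nrow = 2)
  expect_identical(predict_labels(m1, grid), predict_labels(m2, grid))
})

test_that("decision values are permutation-equivariant and empty-safe", {
  toy <- separable_toy()
  model <- train_svm(toy$x, toy$y, svm_params(C = 1, gamma = 0.3))
  f <- decision_values(model, toy$x)
  set.seed(3)
  perm <- sample(ncol(toy$x))
  expect_equal(decision_values(model, toy$x[, perm]), f[perm])
  empty <- toy$x[, integer(0), drop = FALSE]
  expect_length(decision_values(model, empty), 0)
  bad <- toy$x
  rownames(bad) <- c("probe_a", "probe_zzz")
  expect_error(decision_values(model, bad), "probe_b")
})

test_that("prediction uses the sign rule with zero mapping to the case class", {
  model <- structure(list(
    support_vectors = matrix(1, 1, 1, dimnames = list("sv1", "g1")),
    dual_coefs = 1, bias = -1, params = svm_params(1, 1),
    feature_ids = "g1", center = NULL, scale = NULL
  ), class = "svm_model")
  x <- matrix(c(1, 5), 1, dimnames = list("g1", c("at_sv", "far")))
  f <- decision_values(model, x)
  expect_equal(unname(f), c(0, exp(-16) - 1))
  expect_identical(unname(predict_labels(model, x)), c(-1L, -1L))
})

test_that("accuracy and confusion counts follow the case-positive convention", {
  truth <- rep(c(-1L, 1L), c(12, 8))
  expect_equal(accuracy_score(truth, truth), 1)
  expect_equal(accuracy_score(-truth, truth), 0)
  # tp 10, fn 2 among cases; tn 5, fp 3 among controls -> 15/20
  pred <- c(rep(-1L, 10), rep(1L, 2), rep(-1L, 3), rep(1L, 5))
  expect_equal(unname(confusion_counts(pred, truth)), c(10, 5, 3, 2))
  expect_equal(accuracy_score(pred, truth), 0.75)
  expect_error(accuracy_score(integer(0), integer(0)), "nonempty")
  # accuracy + misclassification rate == 1
  set.seed(5)
  for (i in 1:10) {
    t <- sample(c(-1L, 1L), 15, replace = TRUE)
    p <- sample(c(-1L, 1L), 15, replace = TRUE)
    expect_equal(accuracy_score(p, t) + mean(p != t), 1)
  }
})

test_that("roc_auc matches exhaustive pair counting, including ties", {
  truth <- rep(c(-1L, 1L), each = 3)
  # cases score low (case-oriented high); one discordant pair, no ties
  scores <- c(-3, -2, 0.5, -1, 2, 3)
  expect_equal(roc_auc(scores, truth)$auc, 8 / 9)
  expect_equal(auc_bruteforce(scores, truth), 8 / 9)
  # a half-tie instead of the discordance
  scores_tie <- c(-3, -2, -1, -1, 2, 3)
  expect_equal(roc_auc(scores_tie, truth)$auc, 8.5 / 9)
  expect_equal(auc_bruteforce(scores_tie, truth), 8.5 / 9)

  expect_equal(roc_auc(c(-5, -4, 1, 2), rep(c(-1L, 1L), each = 2))$auc, 1)
  expect_equal(roc_auc(rep(0, 6), truth)$auc, 0.5)
  expect_error(roc_auc(1:3, rep(-1L, 3)), "both classes")
})

test_that("ROC curves run from (0,0) to (1,1) with monotone coordinates", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    truth <- c(-1L, 1L, sample(c(-1L, 1L), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # induce ties
    roc <- roc_auc(scores, truth)$roc
    expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  }
})

test_that("cross-validation folds partition the samples and stratify classes", {
  y <- rep(c(-1L, 1L), c(30, 20))
  folds <- gasvm:::make_folds(y, k = 10, seed = 3)
  expect_length(folds, 50)
  expect_true(all(tabulate(folds, 10) == 5))
  for (f in 1:10) expect_setequal(unique(y[folds == f]), c(-1L, 1L))
  expect_identical(folds, gasvm:::make_folds(y, 10, seed = 3))
  expect_error(gasvm:::make_folds(rep(c(-1L, 1L), c(5, 45)), 10, seed = 1),
               "smaller k")
})

test_that("cross-validated accuracy is 1 on strongly separated data and deterministic", {
  ds <- generate_dataset(synthetic_spec(n_probes = 10, n_informative = 5,
                                        shift_delta = 5, noise_sd = 0.5,
                                        seed = 8))
  params <- svm_params(C = 10, gamma = 0.1)
  acc <- cross_val_accuracy(ds$x, ds$y, params, k = 10, seed = 2)
  expect_equal(acc, 1.0)
  expect_identical(acc, cross_val_accuracy(ds$x, ds$y, params, k = 10, seed = 2))
})

test_that("cross-validation on label-permuted data hovers at the majority rate", {
  ds <- generate_dataset(synthetic_spec(n_probes = 20, n_informative = 10,
                                        shift_delta = 2, noise_sd = 0.7,
                                        seed = 12))
  params <- svm_params(C = 1, gamma = 0.05)
  accs <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    y_perm <- ds$y
    y_perm[] <- sample(ds$y)
    cross_val_accuracy(ds$x, y_perm, params, k = 5, seed = s)
  }, numeric(1))
  majority <- max(table(ds$y)) / length(ds$y)
  expect_lt(abs(mean(accs) - majority), 0.15)
})

test_that("seeded sub-operations leave the ambient RNG stream untouched", {
  ds <- generate_dataset(synthetic_spec(n_probes = 5, n_informative = 2,
                                        seed = 1))
  set.seed(99)
  before <- .Random.seed
  invisible(cross_val_accuracy(ds$x, ds$y, svm_params(1, 0.1), k = 3, seed = 4))
  invisible(split_train_test(ds$x, ds$y, 50, seed = 2))
  expect_identical(.Random.seed, before)
})
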