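# RBF-kernel soft-margin SVM contract and the evaluation statistics
# (accuracy, ROC/AUC, k-fold cross-validation) used both as GA fitness and
# for the final held-out assessment.
#
# Training is backed by the libsvm SMO solver via e1071::svm; the exposed
# contract is the decision function f(x) = sum_j dual_coefs_j K(sv_j, x) + b
# with |dual_coefs_j| <= C, oriented so that f(x) > 0 predicts the control
# class (+1) and f(x) <= 0 the case class (-1).

#' SVM hyperparameters
#'
#' @param C Soft-margin tradeoff, > 0.
#' @param gamma RBF kernel width, > 0 (units 1 / (log2 intensity)^2).
#' @param epsilon Nonnegative tolerance carried through the chromosome
#'   encoding for fidelity; the C-classifier itself does not use it.
#' @return A validated `svm_params` list (kernel is always `"rbf"`).
#' @export
svm_params <- function(C, gamma, epsilon = 0) {
  assert_scalar_number(C, "C")
  assert_scalar_number(gamma, "gamma")
  assert_scalar_number(epsilon, "epsilon")
  if (C <= 0) stop("'C' must be > 0", call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  structure(list(C = C, gamma = gamma, epsilon = epsilon, kernel = "rbf"),
            class = "svm_params")
}

#' Gaussian radial basis kernel
#'
#' `K(x, x') = exp(-gamma * ||x - x'||^2)` with the squared Euclidean
#' distance; the value lies in (0, 1].
#'
#' @param x,x2 Numeric vectors of equal length.
#' @param gamma Positive kernel width.
#' @return A single numeric kernel value.
#' @export
rbf_kernel <- function(x, x2, gamma) {
  if (length(x) != length(x2)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  assert_scalar_number(gamma, "gamma")
  exp(-gamma * sum((x - x2)^2))
}

# kernel matrix between the rows of two samples-as-rows matrices
kernel_matrix <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a soft-margin RBF SVM
#'
#' @param x Expression matrix restricted to the selected features (probes as
#'   rows, samples as columns).
#' @param y Named `-1`/`+1` labels covering the samples of `x`.
#' @param params An [svm_params()] object.
#' @param standardize Center/scale features before fitting (default
#'   `FALSE`; the decision function undoes the scaling transparently).
#' @return An `svm_model` list: `support_vectors` (samples-as-rows matrix),
#'   `dual_coefs` (alpha_j * y_j, oriented so positive scores predict +1),
#'   `bias`, `params`, `feature_ids`, and optional `center`/`scale`.
#' @export
train_svm <- function(x, y, params, standardize = FALSE) {
  stopifnot(inherits(params, "svm_params"))
  if (nrow(x) < 1L) stop("at least one feature is required", call. = FALSE)
  y <- check_labels(x, y)
  tx <- t(x)
  fit <- e1071::svm(tx, factor(y, levels = c(-1L, 1L)),
                    type = "C-classification", kernel = "radial",
                    cost = params$C, gamma = params$gamma,
                    scale = standardize)
  # libsvm orients its decision value toward the first encountered class;
  # re-orient the stored coefficients so that f(x) > 0 always means +1
  level1 <- fit$levels[fit$labels[1L]]
  sgn <- if (level1 == "1") 1 else -1
  sv <- tx[fit$index, , drop = FALSE]
  model <- list(
    support_vectors = sv,
    dual_coefs = sgn * as.numeric(fit$coefs),
    bias = -sgn * fit$rho,
    params = params,
    feature_ids = rownames(x),
    center = if (standardize) attr(fit$SV, "scaled:center") else NULL,
    scale = if (standardize) attr(fit$SV, "scaled:scale") else NULL
  )
  class(model) <- "svm_model"
  stopifnot(all(abs(model$dual_coefs) <= params$C + 1e-8))
  model
}

#' Decision values of a fitted SVM
#'
#' `f(x) = sum_j dual_coefs_j K(sv_j, x) + bias`, computed from the stored
#' model fields alone.  Positive scores predict the control class (+1).
#'
#' @param model An `svm_model`.
#' @param x Expression matrix (probes as rows) whose rows cover the model's
#'   `feature_ids`; extra probes are ignored, order is reconciled by ID.
#' @return Named numeric vector of one score per sample (empty for zero
#'   samples).
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  missing <- setdiff(model$feature_ids, rownames(x))
  if (length(missing)) {
    stop("feature(s) missing from input: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  tx <- t(x[model$feature_ids, , drop = FALSE])
  if (!is.null(model$center)) {
    tx <- sweep(tx, 2L, model$center, "-")
    sc <- model$scale
    sc[sc == 0] <- 1
    tx <- sweep(tx, 2L, sc, "/")
  }
  k <- kernel_matrix(model$support_vectors, tx, model$params$gamma)
  stats::setNames(drop(crossprod(k, model$dual_coefs)) + model$bias,
                  colnames(x))
}

#' Predict class labels
#'
#' The sign of the decision value: positive predicts `+1` (control);
#' zero or negative predicts `-1` (case), a fixed documented tie rule.
#'
#' @inheritParams decision_values
#' @return Named integer vector of `-1`/`+1` predictions.
#' @export
predict_labels <- function(model, x) {
  f <- decision_values(model, x)
  stats::setNames(ifelse(f > 0, 1L, -1L), names(f))
}

#' Confusion counts with the case class (-1) as positive
#'
#' @param pred,truth Equal-length `-1`/`+1` vectors.
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    stop("'pred' and 'truth' must be nonempty and of equal length",
         call. = FALSE)
  }
  case <- CLASS_CODES[["case"]]
  c(tp = sum(pred == case & truth == case),
    tn = sum(pred != case & truth != case),
    fp = sum(pred == case & truth != case),
    fn = sum(pred != case & truth == case))
}

#' Classification accuracy
#'
#' `(tp + tn) / total`: the proportion of correct predictions among all
#' samples examined.
#'
#' @inheritParams confusion_counts
#' @return A number in `[0, 1]`.
#' @export
accuracy_score <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  (cc[["tp"]] + cc[["tn"]]) / length(pred)
}

#' ROC curve and area under it
#'
#' Scores are oriented so that the case class (-1) is the positive class
#' scored high (i.e. the negated decision value); the AUC then equals the
#' Mann-Whitney probability that a random case outranks a random control,
#' with ties credited 0.5.  ROC points are produced by thresholding at every
#' distinct score.
#'
#' @param scores Decision values (higher = more control-like), one per
#'   sample.
#' @param truth `-1`/`+1` labels, both classes present.
#' @return A list with `auc` and `roc` (data.frame of `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1), both coordinates
#'   non-decreasing).
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    stop("'scores' and 'truth' must have equal length", call. = FALSE)
  }
  pos <- truth == CLASS_CODES[["case"]]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  oriented <- -scores
  r <- rank(oriented, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(oriented, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last <- !duplicated(oriented[ord], fromLast = TRUE)  # end of each tie block
  roc <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(auc = auc, roc = roc)
}

# deterministic stratified fold assignment; returns an integer fold id per
# sample (in the order of y)
make_folds <- function(y, k, seed) {
  k <- assert_count(k, "k", min = 2L)
  counts <- table(y)
  if (min(counts) < k) {
    stop(sprintf(paste0("smallest class has %d members but k = %d; choose a ",
                        "smaller k so every fold keeps both classes"),
                 min(counts), k), call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Stratified k-fold cross-validated accuracy
#'
#' The fitness statistic of the GA: the mean held-out accuracy over k
#' stratified folds of an RBF SVM refit on each training complement.  Fold
#' assignment is deterministic for a fixed seed, and the caller's RNG state
#' is left untouched.
#'
#' @param x Expression matrix (probes x samples).
#' @param y Named `-1`/`+1` labels.
#' @param params [svm_params()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param standardize Passed to [train_svm()].
#' @return Mean fold accuracy in `[0, 1]`.
#' @export
cross_val_accuracy <- function(x, y, params, k = 10, seed, standardize = FALSE) {
  x <- validate_expression_matrix(x)
  y <- check_labels(x, y)
  folds <- make_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    hold <- folds == f
    model <- train_svm(x[, !hold, drop = FALSE], y[!hold], params,
                       standardize = standardize)
    pred <- predict_labels(model, x[, hold, drop = FALSE])
    accuracy_score(pred, y[hold])
  }, numeric(1L))
  mean(acc)
}

#' Evaluate a fitted model on held-out samples
#'
#' @param model An `svm_model`.
#' @param x Test expression matrix.
#' @param y Test labels.
#' @return An `evaluation_report` list: confusion counts, `accuracy`,
#'   `auc`, `roc` points, and the model's `selected_feature_ids`.
#' @export
evaluate_model <- function(model, x, y) {
  y <- check_labels(x, y)
  scores <- decision_values(model, x)
  pred <- stats::setNames(ifelse(scores > 0, 1L, -1L), names(scores))
  cc <- confusion_counts(pred, y)
  ra <- roc_auc(scores, y)
  structure(list(
    tp = cc[["tp"]], tn = cc[["tn"]], fp = cc[["fp"]], fn = cc[["fn"]],
    accuracy = (cc[["tp"]] + cc[["tn"]]) / length(y),
    auc = ra$auc,
    roc = ra$roc,
    selected_feature_ids = model$feature_ids
  ), class = "evaluation_report")
}
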