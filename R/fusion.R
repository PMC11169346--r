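#' Weighted average of CNN and SVM probabilities
#'
#' `p = w * p_cnn + (1 - w) * p_svm` on the severe-class probability; the
#' label is severe iff `p >= 0.5`. `w = 1` reproduces the CNN's labels,
#' `w = 0` the SVM's.
#'
#' @param p_cnn,p_svm Severe-class probability vectors aligned by subject
#'   (names, when present, must agree).
#' @param w Weight in \[0, 1\] given to the CNN.
#' @return List with `p` (fused severe probability) and `labels`.
#' @export
weighted_average <- function(p_cnn, p_svm, w) {
  stopifnot(w >= 0, w <= 1, length(p_cnn) == length(p_svm))
  if (!is.null(names(p_cnn)) && !is.null(names(p_svm)) &&
      !identical(names(p_cnn), names(p_svm)))
    stop("weighted_average: misaligned subject ids")
  p <- w * p_cnn + (1 - w) * p_svm
  list(p = p, labels = ifelse(p >= 0.5, "severe", "nonsevere"))
}

#' Regularized linear discriminant analysis (two classes)
#'
#' Gaussian discriminant with pooled covariance shrunk toward its diagonal:
#' `Sigma_gamma = (1 - gamma) * Sigma + gamma * diag(Sigma)`. `gamma = 0` is
#' classical LDA; `gamma = 1` is the diagonal-covariance (naive-Bayes-like)
#' discriminant.
#'
#' @param X n x p feature matrix.
#' @param y Binary labels (`"severe"` positive).
#' @param gamma Shrinkage weight in \[0, 1\].
#' @return A `reg_lda` model.
#' @export
reg_lda_fit <- function(X, y, gamma = 0) {
  stopifnot(gamma >= 0, gamma <= 1)
  cls <- labels_to_y(y)
  if (length(unique(cls)) < 2) stop("reg_lda_fit: two classes required")
  X <- as.matrix(X)
  n <- nrow(X)
  m1 <- colMeans(X[cls == 1, , drop = FALSE])
  m2 <- colMeans(X[cls == 2, , drop = FALSE])
  n1 <- sum(cls == 1); n2 <- sum(cls == 2)
  S1 <- stats::cov(X[cls == 1, , drop = FALSE])
  S2 <- stats::cov(X[cls == 2, , drop = FALSE])
  S <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n - 2)
  Sg <- (1 - gamma) * S + gamma * diag(diag(S), ncol(X))
  Sinv <- solve(Sg + diag(1e-10, ncol(X)))
  structure(list(means = rbind(m1, m2), Sinv = Sinv,
                 log_priors = log(c(n1, n2) / n), gamma = gamma,
                 classes = c("nonsevere", "severe")), class = "reg_lda")
}

#' @rdname reg_lda_fit
#' @param model A `reg_lda`.
#' @return `reg_lda_predict` returns a character vector of labels.
#' @export
reg_lda_predict <- function(model, X) {
  X <- as.matrix(X)
  d <- vapply(1:2, function(c) {
    m <- model$means[c, ]
    as.vector(X %*% (model$Sinv %*% m)) -
      0.5 * sum(m * (model$Sinv %*% m)) + model$log_priors[c]
  }, numeric(nrow(X)))
  model$classes[max.col(matrix(d, nrow(X), 2))]
}

#' LDA stacking of model probabilities on half-split test folds
#'
#' Within each outer test fold, a random stratified half trains a regularized
#' LDA on the two-feature input `(p_cnn, p_svm)`; predictions are returned
#' for the other half. If a half-split leaves a class empty the split is
#' redrawn (bounded retries).
#'
#' @param p_cnn,p_svm Severe-class probabilities for the fold's subjects.
#' @param labels True labels for the fold.
#' @param gamma Covariance shrinkage in \[0, 1\].
#' @param seed Integer seed for the half split.
#' @return List with `eval_ix` (indices predicted), `predicted`, `model`.
#' @export
lda_stack <- function(p_cnn, p_svm, labels, gamma = 0, seed = 1L) {
  n <- length(labels)
  X <- cbind(p_cnn = p_cnn, p_svm = p_svm)
  y <- ifelse(labels_to_y(labels) == 2, "severe", "nonsevere")
  for (try in 1:20) {
    sp <- tryCatch(
      resplit_for_validation(seq_len(n), y, 0.5, seed = seed + try - 1),
      error = function(e) NULL)
    if (is.null(sp)) next
    train_ix <- sp$val_ids     # half used for fitting
    eval_ix <- sp$train_ids    # half reserved for evaluation
    if (length(unique(y[train_ix])) < 2 || length(eval_ix) == 0) next
    model <- reg_lda_fit(X[train_ix, , drop = FALSE], y[train_ix], gamma)
    pred <- reg_lda_predict(model, X[eval_ix, , drop = FALSE])
    return(list(eval_ix = eval_ix, predicted = pred, model = model,
                train_ix = train_ix))
  }
  stop("lda_stack: could not draw a half split with both classes")
}

#' Sweep a fusion hyperparameter and record per-repeat metrics
#'
#' Evaluates the fused model over a grid of weights (weighted averaging) or
#' shrinkage values (LDA stacking), one metric row per repeat and value; the
#' best-case value is the grid maximum of the mean F1 - explicitly an
#' optimistic bound on fused performance.
#'
#' @param method `"weighted_average"` or `"lda_stack"`.
#' @param values Weight grid (default 101 values 0..1) or gamma grid
#'   (default 500 linearly spaced values in \[0, 1\]).
#' @param repeats List with one element per repeat, each containing
#'   `p_cnn`, `p_svm` (severe probabilities) and `labels`.
#' @param seed Seed for stacking half-splits.
#' @return A `fusion_result`: `metrics` (repeat x value F1 matrix),
#'   `best_value`, `best_f1`.
#' @export
fusion_sweep <- function(method = c("weighted_average", "lda_stack"),
                         values = NULL, repeats, seed = 1L) {
  method <- match.arg(method)
  if (is.null(values))
    values <- if (method == "weighted_average") seq(0, 1, by = 0.01)
              else seq(0, 1, length.out = 500)
  stopifnot(length(values) > 0, length(repeats) > 0)
  f1 <- matrix(NA_real_, length(repeats), length(values))
  for (r in seq_along(repeats)) {
    rep_d <- repeats[[r]]
    for (vi in seq_along(values)) {
      if (method == "weighted_average") {
        fused <- weighted_average(rep_d$p_cnn, rep_d$p_svm, values[vi])
        f1[r, vi] <- compute_metrics(rep_d$labels, fused$labels)$f1
      } else {
        st <- lda_stack(rep_d$p_cnn, rep_d$p_svm, rep_d$labels,
                        gamma = values[vi], seed = seed + r)
        f1[r, vi] <- compute_metrics(rep_d$labels[st$eval_ix], st$predicted)$f1
      }
    }
  }
  mean_f1 <- colMeans(f1)
  best <- which.max(mean_f1)
  structure(list(method = method, sweep_values = values, metrics = f1,
                 best_value = values[best], best_f1 = mean_f1[best]),
            class = "fusion_result")
}
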