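#' Flatten scaled volumes into a subject-by-voxel table
#'
#' One row per subject, one column per voxel of the scaled representation,
#' with the voxel ordering recorded so tables can be unflattened and columns
#' traced back to coordinates.
#'
#' @param volumes List of 3D arrays sharing one grid.
#' @return n x p numeric matrix with attributes `grid_dim` and column order
#'   following R's array linearisation (first axis fastest).
#' @export
flatten_volumes <- function(volumes) {
  d <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), d), logical(1))))
    stop("flatten_volumes: inconsistent shapes")
  X <- t(vapply(volumes, as.vector, numeric(prod(d))))
  attr(X, "grid_dim") <- d
  X
}

#' @rdname flatten_volumes
#' @param table Matrix produced by `flatten_volumes`.
#' @param row Row index to reshape.
#' @export
unflatten_volume <- function(table, row = 1) {
  d <- attr(table, "grid_dim")
  if (is.null(d)) stop("unflatten_volume: table lacks grid_dim attribute")
  array(table[row, ], d)
}

#' SVM configuration
#'
#' Hyperparameter space for the class-weighted support vector classifier:
#' cost in \[1e-3, 2e4\] and kernel scale in \[1e-3, 1e3\] are searched over
#' 300 logarithmically spaced bins; optional PCA/ICA reduction retains 1-75
#' components and is always fitted on training rows only. The radial kernel
#' uses `gamma = 1/kernel_scale^2` so `kernel_scale` plays the usual width
#' role.
#'
#' @param kernel `"linear"` or `"rbf"` (kernels are not tuned; separate
#'   models are trained per kernel).
#' @param cost Soft-margin cost.
#' @param kernel_scale RBF kernel width.
#' @param reduction `"none"`, `"pca"` or `"ica"`.
#' @param n_components Components retained when reducing.
#' @param n_search_draws Random-search evaluations (default 300).
#' @param seed Integer seed for the random search.
#' @return An `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"), cost = 1,
                       kernel_scale = 1, reduction = c("none", "pca", "ica"),
                       n_components = 10, n_search_draws = 300, seed = 1L) {
  structure(list(kernel = match.arg(kernel), cost = cost,
                 kernel_scale = kernel_scale,
                 reduction = match.arg(reduction),
                 n_components = as.integer(n_components),
                 n_search_draws = as.integer(n_search_draws),
                 seed = as.integer(seed)), class = "svm_config")
}

#' Fit a PCA or ICA projector on training rows
#'
#' PCA keeps the top-k principal components of the centered training table;
#' ICA applies a FastICA rotation (deflation, tanh contrast) to the whitened
#' top-k components. The projector maps any table into k dimensions using
#' training statistics only, so held-out rows never influence the subspace.
#'
#' @param train_table n x p matrix (training rows only).
#' @param method `"pca"` or `"ica"`.
#' @param k Number of components, `k <= min(n-1, p)`.
#' @param seed Seed for the ICA rotation.
#' @return A `reduction_projector`.
#' @export
fit_reduction <- function(train_table, method = c("pca", "ica"), k,
                          seed = 1L) {
  method <- match.arg(method)
  n <- nrow(train_table); p <- ncol(train_table)
  if (k > min(n - 1, p)) stop("fit_reduction: k too large for training data")
  mu <- colMeans(train_table)
  Xc <- sweep(train_table, 2, mu)
  sv <- svd(Xc, nu = k, nv = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xc %*% loadings
  out <- list(method = method, mean = mu, loadings = loadings, k = k)
  if (method == "ica") {
    sds <- apply(scores, 2, sd)
    sds[sds < 1e-12] <- 1
    Z <- sweep(scores, 2, sds, "/")
    out$score_sd <- sds
    out$rotation <- fastica_rotation(Z, seed = seed)
  }
  structure(out, class = "reduction_projector")
}

# FastICA fixed-point iteration with deflation (tanh contrast) on whitened
# data Z (n x k). Returns the k x k orthogonal unmixing rotation.
fastica_rotation <- function(Z, max_iter = 200, tol = 1e-6, seed = 1L) {
  set.seed(seed)
  n <- nrow(Z); k <- ncol(Z)
  W <- matrix(0, k, k)
  for (comp in seq_len(k)) {
    w <- rnorm(k); w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- Z %*% w
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- colMeans(Z * as.vector(g)) - mean(gp) * w
      if (comp > 1) {
        Wp <- W[, seq_len(comp - 1), drop = FALSE]
        w_new <- w_new - Wp %*% (t(Wp) %*% w_new)
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      if (abs(abs(sum(w_new * w)) - 1) < tol) { w <- w_new; break }
      w <- w_new
    }
    W[, comp] <- w
  }
  W
}

#' @rdname fit_reduction
#' @param projector A `reduction_projector`.
#' @param table Any n x p matrix on the same feature grid.
#' @return `project_reduction` returns the n x k reduced table.
#' @export
project_reduction <- function(projector, table) {
  s <- sweep(table, 2, projector$mean) %*% projector$loadings
  if (projector$method == "ica")
    s <- sweep(s, 2, projector$score_sd, "/") %*% projector$rotation
  s
}

#' Train a class-weighted SVM
#'
#' Support vector classification (SMO-family solver) minimising hinge loss
#' with per-class costs multiplied by inverse class frequencies. Probability
#' outputs come from a Platt-style sigmoid calibrated on the training-fold
#' decision values.
#'
#' @param table n x p feature matrix (flattened volumes, CNN features or
#'   flattened saliency maps - the contract is identical).
#' @param labels Binary labels (`"severe"` positive).
#' @param config An [svm_config()].
#' @return A `morph_svm` model.
#' @export
train_svm <- function(table, labels, config = svm_config()) {
  y <- factor(ifelse(labels_to_y(labels) == 2, "severe", "nonsevere"),
              levels = c("nonsevere", "severe"))
  if (nlevels(droplevels(y)) < 2) stop("train_svm: two classes required")
  cw <- inverse_frequency_weights(y)
  proj <- NULL
  Xt <- table
  if (config$reduction != "none") {
    proj <- fit_reduction(table, config$reduction, config$n_components,
                          seed = config$seed)
    Xt <- project_reduction(proj, table)
  }
  fit <- e1071::svm(Xt, y,
                    kernel = if (config$kernel == "rbf") "radial" else "linear",
                    cost = config$cost,
                    gamma = if (config$kernel == "rbf")
                      1 / config$kernel_scale^2 else 1 / ncol(Xt),
                    class.weights = cw, scale = FALSE)
  dv <- attr(predict(fit, Xt, decision.values = TRUE), "decision.values")[, 1]
  # orient decision values so larger means more severe
  orient <- if (mean(dv[y == "severe"]) >= mean(dv[y == "nonsevere"])) 1 else -1
  dv <- orient * dv
  calib <- platt_calibration(dv, y == "severe")
  structure(list(fit = fit, projector = proj, orientation = orient,
                 calibration = calib, config = config,
                 classes = c("nonsevere", "severe")), class = "morph_svm")
}

# Platt sigmoid p(severe) = 1/(1+exp(-(a*d + b))) fitted on training decision
# values; degenerate fits fall back to the clipped class frequency.
platt_calibration <- function(decision, is_positive) {
  if (length(unique(is_positive)) < 2 || sd(decision) < 1e-12) {
    p <- min(max(mean(is_positive), 0.01), 0.99)
    return(list(a = 0, b = log(p / (1 - p)), fallback = TRUE))
  }
  fit <- suppressWarnings(
    stats::glm(is_positive ~ decision, family = stats::binomial()))
  co <- stats::coef(fit)
  if (!all(is.finite(co))) {
    p <- min(max(mean(is_positive), 0.01), 0.99)
    return(list(a = 0, b = log(p / (1 - p)), fallback = TRUE))
  }
  list(a = unname(co[2]), b = unname(co[1]), fallback = FALSE)
}

#' @rdname train_svm
#' @param model A `morph_svm`.
#' @return `decision_values` returns oriented decision values (larger =
#'   more severe).
#' @export
decision_values <- function(model, table) {
  Xt <- if (!is.null(model$projector))
    project_reduction(model$projector, table) else table
  dv <- attr(predict(model$fit, Xt, decision.values = TRUE),
             "decision.values")[, 1]
  model$orientation * dv
}

#' SVM class probabilities
#'
#' Monotone Platt-sigmoid map of decision values to \[0, 1\].
#'
#' @param model A `morph_svm`.
#' @param table Feature matrix on the training grid.
#' @return n x 2 probability matrix (`nonsevere`, `severe`), rows sum to 1.
#' @export
predict_proba_svm <- function(model, table) {
  dv <- decision_values(model, table)
  ps <- 1 / (1 + exp(-(model$calibration$a * dv + model$calibration$b)))
  p <- cbind(nonsevere = 1 - ps, severe = ps)
  rownames(p) <- rownames(table)
  p
}

#' @rdname train_svm
#' @export
predict_label_svm <- function(model, table) {
  p <- predict_proba_svm(model, table)
  ifelse(p[, "severe"] >= 0.5, "severe", "nonsevere")
}

# Weighted hinge loss of oriented decision values.
weighted_hinge <- function(decision, labels, class_weights) {
  y <- ifelse(labels_to_y(labels) == 2, 1, -1)
  w <- class_weights[ifelse(y > 0, "severe", "nonsevere")]
  mean(w * pmax(0, 1 - y * decision))
}

#' Random-search tuning of an SVM over inner folds
#'
#' Draws hyperparameters from 300 logarithmically spaced bins (cost in
#' \[1e-3, 2e4\], kernel scale in \[1e-3, 1e3\]; component counts uniform in
#' 1-75 when reducing), trains on each inner training split with any
#' reduction refitted inside the fold, and scores by class-weighted hinge
#' loss on the held-out inner fold. The kernel itself is never tuned.
#'
#' @param table,labels Outer-fold training data.
#' @param inner_fold Inner fold id per training row.
#' @param config Template [svm_config()] fixing kernel/reduction; `cost`,
#'   `kernel_scale`, `n_components` are searched.
#' @param n_draws Number of random-search draws (default
#'   `config$n_search_draws`).
#' @return List with `chosen` (an `svm_config`), `losses`, `draws`.
#' @export
tune_svm <- function(table, labels, inner_fold, config = svm_config(),
                     n_draws = config$n_search_draws) {
  set.seed(config$seed)
  cost_bins <- 10^seq(log10(1e-3), log10(2e4), length.out = 300)
  scale_bins <- 10^seq(log10(1e-3), log10(1e3), length.out = 300)
  folds <- sort(unique(inner_fold))
  cw <- inverse_frequency_weights(
    factor(ifelse(labels_to_y(labels) == 2, "severe", "nonsevere"),
           levels = c("nonsevere", "severe")))
  draws <- data.frame(cost = sample(cost_bins, n_draws, replace = TRUE),
                      kernel_scale = sample(scale_bins, n_draws, replace = TRUE),
                      n_components = sample.int(min(75, nrow(table) - 2),
                                                n_draws, replace = TRUE))
  losses <- numeric(n_draws)
  for (dr in seq_len(n_draws)) {
    cfg <- config
    cfg$cost <- draws$cost[dr]
    cfg$kernel_scale <- draws$kernel_scale[dr]
    cfg$n_components <- draws$n_components[dr]
    fold_loss <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      tr <- inner_fold != folds[fi]
      fit <- tryCatch(
        train_svm(table[tr, , drop = FALSE], labels[tr], cfg),
        error = function(e) NULL)
      if (is.null(fit)) { fold_loss[fi] <- Inf; next }
      dv <- decision_values(fit, table[!tr, , drop = FALSE])
      fold_loss[fi] <- weighted_hinge(dv, labels[!tr], cw)
    }
    losses[dr] <- mean(fold_loss)
  }
  best <- which.min(losses)
  chosen <- config
  chosen$cost <- draws$cost[best]
  chosen$kernel_scale <- draws$kernel_scale[best]
  chosen$n_components <- draws$n_components[best]
  list(chosen = chosen, losses = losses, draws = draws, chosen_ix = best)
}
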