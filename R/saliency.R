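#' Saliency map container
#'
#' @param grid 3D importance array on the model input lattice.
#' @param method Attribution method tag.
#' @param subject_id Optional subject identifier.
#' @param predicted_class Class the attribution explains.
#' @param normalized Whether the map has been rectified and normalized to
#'   sum 1.
#' @return A `saliency_map`.
#' @export
saliency_map <- function(grid, method = c("gradcampp", "deepshap", "kernelshap"),
                         subject_id = NULL, predicted_class = NULL,
                         normalized = FALSE) {
  structure(list(grid = grid, method = match.arg(method),
                 subject_id = subject_id, predicted_class = predicted_class,
                 normalized = normalized), class = "saliency_map")
}

sal_grid <- function(m) if (inherits(m, "saliency_map")) m$grid else m

#' Grad-CAM++ saliency for the 3D CNN
#'
#' Channel weights are built from the gradients of the class score with
#' respect to the last convolutional block's feature maps using the
#' closed-form second-order weighting for an exponential score target:
#' `alpha = g^2 / (2 g^2 + sum(A) g^3)` per channel/position, channel weight
#' `w_k = sum(alpha * relu(g))`, map `relu(sum_k w_k A_k)`, trilinearly
#' upsampled to the input grid.
#'
#' @param model A `trained_cnn` (or `cnn_model`).
#' @param volume One scaled 3D input array.
#' @param target_class `"severe"`, `"nonsevere"`, or 1/2 column index.
#' @return A `saliency_map` (nonnegative, not yet normalized).
#' @export
gradcampp <- function(model, volume, target_class = "severe") {
  net <- if (inherits(model, "trained_cnn")) model$net else model
  cls <- if (is.character(target_class)) match(target_class, net$classes)
         else as.integer(target_class)
  X <- volumes_to_input(list(volume), net$input_dim)
  fw <- net_forward(net, X, training = FALSE)
  dlogits <- matrix(0, 2, 1)
  dlogits[cls, 1] <- 1
  bw <- net_backward(net, fw, dlogits)
  ix <- net$last_conv_relu_ix
  A <- fw$acts[[ix]]                 # C x nvox x 1
  g <- bw$dacts[[ix + 1]]            # gradient w.r.t. A
  A <- A[, , 1, drop = FALSE]; dim(A) <- dim(A)[1:2]
  g <- g[, , 1, drop = FALSE]; dim(g) <- dim(g)[1:2]
  if (max(abs(g)) < 1e-300) {
    warning("gradcampp: zero gradients; returning zero map")
    return(saliency_map(array(0, net$input_dim), "gradcampp",
                        predicted_class = net$classes[cls]))
  }
  sumA <- rowSums(A)
  denom <- 2 * g^2 + sumA * g^3
  alpha <- ifelse(abs(denom) < 1e-300, 0, g^2 / denom)
  w <- rowSums(alpha * pmax(g, 0))
  cam <- pmax(colSums(w * A), 0)
  conv_dims <- net$layers[[ix + 1]]$dims   # pool layer records input dims
  cam3d <- array(cam, conv_dims)
  up <- upsample_trilinear(cam3d, net$input_dim)
  saliency_map(pmax(up, 0), "gradcampp", predicted_class = net$classes[cls])
}

# DeepLIFT rescale-rule multipliers through the network; linear layers
# propagate like gradients, ReLUs rescale by delta-out/delta-in, max pooling
# routes to the argmax of the explained input's forward pass.
deeplift_attribution <- function(net, fw_x, fw_b, target_class) {
  L <- length(net$layers)
  m <- matrix(0, 2, 1)
  m[target_class, 1] <- 1
  for (i in L:1) {
    ly <- net$layers[[i]]
    in_x <- if (i == 1) fw_x$input else fw_x$acts[[i - 1]]
    in_b <- if (i == 1) fw_b$input else fw_b$acts[[i - 1]]
    if (ly$type == "fc") {
      m <- t(ly$W) %*% m
    } else if (ly$type == "relu") {
      d_in <- in_x - in_b
      d_out <- fw_x$acts[[i]] - fw_b$acts[[i]]
      ratio <- ifelse(abs(d_in) > 1e-7, d_out / pmax(abs(d_in), 1e-300) *
                        sign(d_in), as.numeric(in_x > 0))
      m <- m * ratio
    } else if (ly$type == "dropout") {
      # eval mode: identity
    } else if (ly$type == "bnorm") {
      istd <- 1 / sqrt(ly$rvar + ly$eps)
      m <- m * ly$gamma * istd
    } else if (ly$type == "flatten") {
      m <- array(m, dim(in_x))
    } else if (ly$type == "pool") {
      m <- maxpool3d_backward_cpp(m, fw_x$caches[[i]]$argmax,
                                  fw_x$caches[[i]]$nvox_in)
    } else if (ly$type == "conv") {
      bw <- conv3d_backward_cpp(in_x, m, ly$dims, ly$W)
      m <- bw$dX
    }
  }
  m * (fw_x$input - fw_b$input)
}

#' Deep SHAP attribution for the CNN
#'
#' DeepLIFT-style rescale-rule attributions averaged over a background set
#' drawn from training data: each voxel's attribution measures its role in
#' moving the class score away from the mean background score. For a purely
#' linear model the attribution reduces to `w_i * (x_i - E[background_i])`,
#' and the attributions sum (approximately, exactly without pooling) to
#' `score(x) - mean(score(background))`.
#'
#' @param model A `trained_cnn` (or `cnn_model`).
#' @param volume One scaled 3D input array.
#' @param background_set List of scaled 3D arrays (training samples).
#' @param target_class Class to explain.
#' @return Signed 3D attribution array with attribute `completeness`
#'   (`c(attr_sum, score_delta)`).
#' @export
deep_shap <- function(model, volume, background_set, target_class = "severe") {
  net <- if (inherits(model, "trained_cnn")) model$net else model
  cls <- if (is.character(target_class)) match(target_class, net$classes)
         else as.integer(target_class)
  X <- volumes_to_input(list(volume), net$input_dim)
  fw_x <- net_forward(net, X, training = FALSE)
  total <- array(0, c(1, prod(net$input_dim), 1))
  b_scores <- numeric(length(background_set))
  for (b in seq_along(background_set)) {
    Xb <- volumes_to_input(background_set[b], net$input_dim)
    fw_b <- net_forward(net, Xb, training = FALSE)
    b_scores[b] <- fw_b$logits[cls, 1]
    total <- total + deeplift_attribution(net, fw_x, fw_b, cls)
  }
  attr_map <- array(total[1, , 1] / length(background_set), net$input_dim)
  attr(attr_map, "completeness") <-
    c(attr_sum = sum(attr_map),
      score_delta = fw_x$logits[cls, 1] - mean(b_scores))
  attr_map
}

#' Value of a feature coalition under conditional k-NN imputation
#'
#' Absent features are imputed from the `k` nearest neighbours of `x` in the
#' reference dataset, measured on the present features (all rows when the
#' coalition is empty); the value is the mean model output over the imputed
#' composites.
#'
#' @param predict_fn Function mapping a numeric matrix (rows = samples) to a
#'   numeric vector of model outputs.
#' @param x Numeric feature vector being explained.
#' @param dataset Reference matrix (rows = samples).
#' @param S Logical vector marking present features.
#' @param k Number of neighbours used for imputation.
#' @return Scalar coalition value.
#' @export
shap_coalition_value <- function(predict_fn, x, dataset, S, k) {
  n <- nrow(dataset)
  k <- max(1, min(k, n))
  if (any(S)) {
    d2 <- colSums((t(dataset[, S, drop = FALSE]) - x[S])^2)
    nb <- order(d2)[seq_len(k)]
  } else nb <- seq_len(n)
  comp <- dataset[nb, , drop = FALSE]
  comp[, S] <- matrix(x[S], length(nb), sum(S), byrow = TRUE)
  mean(predict_fn(comp))
}

#' Kernel SHAP by Monte-Carlo permutation sampling
#'
#' Shapley-value estimates for a single prediction: random feature
#' permutations are walked, accumulating each feature's marginal
#' contribution to the coalition value, with absent features imputed from
#' the k nearest neighbours of `x` in the reference dataset
#' (`k = k_fraction * n`, the conditional-kernel convention).
#'
#' @inheritParams shap_coalition_value
#' @param k_fraction Neighbourhood size as a fraction of the dataset
#'   (default 0.1).
#' @param n_draws Number of sampled permutations.
#' @param seed Integer seed recorded with the estimate.
#' @return Numeric vector of per-feature Shapley estimates (attribute
#'   `seed`).
#' @export
kernel_shap <- function(predict_fn, x, dataset, k_fraction = 0.1,
                        n_draws = 50, seed = 1L) {
  p <- length(x)
  n <- nrow(dataset)
  k <- max(1, round(k_fraction * n))
  if (n_draws < 2 * p)
    warning("kernel_shap: n_draws is small relative to the number of features; estimates may be noisy")
  set.seed(seed)
  phi <- numeric(p)
  for (dr in seq_len(n_draws)) {
    perm <- sample.int(p)
    S <- rep(FALSE, p)
    v_prev <- shap_coalition_value(predict_fn, x, dataset, S, k)
    for (f in perm) {
      S[f] <- TRUE
      v_new <- shap_coalition_value(predict_fn, x, dataset, S, k)
      phi[f] <- phi[f] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi <- phi / n_draws
  attr(phi, "seed") <- seed
  phi
}

#' Rectify and normalize a saliency map
#'
#' Negative values are replaced with zeros (attributions toward the
#' predicted class only) and the map is divided by its total so it sums
#' to 1; an all-zero map stays all-zero with `normalized = FALSE`.
#'
#' @param map 3D array or `saliency_map`.
#' @param method Method tag for the result when `map` is a bare array.
#' @return A `saliency_map`.
#' @export
rectify_and_normalize <- function(map, method = "gradcampp") {
  g <- pmax(sal_grid(map), 0)
  tot <- sum(g)
  if (inherits(map, "saliency_map")) method <- map$method
  if (tot <= 0)
    return(saliency_map(g, method, normalized = FALSE))
  saliency_map(g / tot, method,
               subject_id = if (inherits(map, "saliency_map")) map$subject_id,
               predicted_class = if (inherits(map, "saliency_map")) map$predicted_class,
               normalized = TRUE)
}

#' Lesion-centred region-of-interest partition
#'
#' Six binary masks: the lesion, the perilesional shell (lesion dilated by
#' `dilation_radius`, minus the lesion, clipped to left-hemisphere brain),
#' the extralesional remainder of the left hemisphere, and their right-
#' hemisphere homologs by midline reflection (clipped to the right
#' hemisphere when the lesion touches the midline). The three left masks
#' tile the left-hemisphere brain exactly.
#'
#' @param lesion_mask Binary 3D array (left-hemisphere lesion).
#' @param brain_mask Binary 3D array of brain voxels.
#' @param dilation_radius Dilation steps for the perilesional shell
#'   (default 2 voxels, i.e. 16 mm at 8 mm resolution).
#' @param connectivity 26 (default) or 6.
#' @return An `roi_partition`: named list of six binary arrays.
#' @export
build_rois <- function(lesion_mask, brain_mask, dilation_radius = 2,
                       connectivity = 26) {
  d <- dim(lesion_mask)
  left <- left_hemi_mask(d)
  lesion <- lesion_mask != 0
  peri <- dilate_mask(lesion, dilation_radius, connectivity) & !lesion &
    brain_mask & left
  extra <- left & brain_mask & !lesion & !peri
  right <- !left
  rois <- list(
    lesion = lesion,
    perilesional = peri,
    extralesional = extra,
    lesion_homolog = mirror_lr(lesion) & right,
    perilesional_homolog = mirror_lr(peri) & right,
    extralesional_homolog = mirror_lr(extra) & right)
  structure(rois, class = "roi_partition")
}

#' ROI saliency by subject
#'
#' Sum of normalized saliency inside each ROI per subject (the proportion of
#' total feature importance the region carries).
#'
#' @param maps List of normalized `saliency_map`s (or 3D arrays).
#' @param rois An `roi_partition`.
#' @return n x 6 matrix of ROI saliency proportions.
#' @export
roi_saliency <- function(maps, rois) {
  t(vapply(maps, function(m) {
    g <- sal_grid(m)
    vapply(rois, function(r) sum(g[r]), numeric(1))
  }, numeric(length(rois))))
}

#' Group comparison of ROI saliency
#'
#' Per ROI: mean normalized saliency per group and a two-sample t-test of
#' the severe/nonsevere difference. Callers should pass only correctly
#' predicted subjects, matching how group saliency is summarised.
#'
#' @param maps List of normalized `saliency_map`s (or 3D arrays).
#' @param rois An `roi_partition`.
#' @param predicted_groups Character vector (`"severe"`/`"nonsevere"`) per
#'   map.
#' @return data.frame with one row per ROI: group means, `t`, `df`, `p`.
#' @export
roi_group_test <- function(maps, rois, predicted_groups) {
  stopifnot(length(maps) == length(predicted_groups))
  sev <- labels_to_y(predicted_groups) == 2
  if (sum(sev) < 2 || sum(!sev) < 2)
    stop("roi_group_test: each group needs at least 2 subjects")
  vals <- roi_saliency(maps, rois)
  rows <- lapply(seq_along(rois), function(r) {
    a <- vals[sev, r]; b <- vals[!sev, r]
    if (sd(a) < 1e-300 && sd(b) < 1e-300 && mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else tt <- t.test(a, b)
    data.frame(roi = names(rois)[r],
               mean_severe = mean(a), mean_nonsevere = mean(b),
               t = unname(tt$statistic[[1]]), df = unname(tt$parameter[[1]]),
               p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Index of the mean-performing repeat
#'
#' Saliency is computed from the model of the repeat whose F1 is closest to
#' the across-repeat mean (ties to the earlier repeat).
#'
#' @param f1_by_repeat Numeric vector of per-repeat F1 scores.
#' @return Repeat index.
#' @export
mean_performing_repeat <- function(f1_by_repeat) {
  which.min(abs(f1_by_repeat - mean(f1_by_repeat)))
}

#' Write a saliency map as NIfTI (float32)
#'
#' @param map A `saliency_map` or 3D array.
#' @param path Output path.
#' @param voxel_size_mm Voxel size stamped into the header.
#' @return `path`, invisibly.
#' @export
write_saliency_nifti <- function(map, path, voxel_size_mm = 8) {
  g <- sal_grid(map)
  attr(g, "pixdim") <- rep(voxel_size_mm, 3)
  img <- RNifti::asNifti(g, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}
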