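# Shared fixtures built in code: tiny cohorts, toy networks, planted maps.

tiny_cohort_config <- function(seed = 1, n = 24, grid = c(12, 12, 12)) {
  cohort_config(n_subjects = n, grid_shape = grid,
                lesion_volume_range = c(10, 40), atrophy_voxels = 12,
                seed = seed)
}

# Cohort whose labels are driven by the spatial motif (matched atrophy
# totals), the premise the CNN-vs-SVM comparison rests on.
motif_cohort_config <- function(seed = 1, n = 200) {
  cohort_config(n_subjects = n, grid_shape = c(16, 16, 16),
                lesion_volume_range = c(20, 60), atrophy_voxels = 60,
                outcome_coefficients = c(a = 0, b = 60, sigma = 8),
                motif_probs = c(0.35, 0.65), seed = seed)
}

# A small untrained conv net for saliency plumbing tests.
toy_net <- function(input_dim = c(8, 8, 8), seed = 11, scale = 0.3) {
  spec <- architecture_spec(blocks = list(c(1, 8), c(1, 8)), dropout_rate = 0)
  net <- build_network(spec, input_dim, seed = seed)
  for (i in seq_along(net$layers))
    if (net$layers[[i]]$type == "conv")
      net$layers[[i]]$W <- net$layers[[i]]$W * scale
  net
}

# Replace a toy net's head by a global-average-pooling linear head acting
# directly on the last convolutional block's feature maps (the closed-form
# class-activation-map construction).
gap_linear_net <- function(net, class_weights) {
  keep <- 1:net$last_conv_relu_ix
  ly <- net$layers[keep]
  conv_dims <- net$layers[[net$last_conv_relu_ix + 1]]$dims
  C <- ncol(class_weights)
  nv <- prod(conv_dims)
  ly[[length(ly) + 1]] <- list(type = "flatten", c = C, dims = conv_dims)
  W <- matrix(0, 2, C * nv)
  for (cl in 1:2) W[cl, ] <- rep(class_weights[cl, ], times = nv) / nv
  ly[[length(ly) + 1]] <- list(type = "fc", W = W, b = c(0, 0))
  net$layers <- ly
  net$feature_ix <- length(ly)
  net
}

# Single-layer linear "network" on a flattened 3D input.
linear_net <- function(input_dim, W, b = c(0, 0)) {
  structure(list(spec = NULL, input_dim = input_dim,
                 layers = list(list(type = "flatten", c = 1, dims = input_dim),
                               list(type = "fc", W = W, b = b)),
                 last_conv_relu_ix = NA, feature_ix = 2,
                 classes = c("nonsevere", "severe")), class = "cnn_model")
}

# Planted-archetype map matrix for subtyping tests.
planted_maps <- function(n_per = 30, k = 3, p = 64, noise = 0.03, seed = 3) {
  set.seed(seed)
  arch <- matrix(runif(k * p), k, p)
  maps <- arch[rep(1:k, each = n_per), ] +
    matrix(rnorm(k * n_per * p, 0, noise), k * n_per, p)
  maps / rowSums(maps)
}

# Adjusted Rand index (independent of the clustering code under test).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}
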